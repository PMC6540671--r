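# traitshift

Grassland plant communities respond to a dry year through two channels: the
species already present change their trait values (intraspecific trait
variability), and the relative abundances of species change (species
turnover). Community-level functional indices — the community-weighted mean
(CWM) of a trait and functional dispersion (FDis) — feel both at once, and
the two channels can reinforce or oppose each other. `traitshift` is for
community ecologists who have species × year trait tables and per-quadrat
relative-biomass surveys from climatically contrasting years and want to
know *which* channel drove the observed change in each index.

## What it computes

* **Growing-period aridity** — Holdridge potential evapotranspiration,
  `PET (mm) = 58.93 × (period days / year days) × mean bio-temperature`
  (temperatures clipped into [0, 30] °C), and the aridity index
  PET/precipitation, used to label the study years wet and dry.
* **Two-layer relative biomass** — for tussock grasslands:
  `B_t = (A_t − A_Asp)·B_o + B_Asp` with tussock masses predicted from a
  fitted volume–mass allometry, then `p_Asp = B_Asp/B_t` and
  `p_i = (A_t − A_Asp)·B_i/B_t`.
* **Functional indices per quadrat-year** — CWM `Σ p_i x_i`; single-trait
  FDis `Σ p_i |x_i − CWM|`; multi-trait FDis as the abundance-weighted mean
  distance to the abundance-weighted centroid in a Gower/PCoA trait space
  (negative-eigenvalue axes handled as imaginary coordinates); Rao's
  quadratic entropy `Σ_i Σ_j p_i p_j d_ij`.
* **The specific/fixed decomposition** — indices are computed twice: with
  *specific* (year-measured) traits and with *fixed* traits (each species'
  across-year mean). With one-way (year) explained sums of squares,
  `SS_specific = SS_fixed + SS_intra + SS_cov`: turnover, intraspecific
  variability, and their covariation (negative when the two channels
  oppose). Shares are reported with F/p for each series.
* **Compositional tests** — Bray–Curtis dissimilarity and a seeded one-way
  PERMANOVA (Anderson's sums of squares, permutation p-value).
* **A synthetic-community generator** — lognormal traits, Dirichlet
  abundance profiles, with explicit dials for intraspecific shift, abundance
  turnover, and directed turnover that produces covariation of either sign;
  presets encode the canonical regimes. Every stage of the package runs
  without any external data.

## Worked example

Simulate a study in which only intraspecific variation separates the two
years (dry-year shifts of +24% SLA, +15% LDMC, −15% LNC), then decompose
the between-year variation of each significant index in grassland G1:

```r
library(traitshift)

d   <- generate_scenario(scenario_presets("pure_intraspecific"), seed = 2026)
dec <- decompose_dataset(d$traits, d$abundance)
subset(dec, grassland == "G1" & decomposed,
       select = c(metric, share_fixed, share_intra, share_cov, p_specific))
#>      metric share_fixed share_intra share_cov p_specific
#> 1   CWM-SLA    3.85e-07       1.001  -0.00124   2.22e-11
#> 2  CWM-LDMC    2.09e-05       1.009  -0.00917   5.62e-05
#> 3   CWM-LNC    1.62e-05       0.992   0.00803   5.04e-09
#> 5  FDis-SLA    1.66e-06       1.003  -0.00258   1.96e-04
#> 6 FDis-LDMC    8.15e-05       1.018  -0.01822   6.35e-03
#> 7  FDis-LNC    2.50e-05       0.990   0.00995   1.63e-04
```

The turnover share is ~0 and the intraspecific share ~100% for every index
with a significant year effect — the decomposition recovers the generating
process. (Shares of `SS_specific` sum to 1; the covariation share may be
negative.) Composition, by contrast, barely moves between years:

```r
dm <- bray_curtis_matrix(d$abundance, grassland = "G1")
permanova(dm, n_permutations = 999, seed = 2026)
#> PERMANOVA (one-way)
#>          Df SumOfSqs MeanSqs     F R2     p
#> Groups    1   0.0000   0.000 5e-04  0 0.925
#> Residual 16   1.2488   0.078    NA  1    NA
#> Total    17   1.2488      NA    NA  1    NA
#> 999 permutations, seed 2026
```

The whole chain (simulate/ingest → aridity → metrics → decomposition →
PERMANOVA) can also be driven from one YAML config with
`run_pipeline("config.yaml")`, which writes `metrics.csv`,
`decomposition.csv`, `permanova.csv`, `aridity.csv`, a run log, and a
manifest with the seed and config hash; the same config reproduces
byte-identical tables.

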