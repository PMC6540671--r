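---
title: "Decomposing interannual functional-diversity change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing interannual functional-diversity change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitshift)
```

## The scientific problem

Grassland communities answer a dry year in two ways: the species present
change their trait values (intraspecific trait variability, through
plasticity or shifts in genotype composition), and the relative abundances
of species change (species turnover). Community-level functional indices —
the community-weighted mean (CWM) of a trait and functional dispersion
(FDis) — respond to both at once. `traitshift` implements the machinery to
measure both index families per quadrat and year, and to split the
between-year variation of each index into a turnover part, an intraspecific
part, and their covariation.

The package expects the sampling design common in such field studies: a few
grassland types, each with several sites, each site with a few permanent
quadrats, surveyed in two years of contrasting aridity; species-level trait
values measured per grassland and year ("specific" traits); and relative
aboveground biomass per quadrat as the abundance measure.

## Growing-period aridity

Years are classified by the ratio of Holdridge potential evapotranspiration
to precipitation over the growing period up to the sampling date:

PET (mm) = 58.93 × (days in period / days in year) × mean bio-temperature,

where bio-temperature clips temperatures into [0, 30] °C, the band in which
plants are taken to grow. The aridity index is PET/precipitation; the year
with the larger index within a grassland is labelled dry, the other wet.

```{r aridity}
clim <- read_climate_table(system.file("extdata", "growing_season_climate.csv",
                                       package = "traitshift"))
aridity_table(clim)
```

Two numerical conventions matter. First, the period length is an explicit
input (days, with the year length 365 or 366), because "four months before
sampling" has no unique day count; the shipped table uses 123-day periods
for the two Qinghai grasslands and 122-day periods for the Inner Mongolia
steppe, whose wet year (2012) is a leap year. Second, reported indices are
rounded half away from zero at 2 decimals (`round_half_up()`), while all
internal computation keeps full precision. Whether sub-zero daily means are
clipped before averaging or a plain period mean is used is exposed via
`clip_biotemperature`, since either reading is defensible for period data;
with period means above zero, as here, the two coincide.

## Two-layer biomass

Tussock grasslands hold a tall layer (one dominant bunchgrass) over a short
understory, so relative biomass cannot be read off 1 × 1 m clip harvests
alone. In a 5 × 5 m quadrat with total area $A_t$, tussock projected areas
summing to $A_{Asp}$, understory biomass density $B_o$ (g/m²) and per-species
densities $B_i$, the quadrat total is

$$B_t = (A_t - A_{Asp})\,B_o + B_{Asp},$$

with $B_{Asp}$ the summed tussock masses predicted from an allometric fit of
harvested mass on tussock volume. Relative abundances follow as
$p_{Asp} = B_{Asp}/B_t$ and $p_i = (A_t - A_{Asp})B_i/B_t$; when the $B_i$
sum to $B_o$ these fractions sum to 1 exactly. Tussock volume is
operationalised as projected area × height (a cylinder); a `shape_factor`
rescales to other solids, since field studies rarely state the solid they
assumed. The allometry defaults to the power form (log–log least squares),
the standard choice for plant mass–size scaling; a linear form is available.

## Community metrics

For a quadrat with relative abundances $p_i$ (renormalised over the species
that carry trait values) and trait values $x_i$:

* CWM $= \sum_i p_i x_i$;
* single-trait FDis $= \sum_i p_i\,|x_i - \mathrm{CWM}|$;
* multi-trait FDis: species are placed in the Gower trait space
  ($d_{ij} = \tfrac1T\sum_t |x_{it}-x_{jt}|/\mathrm{range}_t$), embedded by
  principal coordinates; FDis is the abundance-weighted mean distance to the
  abundance-weighted centroid, with squared distances equal to the real part
  minus the imaginary part when negative eigenvalues occur;
* Rao's quadratic entropy $Q = \sum_i\sum_j p_i p_j d_{ij}$.

Gower ranges are computed per grassland over the specific trait values of
both years pooled. This keeps one trait space per grassland, so that indices
computed under specific and fixed traits are comparable — a requirement of
the decomposition. Small negative squared centroid distances (possible under
non-Euclidean Gower geometry; typically well under 1% of the largest
distance) are floored at zero; `community_metrics()` counts the affected
communities and reports them once per run. An alternative `euclidean` mode
(traits z-scored over the same pool, centroid computed directly in trait
space, no embedding) exists for cross-checking the Gower/PCoA route.

Species whose traits were measured in only one year keep that value in the
other year (`carry_over_traits()`), mirroring what field studies do when a
year's measurements are lost; the validation report flags every such
species. Samples whose trait-covered biomass falls below the coverage
threshold (default 0.80, chosen because trait campaigns typically cover
83–100% of biomass) yield NA metrics rather than silently biased ones.

## The specific/fixed decomposition

A species' *fixed* trait is the unweighted mean of its specific values over
the years it was measured. Metrics recomputed with fixed traits can differ
between years only through turnover. With one-way (year) explained sums of
squares $SS(\cdot)$ over the per-quadrat series,

$$SS_{specific} = SS_{fixed} + SS_{intra} + SS_{cov},$$

where the intraspecific series is specific − fixed per sample and
$SS_{cov}$ is the remainder. The identity is exact by construction; the
package asserts it to 1e-10 relative in its tests. $SS_{cov}$ is positive
when turnover and plasticity push the metric the same way between years and
negative when they oppose; shares of $SS_{specific}$ may individually exceed
100% but always sum to 100%.

```{r decomposition}
d <- generate_scenario(scenario_presets("mixed_negative_cov"), seed = 1)
dec <- decompose_dataset(d$traits, d$abundance)
subset(dec, metric == "CWM-SLA",
       select = c(grassland, share_fixed, share_intra, share_cov, p_specific))
```

Design choices that were genuinely open:

* **Replication unit.** The year ANOVA runs over quadrats (9 per
  grassland-year under the default design). Field studies often leave the
  unit implicit; site means are available via `unit = "site"` for a more
  conservative test with 3 replicates per year.
* **Significance gate.** By default only metrics with a significant year
  effect on the specific series (p < 0.05) are decomposed, since shares of a
  near-zero $SS_{specific}$ are noise; `only_significant = FALSE` overrides.
* **Per-grassland scope.** The decomposition runs within grassland with year
  as the single factor; grasslands share no species, so pooling would mix
  incommensurable trait spaces.

## Compositional change

Bray–Curtis dissimilarities on relative biomass feed a one-way PERMANOVA
with Anderson's distance-based sums of squares and a permutation p-value
$(\#\{F^\pi \ge F\} + 1)/(B + 1)$ under unrestricted random relabelling,
B = 999 by default. A seed is mandatory: permutation p-values are part of
the reported results and must be reproducible. Permutations are unrestricted
because the two-year, one-factor design has no stated stratification; note
that with strong site heterogeneity an unrestricted test can be insensitive
to a coherent within-site year shift (the site signal inflates the
residual), which is a property of the design, not of the implementation.

## The synthetic generator

`simulation_scenario()` emulates the study's data structure — by default 3
grasslands × 3 sites × 3 quadrats × 2 years, 20 species per grassland with
disjoint pools, and four traits (SLA m²/kg, LDMC g/kg, LNC g/kg, H cm) —
with explicit dials for the processes under study:

* Across-species trait values are lognormal, with default medians
  (SLA 15, LDMC 250, LNC 20, H 25) and log-sds (0.40, 0.30, 0.35, 0.60)
  typical of temperate grassland floras: right-skewed, height most variable.
* The dry-year value of species $s$ for trait $t$ is
  $x_{st}^{wet}\,(1+\delta_t)^{L_s}$ with $L_s$ a per-species lognormal
  plasticity multiplier (`shift_noise_sd = 0.30`). The noise multiplies the
  *shift*, not the value, so $\delta_t = 0$ makes the two years' trait
  tables identical exactly — the property the decomposition's "pure
  turnover" regime requires.
* Site abundance profiles are Dirichlet draws (concentration 1: strong
  dominance structure). The dry-year profile mixes the wet profile with an
  independent target profile by weight $\theta$ (`turnover`); the target can
  be tilted by $e^{-b z_s}$ with $z_s$ the standardised log value of a
  chosen trait, which is how directed turnover — and hence covariation of
  either sign — is generated. Quadrats perturb their site profile with
  lognormal noise (`quadrat_noise_sd = 0.15`, giving within-site abundance
  scatter of the order seen between repeated quadrats).

The presets (`scenario_presets()`) encode the regimes used throughout the
tests: pure intraspecific shift (δ = +24% SLA, +15% LDMC, −15% LNC, 0 H —
the qualitative directions dry years impose on these traits), pure turnover
(θ = 0.8), mixed regimes with positive or negative covariation (δ_SLA = +20%
against turnover tilted towards high- or low-SLA species), and a null. The
four non-null presets reduce quadrat noise to 0.02: they are diagnostic
constructions whose point is a clean attribution signal, and at survey-level
noise the incidental covariation between sampling noise and the imposed
shift (of order twice the square root of the fixed share) blurs the shares
that define the regime. The default scenario keeps the realistic 0.15.

What the generator does *not* emulate: species gains and losses between
years (turnover acts on shared pools), trait–abundance correlations beyond
the directed-turnover tilt, within-species spatial trait variation between
sites, and observation error on traits. Tests passing on these data
therefore certify the estimators and the decomposition algebra, not
robustness to every field artefact.

## Numerical conventions and test design

* Abundance tables must sum to 1 per sample within 1e-6 (hand-rounded
  tables are renormalised and logged); trait values must be strictly
  positive; duplicate keys are rejected outright.
* PCoA drops eigenvalues within 1e-10 (scaled with the matrix) of zero;
  distance preservation on Euclidean inputs is tested to 1e-8.
* The permutation count comparison uses a 1e-12 relative tie guard so that
  fully symmetric inputs give p ≈ 1 rather than an arbitrary split.
* Writers serialise numerics with 17 significant digits, making write/read
  round trips exact.
* The type-I-error check of the PERMANOVA runs 1000 null datasets × 499
  permutations on a single-site design (two year labels over 10 iid
  quadrats). With one site the quadrats are exchangeable and the permutation
  test is exact, so the empirical rejection rate at α = 0.05 must sit in
  [0.035, 0.065]; with several sites unrestricted permutations would not
  guarantee the nominal level (see above). Problem sizes throughout the test
  suite (typically 1 grassland × 8–20 species for property loops, the full
  3 × 3 × 3 × 2 design for end-to-end runs) were chosen so the whole suite
  exercises every code path at small cost.

## Limitations

* Only quantitative traits are supported; Gower here is the quantitative
  special case, not the mixed-type general form.
* The decomposition is two-group (year) only; continuous gradients or
  multi-year series need a different explained-SS model.
* The PERMANOVA is one-way and unstratified.
* Fixed traits average the available years unweighted; with more than two
  years of data other weightings become defensible.
* The aridity module implements the Holdridge PET formulation only.
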