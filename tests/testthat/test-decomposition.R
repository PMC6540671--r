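test_that("fixed traits are across-year means with single-year carry", {
  traits <- as_trait_table(data.frame(
    grassland = "G1", year = c(2013L, 2014L, 2013L),
    species = c("sp1", "sp1", "sp2"), trait = "SLA", value = c(10, 14, 9)))
  fx <- fixed_trait_table(traits)
  expect_equal(fx$value[fx$species == "sp1"], 12)
  expect_equal(fx$value[fx$species == "sp2"], 9)
  expect_equal(fx$n_years, c(2, 1))

  # identical years -> fixed equals either year
  t2 <- tiny_traits()
  df <- as.data.frame(t2)
  df$value[df$year == 2014] <- df$value[df$year == 2013]
  fx2 <- fixed_trait_table(as_trait_table(df))
  m <- merge(fx2, df[df$year == 2013, ], by = c("grassland", "species", "trait"))
  expect_equal(m$value.x, m$value.y)
})

test_that("explained_ss reproduces the hand-computed one-way ANOVA", {
  r <- explained_ss(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(r$ss_effect, 4)
  expect_equal(r$ss_residual, 1)
  expect_equal(r$f, 8)
  # equal group means
  r0 <- explained_ss(c(1, 2, 1, 2), c("A", "A", "B", "B"))
  expect_equal(r0$ss_effect, 0)
  expect_equal(r0$f, 0)
  expect_error(explained_ss(1:4, rep("A", 4)), "factor error")
})

test_that("explained_ss p-value matches quadrature of the F density", {
  dens <- function(x) df(x, 1, 2)
  p_num <- integrate(dens, 8, Inf, rel.tol = 1e-12)$value
  r <- explained_ss(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(r$p, p_num, tolerance = 1e-8)
})

test_that("explained_ss agrees with stats::anova on random data", {
  set.seed(61)
  for (rep in 1:10) {
    g <- factor(rep(c("w", "d"), each = 9))
    y <- rnorm(18, mean = ifelse(g == "d", 0.5, 0))
    mine <- explained_ss(y, g)
    ref <- anova(lm(y ~ g))
    expect_equal(mine$ss_effect, ref$`Sum Sq`[1], tolerance = 1e-12)
    expect_equal(mine$ss_residual, ref$`Sum Sq`[2], tolerance = 1e-12)
    expect_equal(mine$f, ref$`F value`[1], tolerance = 1e-12)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
  }
})

test_that("pure regimes decompose entirely into their own component", {
  # identical abundances, shifted traits: all intraspecific
  years <- rep(c(2013, 2014), each = 6)
  base <- rep(c(10, 11, 12, 10.5, 11.5, 12.5), 2)
  spec <- ifelse(years == 2014, base + 3, base)
  fix <- base
  d1 <- decompose_metric(spec, fix, years)
  expect_equal(d1$ss_fixed, 0)
  expect_equal(d1$ss_cov, 0)
  expect_equal(unname(d1$shares["intra"]), 1)

  # identical traits, changed abundances: all turnover
  spec2 <- ifelse(years == 2014, base * 1.5, base)
  d2 <- decompose_metric(spec2, spec2, years)
  expect_equal(d2$ss_intra, 0)
  expect_equal(d2$ss_cov, 0)
  expect_equal(unname(d2$shares["fixed"]), 1)
})

test_that("mixed scenarios satisfy the SS identity against brute force", {
  set.seed(62)
  for (rep in 1:20) {
    years <- rep(c("w", "d"), each = 8)
    fixed <- rnorm(16, ifelse(years == "d", 1, 0))
    intra <- rnorm(16, ifelse(years == "d", -0.6, 0))
    spec <- fixed + intra
    dec <- decompose_metric(spec, fixed, years)
    # independent recomputation from the raw series
    ssb <- function(y) {
      gm <- tapply(y, years, mean)
      sum(table(years) * (gm - mean(y))^2)
    }
    expect_equal(dec$ss_specific, ssb(spec), tolerance = 1e-12)
    expect_equal(dec$ss_fixed, ssb(fixed), tolerance = 1e-12)
    expect_equal(dec$ss_intra, ssb(spec - fixed), tolerance = 1e-12)
    expect_equal(dec$ss_fixed + dec$ss_intra + dec$ss_cov, dec$ss_specific,
                 tolerance = 1e-10 * max(1, dec$ss_specific))
    expect_equal(sum(dec$shares), 1, tolerance = 1e-10)
  }
})

test_that("scaling a series scales all SS terms quadratically", {
  set.seed(63)
  years <- rep(c("w", "d"), each = 5)
  fixed <- rnorm(10, ifelse(years == "d", 1, 0))
  spec <- fixed + rnorm(10, 0.3)
  d1 <- decompose_metric(spec, fixed, years)
  k <- 3.7
  d2 <- decompose_metric(k * spec, k * fixed, years)
  expect_equal(d2$ss_specific, k^2 * d1$ss_specific, tolerance = 1e-10)
  expect_equal(d2$ss_fixed, k^2 * d1$ss_fixed, tolerance = 1e-10)
  expect_equal(d2$ss_intra, k^2 * d1$ss_intra, tolerance = 1e-10)
  expect_equal(d2$ss_cov, k^2 * d1$ss_cov, tolerance = 1e-8)
  expect_equal(d2$shares, d1$shares, tolerance = 1e-10)
})

test_that("misaligned series are rejected", {
  expect_error(decompose_metric(1:4, 1:3, c(1, 1, 2, 2)), "alignment")
})

test_that("dataset-level decomposition attributes the generating regime", {
  d <- generate_scenario(scenario_presets("pure_intraspecific"), seed = 71)
  dec <- decompose_dataset(d$traits, d$abundance)
  sub <- dec[dec$metric %in% c("CWM-SLA", "CWM-LDMC", "CWM-LNC") & dec$decomposed, ]
  expect_gt(nrow(sub), 0)
  expect_true(all(sub$share_intra >= 0.95))
  expect_true(all(sub$share_fixed <= 0.05))

  d2 <- generate_scenario(scenario_presets("pure_turnover"), seed = 71)
  dec2 <- decompose_dataset(d2$traits, d2$abundance)
  sub2 <- dec2[dec2$decomposed, ]
  expect_gt(nrow(sub2), 0)
  expect_true(all(sub2$share_fixed >= 0.95))
  # with identical trait tables the intraspecific series vanishes exactly
  expect_true(all(abs(sub2$ss_intra) < 1e-20 * pmax(sub2$ss_specific, 1)))
})

test_that("year-significance gate controls which metrics are decomposed", {
  d <- generate_scenario(scenario_presets("null"), seed = 72)
  dec <- decompose_dataset(d$traits, d$abundance, alpha = 1e-6)
  expect_true(all(!dec$decomposed))
  expect_true(all(is.na(dec$ss_specific)))
  dec_all <- decompose_dataset(d$traits, d$abundance, only_significant = FALSE)
  expect_true(all(dec_all$decomposed))
})

test_that("site-level aggregation is available as the replication unit", {
  d <- generate_scenario(scenario_presets("pure_intraspecific"), seed = 73)
  dec <- decompose_dataset(d$traits, d$abundance, unit = "site",
                           only_significant = FALSE)
  expect_true(all(dec$n == 6))  # 3 sites x 2 years
})

test_that("FDis series decompose with the same machinery and identity", {
  d <- generate_scenario(scenario_presets("mixed_negative_cov"), seed = 74)
  dec <- decompose_dataset(d$traits, d$abundance, only_significant = FALSE)
  fd <- dec[grepl("FDis", dec$metric), ]
  ok <- !is.na(fd$ss_specific)
  expect_true(any(ok))
  expect_equal(fd$ss_fixed[ok] + fd$ss_intra[ok] + fd$ss_cov[ok],
               fd$ss_specific[ok],
               tolerance = 1e-10)
})
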