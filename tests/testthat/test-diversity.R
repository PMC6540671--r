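test_that("cwm is the abundance-weighted mean", {
  expect_equal(cwm(c(10, 20), c(0.5, 0.5)), 15)
  expect_equal(cwm(c(10, 20, 30), c(1, 0, 0)), 10)
  expect_equal(cwm(c(10, 20, 30), c(0.2, 0.3, 0.5)), 23)
  # NA traits drop out with renormalisation
  expect_equal(cwm(c(10, NA, 30), c(0.25, 0.5, 0.25)), 20)
  expect_error(cwm(c(NA, NA), c(0.5, 0.5)), "undefined")
})

test_that("single-trait FDis is the weighted mean deviation from the CWM", {
  expect_equal(fdis_single(c(0, 1), c(0.5, 0.5)), 0.5)
  expect_equal(fdis_single(c(4, 4, 4), c(0.2, 0.3, 0.5)), 0)
  expect_equal(fdis_single(c(0, 10), c(0.9, 0.1)), 1.8)
})

test_that("multi-trait FDis reduces to single-trait FDis over the Gower range", {
  x <- cbind(SLA = c(a = 0, b = 10))
  d <- gower_distance(x, ranges = c(SLA = 10))
  emb <- pcoa_embed(d)
  p <- c(a = 0.5, b = 0.5)
  expect_equal(fdis_multi(emb, p), 0.5)
  expect_equal(fdis_multi(emb, p), fdis_single(x[, 1], p) / 10)

  set.seed(51)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    v <- runif(n, 0, 50)
    names(v) <- paste0("s", seq_len(n))
    p <- rgamma(n, 1); p <- p / sum(p); names(p) <- names(v)
    rng <- diff(range(v))
    d <- gower_distance(cbind(tr = v), ranges = c(tr = rng))
    expect_equal(fdis_multi(pcoa_embed(d), p), fdis_single(v, p) / rng,
                 tolerance = 1e-10)
  }
})

test_that("multi-trait FDis matches the brute-force centroid computation", {
  set.seed(52)
  for (rep in 1:20) {
    cm <- random_community(sample(3:12, 1))
    d <- as.matrix(dist(cm$x))
    emb <- pcoa_embed(d)
    p <- cm$p
    names(p) <- rownames(cm$x)
    centroid <- colSums(cm$x * p)
    brute <- sum(p * sqrt(rowSums(sweep(cm$x, 2, centroid)^2)))
    expect_equal(fdis_multi(emb, p), brute, tolerance = 1e-10)
  }
})

test_that("identical species give zero dispersion", {
  x <- matrix(5, 4, 3, dimnames = list(paste0("s", 1:4), paste0("t", 1:3)))
  d <- matrix(0, 4, 4, dimnames = dimnames(x)[c(1, 1)])
  expect_equal(fdis_multi(pcoa_embed(d), rep(0.25, 4)), 0)
  expect_equal(rao_q(d, rep(0.25, 4)), 0)
})

test_that("Rao's Q is the expected pairwise distance", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(rao_q(d, c(a = 0.5, b = 0.5)), 0.5)
  expect_equal(rao_q(d, c(a = 1, b = 0)), 0)
  expect_equal(rao_q(matrix(0, 1, 1, dimnames = list("a", "a")), c(a = 1)), 0)
})

test_that("duplicating a species with split abundance changes nothing", {
  set.seed(53)
  for (rep in 1:10) {
    cm <- random_community(sample(3:8, 1))
    n <- nrow(cm$x)
    p <- cm$p
    # duplicate the first species, split its abundance at a random ratio
    w <- runif(1)
    x2 <- rbind(cm$x[1, , drop = FALSE], cm$x)
    rownames(x2) <- c("dup", rownames(cm$x))
    p2 <- c(p[1] * w, p[1] * (1 - w), p[2:n])

    expect_equal(cwm(x2[, 1], p2), cwm(cm$x[, 1], p), tolerance = 1e-10)
    expect_equal(fdis_single(x2[, 1], p2), fdis_single(cm$x[, 1], p),
                 tolerance = 1e-10)
    rng <- apply(cm$x, 2, function(v) diff(range(v)))
    d1 <- gower_distance(cm$x, ranges = rng)
    d2 <- gower_distance(x2, ranges = rng)
    expect_equal(rao_q(d2, p2), rao_q(d1, p), tolerance = 1e-10)
    expect_equal(fdis_multi(pcoa_embed(d2), p2), fdis_multi(pcoa_embed(d1), p),
                 tolerance = 1e-10)
  }
})

test_that("CWM is bounded by contributing species and FDis/RaoQ are nonnegative", {
  set.seed(54)
  for (rep in 1:25) {
    cm <- random_community(sample(2:10, 1), n_traits = 2)
    v <- cm$x[, 1]
    m <- cwm(v, cm$p)
    expect_gte(m, min(v))
    expect_lte(m, max(v))
    expect_gte(fdis_single(v, cm$p), 0)
    d <- gower_distance(cm$x)
    expect_gte(rao_q(d, cm$p), 0)
    expect_lte(rao_q(d, cm$p), max(d))
  }
})

test_that("community_metrics matches hand computation on a two-species fixture", {
  traits <- tiny_traits()
  ab <- tiny_abundance(p1 = c(0.6, 0.4), p2 = c(0.3, 0.7))
  mt <- community_metrics(traits, ab, trait_mode = "specific")
  grab <- function(metric, year) {
    mt$value[mt$metric == metric & mt$year == year & mt$quadrat == "Q1"]
  }
  # 2013: SLA (10, 20) at p (0.6, 0.4)
  expect_equal(grab("CWM-SLA", 2013), 0.6 * 10 + 0.4 * 20)
  expect_equal(grab("FDis-SLA", 2013), 0.6 * 4 + 0.4 * 6)
  # 2014: SLA (14, 22) at p (0.3, 0.7)
  expect_equal(grab("CWM-SLA", 2014), 0.3 * 14 + 0.7 * 22, tolerance = 1e-12)
  # multi-FDis on two species = RaoQ on two species = 2 p1 p2 d; check vs hand
  # Gower d uses pooled ranges: SLA 10-22 -> range 12, etc.
  rng <- c(SLA = 12, LDMC = 100, LNC = 13, H = 20)
  x13 <- rbind(sp1 = c(10, 200, 15, 20), sp2 = c(20, 300, 25, 40))
  d13 <- mean(abs(x13[1, ] - x13[2, ]) / rng)
  expect_equal(grab("RaoQ", 2013), 2 * 0.6 * 0.4 * d13, tolerance = 1e-12)
  expect_equal(grab("multi-FDis", 2013),
               0.6 * (0.4 * d13) + 0.4 * (0.6 * d13), tolerance = 1e-12)
})

test_that("fixed mode equals specific mode when traits do not change", {
  traits <- as_trait_table(data.frame(
    grassland = "G1", year = rep(c(2013L, 2014L), each = 8),
    species = rep(rep(c("sp1", "sp2"), each = 4), 2),
    trait = rep(c("SLA", "LDMC", "LNC", "H"), 4),
    value = rep(c(10, 200, 15, 20, 20, 300, 25, 40), 2)))
  ab <- tiny_abundance()
  both <- community_metrics(traits, ab, trait_mode = "both")
  sp <- both[both$trait_mode == "specific", ]
  fx <- both[both$trait_mode == "fixed", ]
  key <- function(d) paste(d$quadrat, d$year, d$metric)
  expect_equal(fx$value[match(key(sp), key(fx))], sp$value)
})

test_that("a one-species community has zero dispersion and its own CWM", {
  traits <- as_trait_table(data.frame(
    grassland = "G1", year = 2013L, species = "sp1",
    trait = c("SLA", "LDMC", "LNC", "H"), value = c(10, 200, 15, 20)))
  ab <- as_abundance_table(data.frame(
    grassland = "G1", site = "S1", quadrat = "Q1", year = 2013L,
    species = "sp1", rel_biomass = 1))
  mt <- community_metrics(traits, ab, trait_mode = "specific")
  expect_equal(mt$value[mt$metric == "CWM-SLA"], 10)
  expect_true(all(mt$value[grepl("FDis|RaoQ", mt$metric)] == 0))
})

test_that("low-coverage samples yield NA metrics with a warning", {
  traits <- as_trait_table(data.frame(
    grassland = "G1", year = rep(c(2013L, 2014L), each = 4),
    species = "sp1", trait = rep(c("SLA", "LDMC", "LNC", "H"), 2),
    value = rep(c(10, 200, 15, 20), 2)))
  ab <- tiny_abundance(p1 = c(0.5, 0.5), p2 = c(0.5, 0.5))  # sp2 unmeasured
  expect_warning(mt <- community_metrics(traits, ab, trait_mode = "specific"),
                 "coverage")
  expect_true(all(is.na(mt$value)))
  mt2 <- community_metrics(traits, ab, trait_mode = "specific",
                           coverage_threshold = 0.4)
  expect_true(all(!is.na(mt2$value)))
})

test_that("multi-FDis modes reduce to scaled single-trait FDis on one trait", {
  d <- generate_scenario(simulation_scenario(n_grasslands = 1, n_species = 10),
                         seed = 55)
  g <- suppressMessages(
    community_metrics(d$traits, d$abundance, trait_mode = "specific",
                      distance = "gower", trait_names = "SLA"))
  e <- suppressMessages(
    community_metrics(d$traits, d$abundance, trait_mode = "specific",
                      distance = "euclidean", trait_names = "SLA"))
  # pooled specific SLA values over both years set the range and sd
  sla <- d$traits$value[d$traits$trait == "SLA"]
  key <- function(m) paste(m$site, m$quadrat, m$year)
  gm <- g[g$metric == "multi-FDis", ]
  gs <- g[g$metric == "FDis-SLA", ]
  expect_equal(gm$value, gs$value[match(key(gm), key(gs))] / diff(range(sla)),
               tolerance = 1e-10)
  em <- e[e$metric == "multi-FDis", ]
  es <- e[e$metric == "FDis-SLA", ]
  expect_equal(em$value, es$value[match(key(em), key(es))] / sd(sla),
               tolerance = 1e-10)
})
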