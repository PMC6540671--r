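# small in-code fixtures shared across test files

# two species, two years, one grassland; values chosen for hand computation
tiny_traits <- function() {
  as_trait_table(data.frame(
    grassland = "G1",
    year = rep(c(2013L, 2014L), each = 8),
    species = rep(rep(c("sp1", "sp2"), each = 4), 2),
    trait = rep(c("SLA", "LDMC", "LNC", "H"), 4),
    value = c(10, 200, 15, 20,   20, 300, 25, 40,    # 2013 sp1, sp2
              14, 220, 12, 20,   22, 280, 20, 40)))  # 2014 sp1, sp2
}

tiny_abundance <- function(p1 = c(0.6, 0.4), p2 = c(0.3, 0.7)) {
  rows <- expand.grid(quadrat = c("Q1", "Q2"), year = c(2013L, 2014L),
                      species = c("sp1", "sp2"), stringsAsFactors = FALSE)
  rows$grassland <- "G1"
  rows$site <- "S1"
  rows$rel_biomass <- ifelse(rows$year == 2013L,
                             p1[match(rows$species, c("sp1", "sp2"))],
                             p2[match(rows$species, c("sp1", "sp2"))])
  as_abundance_table(rows)
}

# random trait matrix + abundance vector for property-style loops
random_community <- function(n_species, n_traits = 3) {
  x <- matrix(stats::runif(n_species * n_traits, 1, 50), n_species, n_traits,
              dimnames = list(paste0("sp", seq_len(n_species)),
                              paste0("tr", seq_len(n_traits))))
  p <- stats::rgamma(n_species, 1)
  list(x = x, p = p / sum(p))
}

write_tmp_csv <- function(df, name = "tmp.csv") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
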