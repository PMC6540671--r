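# wide species x trait matrix for one grassland-year from a long trait table
trait_matrix_for <- function(completed, grassland, year, trait_names) {
  rec <- completed[completed$grassland == grassland & completed$year == year &
                     completed$trait %in% trait_names, , drop = FALSE]
  if (nrow(rec) == 0) return(NULL)
  sp <- sort(unique(rec$species))
  m <- matrix(NA_real_, length(sp), length(trait_names),
              dimnames = list(sp, trait_names))
  m[cbind(match(rec$species, sp), match(rec$trait, trait_names))] <- rec$value
  m
}

#' Community trait metrics per quadrat-year
#'
#' Computes, for every (grassland, site, quadrat, year) sample: CWM and
#' single-trait FDis for each trait, multi-trait FDis over the joint trait
#' space, and Rao's quadratic entropy. Under `trait_mode = "specific"`
#' species carry their year-specific trait values; under `"fixed"` they
#' carry the across-year average ([fixed_trait_table()]), so between-year
#' differences can only come from species turnover.
#'
#' Gower ranges (and z-score scalings) are computed per grassland over the
#' specific values of both years pooled, so that specific and fixed metrics
#' live in the same trait space. Abundances are renormalised over the
#' trait-covered species of each sample; samples whose covered biomass falls
#' below `coverage_threshold` get NA metrics with a warning.
#'
#' @param traits trait table ([as_trait_table()]).
#' @param abund abundance table ([as_abundance_table()]).
#' @param trait_mode `"specific"`, `"fixed"` or `"both"`.
#' @param distance trait space for multi-FDis and Rao's Q: `"gower"`
#'   (range-normalised, embedded by PCoA, the default) or `"euclidean"`
#'   (traits z-scored over the grassland pool, centroid computed directly) —
#'   the latter is a cross-checking mode.
#' @param trait_names traits to analyse; default all of the table's levels.
#' @param coverage_threshold minimum covered biomass fraction per sample.
#' @return data.frame `grassland, site, quadrat, year, metric, trait_mode,
#'   value` with class `metric_table`. Metrics are named `CWM-<trait>`,
#'   `FDis-<trait>`, `multi-FDis`, `RaoQ`.
#' @export
community_metrics <- function(traits, abund,
                              trait_mode = c("specific", "fixed", "both"),
                              distance = c("gower", "euclidean"),
                              trait_names = NULL,
                              coverage_threshold = 0.8) {
  trait_mode <- match.arg(trait_mode)
  distance <- match.arg(distance)
  stopifnot(inherits(traits, "trait_table"), inherits(abund, "abundance_table"))
  if (is.null(trait_names)) trait_names <- attr(traits, "trait_levels")
  modes <- if (trait_mode == "both") c("specific", "fixed") else trait_mode

  years <- sort(unique(abund$year))
  completed <- carry_over_traits(traits, years = years)
  fixed <- fixed_trait_table(traits)

  out <- list()
  low_coverage <- 0
  floored <- 0L
  for (g in unique(abund$grassland)) {
    ab_g <- abund[abund$grassland == g, , drop = FALSE]
    # pooled specific values of both years define the grassland trait space
    pool <- completed[completed$grassland == g &
                        completed$trait %in% trait_names, , drop = FALSE]
    ranges <- tapply(pool$value, factor(pool$trait, levels = trait_names),
                     function(v) diff(range(v)))
    sds <- tapply(pool$value, factor(pool$trait, levels = trait_names),
                  stats::sd)
    means <- tapply(pool$value, factor(pool$trait, levels = trait_names), mean)

    mats <- list()
    for (y in years) {
      mats[[paste("specific", y)]] <- trait_matrix_for(completed, g, y, trait_names)
      fx <- fixed[fixed$grassland == g, , drop = FALSE]
      if (nrow(fx) > 0) {
        fx$year <- y
        mats[[paste("fixed", y)]] <- trait_matrix_for(fx, g, y, trait_names)
      }
    }

    samples <- unique(ab_g[, c("site", "quadrat", "year")])
    for (r in seq_len(nrow(samples))) {
      sel <- ab_g$site == samples$site[r] & ab_g$quadrat == samples$quadrat[r] &
        ab_g$year == samples$year[r]
      p_all <- stats::setNames(ab_g$rel_biomass[sel], ab_g$species[sel])
      for (mode in modes) {
        m <- mats[[paste(mode, samples$year[r])]]
        present <- names(p_all)[p_all > 0]
        covered <- if (is.null(m)) character() else {
          intersect(present, rownames(m)[stats::complete.cases(m)])
        }
        coverage <- sum(p_all[covered]) / sum(p_all)
        metric_names <- c(paste0("CWM-", trait_names),
                          paste0("FDis-", trait_names), "multi-FDis", "RaoQ")
        if (length(covered) == 0 || coverage < coverage_threshold) {
          low_coverage <- low_coverage + 1
          vals <- rep(NA_real_, length(metric_names))
        } else {
          p <- p_all[covered] / sum(p_all[covered])
          x <- m[covered, , drop = FALSE]
          vals <- numeric(0)
          for (tr in trait_names) vals <- c(vals, cwm(x[, tr], p))
          for (tr in trait_names) vals <- c(vals, fdis_single(x[, tr], p))
          if (length(covered) == 1) {
            vals <- c(vals, 0, 0)
          } else if (distance == "gower") {
            d <- gower_distance(x, ranges = ranges)
            emb <- pcoa_embed(d)
            # collect the flooring warnings of non-Euclidean communities into
            # one counter instead of one warning per quadrat
            fd <- withCallingHandlers(
              fdis_multi(emb, p),
              warning = function(w) {
                if (grepl("floored", conditionMessage(w))) {
                  floored <<- floored + 1L
                  invokeRestart("muffleWarning")
                }
              })
            vals <- c(vals, fd, rao_q(d, p))
          } else {
            z <- sweep(sweep(x, 2, means), 2, sds, "/")
            cz <- colSums(z * p)
            dist_to_c <- sqrt(rowSums(sweep(z, 2, cz)^2))
            d <- as.matrix(stats::dist(z))
            vals <- c(vals, sum(p * dist_to_c), rao_q(d, p))
          }
        }
        out[[length(out) + 1]] <- data.frame(
          grassland = g, site = samples$site[r], quadrat = samples$quadrat[r],
          year = samples$year[r], metric = metric_names, trait_mode = mode,
          value = vals, stringsAsFactors = FALSE)
      }
    }
  }
  if (low_coverage > 0) {
    warning(low_coverage, " sample/mode combination(s) below the coverage ",
            "threshold; their metrics are NA")
  }
  if (floored > 0) {
    message("multi-FDis: floored small negative squared distances in ",
            floored, " communities (non-Euclidean Gower space)")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("metric_table", "data.frame")
  res
}
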