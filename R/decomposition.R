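#' Fixed (across-year average) trait table
#'
#' A species' fixed trait value in a grassland is the unweighted mean of its
#' specific (per-year) values over the years in which it was measured there;
#' a species measured in one year keeps that value. Community metrics
#' computed from fixed traits can differ between years only through species
#' turnover.
#'
#' @param traits trait table.
#' @return data.frame `grassland, species, trait, value, n_years` with class
#'   `fixed_trait_table`.
#' @export
fixed_trait_table <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  df <- as.data.frame(traits)
  agg <- stats::aggregate(value ~ grassland + species + trait, data = df,
                          FUN = mean)
  n <- stats::aggregate(value ~ grassland + species + trait, data = df,
                        FUN = length)
  agg$n_years <- n$value
  agg <- agg[order(agg$grassland, agg$species, agg$trait), ]
  rownames(agg) <- NULL
  attr(agg, "trait_levels") <- attr(traits, "trait_levels")
  class(agg) <- c("fixed_trait_table", "data.frame")
  agg
}

#' One-way ANOVA sums of squares
#'
#' Between-group ("explained") and residual sums of squares with the F test
#' of the group effect: `SS_effect = sum_g n_g (ybar_g - ybar)^2`,
#' `SS_residual = sum within-group squared deviations`,
#' `F = (SS_effect / (a-1)) / (SS_residual / (N-a))`.
#'
#' @param y numeric response values.
#' @param groups factor (or coercible) of group labels, >= 2 levels, each
#'   with >= 2 observations.
#' @return list `ss_effect, ss_residual, df_effect, df_residual, f, p`.
#' @export
explained_ss <- function(y, groups) {
  groups <- factor(groups)
  if (length(y) != length(groups)) {
    stop("explained_ss: y and groups must have equal length", call. = FALSE)
  }
  ok <- !is.na(y)
  y <- y[ok]
  groups <- droplevels(groups[ok])
  a <- nlevels(groups)
  n <- length(y)
  if (a < 2) stop("factor error: need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("factor error: every group needs at least 2 observations", call. = FALSE)
  }
  gm <- tapply(y, groups, mean)
  ng <- tabulate(groups)
  grand <- mean(y)
  ss_effect <- sum(ng * (gm - grand)^2)
  ss_residual <- sum((y - gm[groups])^2)
  df1 <- a - 1
  df2 <- n - a
  f <- if (ss_residual > 0) {
    (ss_effect / df1) / (ss_residual / df2)
  } else if (ss_effect > 0) Inf else 0
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(ss_effect = ss_effect, ss_residual = ss_residual,
       df_effect = df1, df_residual = df2, f = f, p = p)
}

#' Decompose the between-year variation of one community metric
#'
#' Splits the between-year sum of squares of a metric computed with specific
#' (year-measured) traits into the part reproduced with fixed traits (species
#' turnover), the part carried by the specific-minus-fixed difference
#' (intraspecific trait variability), and the covariation remainder:
#' `SS_cov = SS_specific - SS_fixed - SS_intra`. A positive covariation
#' means turnover and intraspecific shifts push the metric the same way
#' between years; a negative one means they oppose.
#'
#' @param specific per-sample metric values under specific traits.
#' @param fixed per-sample metric values under fixed traits, same samples in
#'   the same order.
#' @param groups per-sample year labels.
#' @return object of class `trait_decomposition`: the four SS terms, shares
#'   of `ss_specific` (shares sum to 1; `share_cov` may be negative), and
#'   the F/p of the year effect on the specific, fixed and intraspecific
#'   series.
#' @export
decompose_metric <- function(specific, fixed, groups) {
  if (length(specific) != length(fixed) || length(specific) != length(groups)) {
    stop("alignment error: specific, fixed and groups must describe the same samples",
         call. = FALSE)
  }
  if (anyNA(specific) != anyNA(fixed) ||
      (anyNA(specific) && !identical(which(is.na(specific)), which(is.na(fixed))))) {
    stop("alignment error: specific and fixed have NA at different samples",
         call. = FALSE)
  }
  intra <- specific - fixed
  a_spec <- explained_ss(specific, groups)
  a_fix <- explained_ss(fixed, groups)
  a_intra <- explained_ss(intra, groups)
  ss_cov <- a_spec$ss_effect - a_fix$ss_effect - a_intra$ss_effect
  shares <- if (a_spec$ss_effect > 0) {
    c(fixed = a_fix$ss_effect, intra = a_intra$ss_effect,
      cov = ss_cov) / a_spec$ss_effect
  } else {
    c(fixed = NA_real_, intra = NA_real_, cov = NA_real_)
  }
  structure(list(
    ss_specific = a_spec$ss_effect, ss_fixed = a_fix$ss_effect,
    ss_intra = a_intra$ss_effect, ss_cov = ss_cov, shares = shares,
    f_specific = a_spec$f, p_specific = a_spec$p,
    f_fixed = a_fix$f, p_fixed = a_fix$p,
    f_intra = a_intra$f, p_intra = a_intra$p,
    n = sum(!is.na(specific))), class = "trait_decomposition")
}

#' @export
print.trait_decomposition <- function(x, ...) {
  cat("Between-year decomposition of one community metric\n")
  cat(sprintf("  SS specific: %.6g (F = %.3f, p = %.4g)\n",
              x$ss_specific, x$f_specific, x$p_specific))
  cat(sprintf("  SS fixed (turnover):       %.6g  share %6.1f%%\n",
              x$ss_fixed, 100 * x$shares["fixed"]))
  cat(sprintf("  SS intraspecific:          %.6g  share %6.1f%%\n",
              x$ss_intra, 100 * x$shares["intra"]))
  cat(sprintf("  SS covariation:            %.6g  share %6.1f%%\n",
              x$ss_cov, 100 * x$shares["cov"]))
  invisible(x)
}

#' Decompose every metric of a dataset, per grassland
#'
#' Runs [community_metrics()] under both trait modes, aligns the specific
#' and fixed per-sample series of every (grassland, metric), and applies
#' [decompose_metric()] with year as the factor. By default only metrics
#' whose specific series shows a significant year effect (p < `alpha`) are
#' decomposed — the others keep their test columns and NA components.
#'
#' @param traits trait table.
#' @param abund abundance table.
#' @param metrics metric names to decompose; default all computed metrics.
#' @param unit replication unit for the year ANOVA: `"quadrat"` (default) or
#'   `"site"` (quadrats averaged per site first).
#' @param alpha significance level for the year effect gate.
#' @param only_significant decompose only significant metrics (default TRUE).
#' @param ... passed to [community_metrics()] (`distance`, `trait_names`,
#'   `coverage_threshold`).
#' @return data.frame: one row per grassland x metric with n, the four SS
#'   terms, shares, F/p per series and a `decomposed` flag.
#' @export
decompose_dataset <- function(traits, abund, metrics = NULL,
                              unit = c("quadrat", "site"), alpha = 0.05,
                              only_significant = TRUE, ...) {
  unit <- match.arg(unit)
  mt <- community_metrics(traits, abund, trait_mode = "both", ...)
  if (is.null(metrics)) metrics <- unique(mt$metric)

  if (unit == "site") {
    mt <- stats::aggregate(value ~ grassland + site + year + metric + trait_mode,
                           data = mt, FUN = mean, na.action = stats::na.pass)
    mt$quadrat <- "site-mean"
  }
  mt$sample <- paste(mt$site, mt$quadrat, mt$year, sep = "/")

  rows <- list()
  for (g in unique(mt$grassland)) {
    for (m in metrics) {
      sel <- mt$grassland == g & mt$metric == m
      sp <- mt[sel & mt$trait_mode == "specific", , drop = FALSE]
      fx <- mt[sel & mt$trait_mode == "fixed", , drop = FALSE]
      fx <- fx[match(sp$sample, fx$sample), , drop = FALSE]
      ok <- !is.na(sp$value) & !is.na(fx$value)
      year_test <- explained_ss(sp$value[ok], sp$year[ok])
      significant <- is.finite(year_test$p) && year_test$p < alpha
      base <- data.frame(grassland = g, metric = m, n = sum(ok),
                         f_specific = year_test$f, p_specific = year_test$p,
                         decomposed = FALSE, ss_specific = NA_real_,
                         ss_fixed = NA_real_, ss_intra = NA_real_,
                         ss_cov = NA_real_, share_fixed = NA_real_,
                         share_intra = NA_real_, share_cov = NA_real_,
                         f_fixed = NA_real_, p_fixed = NA_real_,
                         f_intra = NA_real_, p_intra = NA_real_,
                         stringsAsFactors = FALSE)
      if (significant || !only_significant) {
        dec <- decompose_metric(sp$value[ok], fx$value[ok], sp$year[ok])
        base$decomposed <- TRUE
        base$ss_specific <- dec$ss_specific
        base$ss_fixed <- dec$ss_fixed
        base$ss_intra <- dec$ss_intra
        base$ss_cov <- dec$ss_cov
        base$share_fixed <- dec$shares["fixed"]
        base$share_intra <- dec$shares["intra"]
        base$share_cov <- dec$shares["cov"]
        base$f_fixed <- dec$f_fixed
        base$p_fixed <- dec$p_fixed
        base$f_intra <- dec$f_intra
        base$p_intra <- dec$p_intra
      }
      rows[[length(rows) + 1]] <- base
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
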