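#' Sample-by-species abundance matrix
#'
#' Reshapes an abundance table into the wide matrix form used by
#' dissimilarity computations, optionally restricted to one grassland
#' (samples from different grasslands share no species, so restricting is
#' the usual scope). Row names are `grassland/site/quadrat/year`; the
#' per-row year labels are attached as attribute `groups`.
#'
#' @param abund abundance table.
#' @param grassland optional grassland id to restrict to.
#' @return numeric samples x species matrix with attribute `groups`.
#' @export
abundance_matrix <- function(abund, grassland = NULL) {
  stopifnot(inherits(abund, "abundance_table"))
  if (!is.null(grassland)) {
    abund <- abund[abund$grassland %in% grassland, , drop = FALSE]
    if (nrow(abund) == 0) stop("lookup error: no samples for grassland ",
                               grassland, call. = FALSE)
  }
  id <- sample_id(abund)
  ids <- unique(id)
  sp <- sort(unique(abund$species))
  m <- matrix(0, length(ids), length(sp), dimnames = list(ids, sp))
  m[cbind(match(id, ids), match(abund$species, sp))] <- abund$rel_biomass
  attr(m, "groups") <- abund$year[match(ids, id)]
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 * sum(min(x_s, y_s)) / sum(x_s + y_s)` over the shared
#' species universe (absences count as zero). Computed with
#' [vegan::vegdist()].
#'
#' @param x samples x species non-negative matrix (e.g. from
#'   [abundance_matrix()]), or an abundance table, in which case `...` is
#'   passed to [abundance_matrix()].
#' @param ... passed to [abundance_matrix()] when `x` is an abundance table.
#' @return symmetric samples x samples matrix in [0, 1]; attribute `groups`
#'   is carried over when present.
#' @export
bray_curtis_matrix <- function(x, ...) {
  if (inherits(x, "abundance_table")) x <- abundance_matrix(x, ...)
  x <- as.matrix(x)
  if (any(x < 0)) stop("bray_curtis_matrix: abundances must be >= 0", call. = FALSE)
  if (any(rowSums(x) == 0)) {
    stop("undefined-distance error: sample(s) with all-zero abundances: ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "), call. = FALSE)
  }
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  attr(d, "groups") <- attr(x, "groups")
  d
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix (Anderson's distance-based sums of squares):
#' `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_residual = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `SS_effect = SS_total - SS_residual`, with
#' `pseudo-F = (SS_effect / (a-1)) / (SS_residual / (N-a))`. The p-value is
#' `(#{permuted F >= observed} + 1) / (n_permutations + 1)` under uniform
#' random relabelling of the samples.
#'
#' @param d symmetric dissimilarity matrix or `dist`.
#' @param groups factor of group labels, one per sample; taken from
#'   `attr(d, "groups")` when omitted. Every group needs >= 2 samples.
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the permutations (required: the analysis
#'   pipeline demands reproducible p-values).
#' @return object of class `permanova_result` with df, SS, MS, pseudo-F,
#'   R2, p, `n_permutations` and `seed`.
#' @export
permanova <- function(d, groups = NULL, n_permutations = 999, seed) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (is.null(groups)) groups <- attr(d, "groups")
  if (is.null(groups)) stop("permanova: group labels required", call. = FALSE)
  groups <- factor(groups)
  n <- nrow(d)
  if (length(groups) != n) {
    stop("permanova: one group label per sample required", call. = FALSE)
  }
  if (n < 4) stop("design error: need at least 4 samples", call. = FALSE)
  a <- nlevels(groups)
  if (a < 2) stop("design error: need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("design error: every group needs at least 2 samples", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("permanova: a seed is required for reproducible permutations",
         call. = FALSE)
  }

  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  ng <- as.integer(table(groups))
  idx <- split(seq_len(n), groups)
  ss_within <- function(index_list) {
    s <- 0
    for (k in seq_along(index_list)) {
      i <- index_list[[k]]
      s <- s + sum(d2[i, i]) / (2 * length(i))
    }
    s
  }
  ss_residual <- ss_within(idx)
  ss_effect <- ss_total - ss_residual
  df1 <- a - 1L
  df2 <- n - a
  f_obs <- (ss_effect / df1) / (ss_residual / df2)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  count <- 0L
  labels <- as.integer(groups)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    idx_b <- split(perm, labels)
    ss_res_b <- ss_within(idx_b)
    f_b <- ((ss_total - ss_res_b) / df1) / (ss_res_b / df2)
    if (f_b >= f_obs - 1e-12 * abs(f_obs)) count <- count + 1L
  }
  p <- (count + 1) / (n_permutations + 1)

  structure(list(df_effect = df1, df_residual = df2,
                 ss_effect = ss_effect, ss_residual = ss_residual,
                 ss_total = ss_total,
                 ms_effect = ss_effect / df1, ms_residual = ss_residual / df2,
                 pseudo_f = f_obs, r2 = ss_effect / ss_total, p = p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (one-way)\n")
  tab <- data.frame(
    Df = c(x$df_effect, x$df_residual, x$df_effect + x$df_residual),
    SumOfSqs = c(x$ss_effect, x$ss_residual, x$ss_total),
    MeanSqs = c(x$ms_effect, x$ms_residual, NA),
    F = c(x$pseudo_f, NA, NA),
    R2 = c(x$r2, 1 - x$r2, 1),
    p = c(x$p, NA, NA),
    row.names = c("Groups", "Residual", "Total"))
  print(round(tab, 4))
  cat(sprintf("%d permutations, seed %d\n", x$n_permutations, x$seed))
  invisible(x)
}
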