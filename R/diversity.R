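# abundance weights: drop NA trait entries, renormalise over the rest
weights_over <- function(values, p) {
  if (length(values) != length(p)) {
    stop("values and abundances must have equal length", call. = FALSE)
  }
  if (any(p < 0)) stop("abundances must be >= 0", call. = FALSE)
  ok <- !is.na(values) & p > 0
  if (!any(ok)) {
    stop("undefined metric: no species with both trait values and abundance",
         call. = FALSE)
  }
  s <- sum(p[ok])
  if (s <= 0) stop("undefined metric: total abundance is zero", call. = FALSE)
  list(values = values[ok], p = p[ok] / s)
}

#' Community-weighted mean of a trait
#'
#' `CWM = sum(p_i * x_i)` with relative abundances renormalised over the
#' species that have a trait value.
#'
#' @param values per-species trait values (NA = not measured).
#' @param p per-species relative abundances, >= 0.
#' @return the weighted mean.
#' @export
cwm <- function(values, p) {
  w <- weights_over(values, p)
  sum(w$p * w$values)
}

#' Single-trait functional dispersion
#'
#' Abundance-weighted mean absolute distance of species to the
#' abundance-weighted community mean of one trait:
#' `FDis = sum(p_i * |x_i - CWM|)`.
#'
#' @inheritParams cwm
#' @return FDis, >= 0, in trait units.
#' @export
fdis_single <- function(values, p) {
  w <- weights_over(values, p)
  centroid <- sum(w$p * w$values)
  sum(w$p * abs(w$values - centroid))
}

#' Multi-trait functional dispersion from a trait-space embedding
#'
#' Abundance-weighted mean distance of species to the abundance-weighted
#' centroid in the principal-coordinates space. With non-Euclidean (e.g.
#' Gower) distances, squared distances are the real part minus the
#' imaginary part; small negative squared distances are floored at zero
#' with a warning.
#'
#' @param embedding a [pcoa_embed()] result.
#' @param p relative abundances, named by species or aligned with
#'   `embedding$labels`; renormalised over embedded species with p > 0.
#' @return FDis, >= 0.
#' @export
fdis_multi <- function(embedding, p) {
  stopifnot(inherits(embedding, "trait_space_embedding"))
  if (!is.null(names(p))) {
    if (!all(names(p) %in% embedding$labels)) {
      stop("fdis_multi: abundances name species missing from the embedding",
           call. = FALSE)
    }
    full <- stats::setNames(numeric(length(embedding$labels)), embedding$labels)
    full[names(p)] <- p
    p <- full
  }
  if (length(p) != length(embedding$labels)) {
    stop("fdis_multi: abundance vector does not match the embedding",
         call. = FALSE)
  }
  if (any(p < 0)) stop("abundances must be >= 0", call. = FALSE)
  if (sum(p) <= 0) {
    stop("undefined metric: empty community", call. = FALSE)
  }
  p <- p / sum(p)
  xr <- embedding$coordinates
  xi <- embedding$imaginary_coordinates
  cr <- colSums(xr * p)
  d2 <- rowSums(sweep(xr, 2, cr)^2)
  if (ncol(xi) > 0) {
    ci <- colSums(xi * p)
    d2 <- d2 - rowSums(sweep(xi, 2, ci)^2)
  }
  scale <- max(abs(d2), 1e-300)
  n_floored <- sum(d2 < -1e-12 * scale)
  if (n_floored > 0) {
    warning("fdis_multi: ", n_floored,
            " negative squared distance(s) floored at 0 (imaginary axes dominate)")
  }
  sum(p * sqrt(pmax(d2, 0)))
}

#' Rao's quadratic entropy
#'
#' Expected trait distance between two individuals drawn at random with
#' replacement: `Q = sum_i sum_j p_i p_j d(i, j)`.
#'
#' @param d symmetric species x species distance matrix.
#' @param p relative abundances named by species (or aligned with the rows
#'   of `d`); renormalised.
#' @return Q, >= 0.
#' @export
rao_q <- function(d, p) {
  d <- as.matrix(d)
  if (!is.null(names(p)) && !is.null(rownames(d))) {
    if (!all(names(p) %in% rownames(d))) {
      stop("rao_q: abundances name species missing from the distance matrix",
           call. = FALSE)
    }
    full <- stats::setNames(numeric(nrow(d)), rownames(d))
    full[names(p)] <- p
    p <- full
  }
  if (length(p) != nrow(d)) {
    stop("rao_q: abundance vector does not match the distance matrix",
         call. = FALSE)
  }
  if (any(p < 0) || sum(p) <= 0) {
    stop("rao_q: abundances must be >= 0 with positive total", call. = FALSE)
  }
  p <- p / sum(p)
  as.numeric(t(p) %*% d %*% p)
}
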