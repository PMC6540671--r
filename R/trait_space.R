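#' Gower distance between species in trait space
#'
#' For quantitative traits, the Gower dissimilarity between two species is
#' the mean over traits of `|x_i - x_j| / range_t`. Ranges default to the
#' ranges observed in the supplied matrix, but should normally be supplied
#' from the full species pool under analysis so that communities share one
#' trait space.
#'
#' @param trait_matrix numeric matrix, species (rows, named) x traits (columns).
#' @param ranges named positive per-trait ranges; defaults to column ranges
#'   of `trait_matrix`.
#' @param drop_degenerate with the default FALSE a zero-range trait is an
#'   error; with TRUE it is dropped with a warning.
#' @return symmetric species x species matrix with zero diagonal and
#'   entries in [0, 1].
#' @export
gower_distance <- function(trait_matrix, ranges = NULL, drop_degenerate = FALSE) {
  trait_matrix <- as.matrix(trait_matrix)
  if (anyNA(trait_matrix)) {
    stop("gower_distance: missing trait entries are not supported", call. = FALSE)
  }
  if (is.null(ranges)) {
    ranges <- apply(trait_matrix, 2, function(v) diff(range(v)))
  }
  ranges <- ranges[colnames(trait_matrix)]
  zero <- !is.finite(ranges) | ranges <= 0
  if (any(zero)) {
    if (!drop_degenerate) {
      stop("gower_distance: degenerate trait(s) with zero range: ",
           paste(colnames(trait_matrix)[zero], collapse = ", "), call. = FALSE)
    }
    warning("gower_distance: dropping degenerate trait(s): ",
            paste(colnames(trait_matrix)[zero], collapse = ", "))
    trait_matrix <- trait_matrix[, !zero, drop = FALSE]
    ranges <- ranges[!zero]
    if (ncol(trait_matrix) == 0) {
      stop("gower_distance: no non-degenerate traits left", call. = FALSE)
    }
  }
  n <- nrow(trait_matrix)
  d <- matrix(0, n, n, dimnames = list(rownames(trait_matrix),
                                       rownames(trait_matrix)))
  for (t in seq_len(ncol(trait_matrix))) {
    x <- trait_matrix[, t]
    d <- d + abs(outer(x, x, "-")) / ranges[t]
  }
  d / ncol(trait_matrix)
}

#' Principal coordinates embedding of a distance matrix
#'
#' Classical scaling: the doubly centred matrix of `-d^2 / 2` is
#' eigen-decomposed; axes with positive eigenvalues give real coordinates
#' and axes with negative eigenvalues (non-Euclidean distances) give
#' "imaginary" coordinates whose squared distances subtract. Eigenvalues
#' numerically indistinguishable from zero are dropped.
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal.
#' @param tol absolute eigenvalue threshold below which an axis is dropped;
#'   scaled up with the matrix when its largest eigenvalue exceeds 1.
#' @return object of class `trait_space_embedding` with elements
#'   `coordinates` (n x k_pos), `imaginary_coordinates` (n x k_neg),
#'   `eigenvalues` (all retained, descending) and `labels`.
#' @export
pcoa_embed <- function(d, tol = 1e-10) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12) {
    stop("pcoa_embed: distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 2) stop("pcoa_embed: need at least 2 species", call. = FALSE)
  a <- -0.5 * d^2
  # double centering: G = (I - 11'/n) A (I - 11'/n)
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  cut <- max(tol, tol * max(abs(e$values)))
  keep <- abs(e$values) > cut
  values <- e$values[keep]
  vectors <- e$vectors[, keep, drop = FALSE]
  pos <- values > 0
  coords <- vectors[, pos, drop = FALSE] %*% diag(sqrt(values[pos]),
                                                  nrow = sum(pos))
  icoords <- vectors[, !pos, drop = FALSE] %*% diag(sqrt(-values[!pos]),
                                                    nrow = sum(!pos))
  rownames(coords) <- rownames(icoords) <- rownames(d)
  structure(list(coordinates = coords, imaginary_coordinates = icoords,
                 eigenvalues = values, labels = rownames(d)),
            class = "trait_space_embedding")
}

#' @export
print.trait_space_embedding <- function(x, ...) {
  cat(sprintf(
    "Trait-space embedding: %d species, %d real + %d imaginary axes\n",
    length(x$labels), ncol(x$coordinates), ncol(x$imaginary_coordinates)))
  invisible(x)
}
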