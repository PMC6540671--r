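#' Fit a tussock volume-to-biomass allometry
#'
#' Least-squares fit of aboveground dry mass on tussock volume, either
#' linear (`mass = a + b * volume`) or power (`mass = a * volume^b`, fitted
#' as a log-log linear model). Power is the default: plant allometries are
#' typically multiplicative.
#'
#' @param volumes tussock volumes, m3 (> 0).
#' @param masses harvested dry masses, g (> 0 for the power form).
#' @param form `"power"` or `"linear"`.
#' @return object of class `tussock_allometry`: form, coefficients,
#'   `r_squared`, `n` and the fitted volume range.
#' @export
fit_tussock_allometry <- function(volumes, masses, form = c("power", "linear")) {
  form <- match.arg(form)
  if (length(volumes) != length(masses)) {
    stop("fit error: volumes and masses must have equal length", call. = FALSE)
  }
  if (length(volumes) < 3) {
    stop("fit error: need at least 3 calibration tussocks", call. = FALSE)
  }
  if (any(volumes <= 0)) {
    stop("domain error: tussock volumes must be positive", call. = FALSE)
  }
  if (form == "power" && any(masses <= 0)) {
    stop("domain error: power-form fit needs positive masses", call. = FALSE)
  }
  if (form == "linear") {
    fit <- stats::lm(masses ~ volumes)
    coefs <- c(intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]))
    r2 <- suppressWarnings(summary(fit)$r.squared)
    pred_range <- coefs["intercept"] + coefs["slope"] * range(volumes)
    if (any(pred_range < 0)) {
      warning("linear allometry predicts negative mass inside the fitted volume range")
    }
  } else {
    fit <- stats::lm(log(masses) ~ log(volumes))
    coefs <- c(scale = unname(exp(stats::coef(fit)[1])),
               exponent = unname(stats::coef(fit)[2]))
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  structure(list(form = form, coefficients = coefs, r_squared = r2,
                 n = length(volumes), volume_range = range(volumes)),
            class = "tussock_allometry")
}

#' @export
print.tussock_allometry <- function(x, ...) {
  eqn <- if (x$form == "linear") {
    sprintf("mass = %.4g + %.4g * volume", x$coefficients["intercept"],
            x$coefficients["slope"])
  } else {
    sprintf("mass = %.4g * volume^%.4g", x$coefficients["scale"],
            x$coefficients["exponent"])
  }
  cat(sprintf("Tussock allometry (%s): %s  [R2 = %.4f, n = %d]\n",
              x$form, eqn, x$r_squared, x$n))
  invisible(x)
}

#' Predict tussock mass from volume
#'
#' @param object fitted `tussock_allometry`.
#' @param volumes tussock volumes, m3.
#' @param ... unused.
#' @return predicted dry masses, g.
#' @export
predict.tussock_allometry <- function(object, volumes, ...) {
  cf <- object$coefficients
  if (object$form == "linear") {
    cf["intercept"] + cf["slope"] * volumes
  } else {
    cf["scale"] * volumes^cf["exponent"]
  }
}

#' Construct a two-layer quadrat survey
#'
#' Field record for one large quadrat of a two-layer grassland: the tall
#' tussock layer is described by the projected area and height of every
#' tussock; the understory by its total biomass density and a per-species
#' breakdown, both from inner 1 x 1 m quadrats.
#'
#' @param quadrat_area area of the large quadrat, m2 (25 for 5 x 5 m).
#' @param tussock_area projected areas of the tussocks, m2 (may be empty).
#' @param tussock_height tussock heights, m (same length).
#' @param understory_biomass total understory biomass density B_o, g/m2.
#' @param understory_species_biomass named numeric vector: per-species
#'   understory biomass densities B_i, g/m2; must sum to at most B_o
#'   (equality when every species was recorded).
#' @return object of class `tussock_survey`.
#' @export
tussock_survey <- function(quadrat_area = 25, tussock_area = numeric(),
                           tussock_height = numeric(), understory_biomass,
                           understory_species_biomass) {
  if (length(tussock_area) != length(tussock_height)) {
    stop("survey error: tussock_area and tussock_height lengths differ",
         call. = FALSE)
  }
  if (any(tussock_area < 0) || any(tussock_height < 0) ||
      understory_biomass < 0 || any(understory_species_biomass < 0)) {
    stop("survey error: areas, heights and biomasses must be >= 0", call. = FALSE)
  }
  if (is.null(names(understory_species_biomass)) ||
      any(names(understory_species_biomass) == "")) {
    stop("survey error: understory_species_biomass must be named by species",
         call. = FALSE)
  }
  a_asp <- sum(tussock_area)
  if (a_asp > quadrat_area) {
    stop("geometry error: summed tussock area exceeds the quadrat area",
         call. = FALSE)
  }
  s <- sum(understory_species_biomass)
  if (s > understory_biomass * (1 + 1e-6)) {
    stop("survey error: per-species understory biomass exceeds the total B_o",
         call. = FALSE)
  }
  structure(list(quadrat_area = quadrat_area, tussock_area = tussock_area,
                 tussock_height = tussock_height,
                 understory_biomass = understory_biomass,
                 understory_species_biomass = understory_species_biomass),
            class = "tussock_survey")
}

#' Total and tussock-layer biomass of a two-layer quadrat
#'
#' Each tussock's volume is its projected area times its height (a cylinder;
#' `shape_factor` rescales to other solids), fed through the allometry to
#' give the layer total B_Asp. Quadrat total follows
#' `B_t = (A_t - A_Asp) * B_o + B_Asp`.
#'
#' @param survey a [tussock_survey()].
#' @param model fitted [fit_tussock_allometry()] model; may be NULL when the
#'   survey has no tussocks.
#' @param shape_factor multiplier on area x height for non-cylindrical
#'   tussock shapes (default 1).
#' @return list with `b_asp` (tussock layer, g) and `b_t` (quadrat total, g).
#' @export
tussock_layer_biomass <- function(survey, model = NULL, shape_factor = 1) {
  stopifnot(inherits(survey, "tussock_survey"))
  a_asp <- sum(survey$tussock_area)
  if (length(survey$tussock_area) == 0) {
    b_asp <- 0
  } else {
    stopifnot(inherits(model, "tussock_allometry"))
    volumes <- survey$tussock_area * survey$tussock_height * shape_factor
    b_asp <- sum(predict(model, volumes))
  }
  b_t <- (survey$quadrat_area - a_asp) * survey$understory_biomass + b_asp
  list(b_asp = b_asp, b_t = b_t)
}

#' Relative aboveground biomass of every species in a two-layer quadrat
#'
#' `p_Asp = B_Asp / B_t` for the tussock species and
#' `p_i = (A_t - A_Asp) * B_i / B_t` for each understory species. When the
#' per-species understory densities sum to B_o, the returned fractions sum
#' to 1 exactly.
#'
#' @param survey a [tussock_survey()].
#' @param b_asp tussock-layer biomass, g (from [tussock_layer_biomass()]).
#' @param b_t quadrat total biomass, g.
#' @param tussock_species name used for the tussock species in the result.
#' @return named numeric vector of relative biomass fractions.
#' @export
relative_biomass <- function(survey, b_asp, b_t,
                             tussock_species = "A.splendens") {
  stopifnot(inherits(survey, "tussock_survey"))
  if (b_t <= 0) stop("division error: total biomass B_t must be > 0", call. = FALSE)
  open_area <- survey$quadrat_area - sum(survey$tussock_area)
  p <- open_area * survey$understory_species_biomass / b_t
  p_asp <- b_asp / b_t
  out <- c(p_asp, p)
  names(out) <- c(tussock_species, names(survey$understory_species_biomass))
  out
}
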