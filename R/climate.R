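#' Holdridge bio-temperature
#'
#' Mean of a temperature series after clipping every value into the
#' Holdridge bio-temperature band of 0 to 30 degrees C (temperatures at
#' which plants do not grow count as zero). A scalar period mean that is
#' already inside the band is returned unchanged.
#'
#' @param daily_temps numeric vector of temperatures (degrees C); a daily
#'   series or a single period mean.
#' @return mean bio-temperature, degrees C.
#' @export
bio_temperature <- function(daily_temps) {
  if (length(daily_temps) == 0 || !is.numeric(daily_temps) || anyNA(daily_temps)) {
    stop("bio_temperature: need a non-empty numeric temperature series",
         call. = FALSE)
  }
  mean(pmin(pmax(daily_temps, 0), 30))
}

#' Holdridge potential evapotranspiration over a period
#'
#' PET (mm) = 58.93 x (period_days / year_days) x mean bio-temperature.
#' The annual constant 58.93 mm per degree C is scaled by the fraction of the
#' year the period covers.
#'
#' @param mean_biotemp mean bio-temperature of the period, degrees C
#'   (clip raw temperatures first via [bio_temperature()]).
#' @param period_days length of the period in days.
#' @param year_days days in the year the period belongs to (365 or 366).
#' @return PET in mm.
#' @export
holdridge_pet <- function(mean_biotemp, period_days, year_days = 365) {
  if (any(mean_biotemp < 0)) {
    stop("holdridge_pet: mean bio-temperature must be >= 0 (clip via bio_temperature)",
         call. = FALSE)
  }
  if (any(period_days < 1) || any(period_days > year_days)) {
    stop("holdridge_pet: need 1 <= period_days <= year_days", call. = FALSE)
  }
  58.93 * (period_days / year_days) * mean_biotemp
}

#' Aridity index
#'
#' Ratio of potential evapotranspiration to precipitation over the same
#' period. Higher values indicate a more arid environment.
#'
#' @param pet potential evapotranspiration, mm.
#' @param precipitation precipitation over the same period, mm; must be > 0.
#' @return dimensionless aridity index.
#' @export
aridity_index <- function(pet, precipitation) {
  if (any(precipitation <= 0)) {
    stop("aridity_index: precipitation must be > 0 (index undefined at 0 mm)",
         call. = FALSE)
  }
  pet / precipitation
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.625 -> 0.63 at 2 digits), the
#' convention used for reported climate indices; R's own `round()` rounds
#' ties to even.
#'
#' @param x numeric.
#' @param digits decimal digits.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Read a growing-period climate table from CSV
#'
#' Columns: `grassland,year,mean_temp,precip_mm,period_days,year_days`.
#' `mean_temp` is the period mean temperature (degrees C).
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_climate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("grassland", "year", "mean_temp", "precip_mm",
                "period_days", "year_days")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("climate table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x
}

#' Aridity table with wet/dry year labels
#'
#' Computes PET and the aridity index for every grassland-year and, within
#' each grassland, labels the year with the largest index `dry` and the
#' smallest `wet` (ties, or a single year, stay `unlabeled`).
#'
#' @param climate data.frame as returned by [read_climate_table()].
#' @param clip_biotemperature clip period mean temperatures into the
#'   Holdridge 0-30 degree band before the PET formula (default TRUE); with
#'   FALSE, a plain period mean is used as-is and must be non-negative.
#' @return data.frame `grassland, year, pet, aridity_index, label`.
#' @export
aridity_table <- function(climate, clip_biotemperature = TRUE) {
  bt <- if (clip_biotemperature) {
    vapply(climate$mean_temp, bio_temperature, numeric(1))
  } else {
    climate$mean_temp
  }
  pet <- holdridge_pet(bt, climate$period_days, climate$year_days)
  ai <- aridity_index(pet, climate$precip_mm)
  out <- data.frame(grassland = as.character(climate$grassland),
                    year = as.integer(climate$year),
                    pet = pet, aridity_index = ai,
                    label = "unlabeled", stringsAsFactors = FALSE)
  for (g in unique(out$grassland)) {
    i <- which(out$grassland == g)
    if (length(i) < 2) next
    hi <- i[out$aridity_index[i] == max(out$aridity_index[i])]
    lo <- i[out$aridity_index[i] == min(out$aridity_index[i])]
    if (length(hi) == 1 && length(lo) == 1 && hi != lo) {
      out$label[hi] <- "dry"
      out$label[lo] <- "wet"
    }
  }
  out
}
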