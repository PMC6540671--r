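#' Default quantitative traits
#'
#' The four leaf and stature traits the package works with by default:
#' specific leaf area (SLA, m2/kg), leaf dry matter content (LDMC, g/kg),
#' leaf nitrogen concentration (LNC, g/kg) and maximum plant height (H, cm).
#' All functions taking a `trait_levels` argument accept any other set of
#' strictly positive quantitative traits.
#'
#' @return Character vector of trait names.
#' @export
default_traits <- function() c("SLA", "LDMC", "LNC", "H")

#' Construct a species-by-year trait table
#'
#' A trait table holds the "specific" trait values: one value per
#' (grassland, year, species, trait), the mean over the individuals of that
#' species measured in that grassland and year.
#'
#' @param x data.frame with columns `grassland`, `year`, `species`, `trait`,
#'   `value` and optionally `n_individuals`. A `site` column, if present, is
#'   dropped with a message: the data model keeps one value per grassland-year.
#' @param trait_levels allowed trait names; defaults to [default_traits()].
#' @return `x` with class `trait_table` and attribute `trait_levels`.
#' @export
as_trait_table <- function(x, trait_levels = default_traits()) {
  x <- as.data.frame(x)
  required <- c("grassland", "year", "species", "trait", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("trait table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("site" %in% names(x)) {
    message("trait table: ignoring 'site' column (one value per grassland-year)")
    x$site <- NULL
  }
  x$grassland <- as.character(x$grassland)
  x$species <- as.character(x$species)
  x$trait <- as.character(x$trait)
  x$year <- as.integer(x$year)
  x$value <- as.numeric(x$value)
  if (anyNA(x$year)) stop("trait table: non-integer year", call. = FALSE)
  bad_trait <- setdiff(unique(x$trait), trait_levels)
  if (length(bad_trait) > 0) {
    stop("trait table: unknown trait(s) ", paste(bad_trait, collapse = ", "),
         "; declare them via trait_levels", call. = FALSE)
  }
  if (anyNA(x$value) || any(x$value <= 0)) {
    stop("trait table value error: all trait values must be positive",
         call. = FALSE)
  }
  key <- paste(x$grassland, x$year, x$species, x$trait, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf(
      "trait table duplicate-key error: more than one record for (%s, %d, %s, %s)",
      dup$grassland, dup$year, dup$species, dup$trait), call. = FALSE)
  }
  keep <- intersect(c(required, "n_individuals"), names(x))
  x <- x[, keep, drop = FALSE]
  rownames(x) <- NULL
  attr(x, "trait_levels") <- trait_levels
  class(x) <- c("trait_table", "data.frame")
  x
}

#' Read a trait table from CSV
#'
#' Expects tidy (long) rows: `grassland,year,species,trait,value[,n_individuals]`,
#' comma-separated, UTF-8, one header row.
#'
#' @param path file path.
#' @inheritParams as_trait_table
#' @return a [as_trait_table()] object.
#' @export
read_trait_table <- function(path, trait_levels = default_traits()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as_trait_table(utils::read.csv(path, stringsAsFactors = FALSE),
                 trait_levels = trait_levels)
}

#' Write a trait table to CSV
#'
#' Numeric values are written with 17 significant digits so that a
#' write/read round trip reproduces them exactly.
#'
#' @param x trait table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(x, path) {
  stopifnot(inherits(x, "trait_table"))
  out <- as.data.frame(x)
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a per-quadrat relative-abundance table
#'
#' Holds relative aboveground biomass per species within each
#' (grassland, site, quadrat, year) sample. Per-sample sums within
#' `tolerance` of 1 are renormalised to exactly 1 (with a message); larger
#' deviations are rejected.
#'
#' @param x data.frame with columns `grassland`, `site`, `quadrat`, `year`,
#'   `species`, `rel_biomass`.
#' @param tolerance maximum allowed absolute deviation of a per-sample sum
#'   from 1 before the sample is rejected.
#' @return `x` with class `abundance_table`; attribute `renormalized` lists
#'   samples whose sums were nudged back to 1.
#' @export
as_abundance_table <- function(x, tolerance = 1e-6) {
  x <- as.data.frame(x)
  required <- c("grassland", "site", "quadrat", "year", "species", "rel_biomass")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("abundance table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("grassland", "site", "quadrat", "species")) {
    x[[col]] <- as.character(x[[col]])
  }
  x$year <- as.integer(x$year)
  x$rel_biomass <- as.numeric(x$rel_biomass)
  if (anyNA(x$rel_biomass) || any(x$rel_biomass < 0)) {
    stop("abundance table value error: rel_biomass must be >= 0", call. = FALSE)
  }
  sample_id <- paste(x$grassland, x$site, x$quadrat, x$year, sep = "/")
  key <- paste(sample_id, x$species, sep = "\r")
  if (anyDuplicated(key)) {
    stop("abundance table duplicate-key error: repeated species within a sample",
         call. = FALSE)
  }
  sums <- tapply(x$rel_biomass, sample_id, sum)
  off <- abs(sums - 1) > tolerance
  if (any(off)) {
    stop("abundance table normalization error: sample(s) ",
         paste(names(sums)[off], collapse = ", "),
         " sum to ", paste(signif(sums[off], 7), collapse = ", "),
         " (must be 1 within ", tolerance, ")", call. = FALSE)
  }
  inexact <- names(sums)[sums != 1]
  if (length(inexact) > 0) {
    x$rel_biomass <- x$rel_biomass / as.numeric(sums[sample_id])
    message("abundance table: renormalized ", length(inexact),
            " sample(s) whose biomass fractions summed to 1 within tolerance")
  }
  x <- x[, required, drop = FALSE]
  rownames(x) <- NULL
  attr(x, "renormalized") <- inexact
  class(x) <- c("abundance_table", "data.frame")
  x
}

#' Read a relative-abundance table from CSV
#'
#' Expects tidy rows `grassland,site,quadrat,year,species,rel_biomass`.
#'
#' @inheritParams read_trait_table
#' @inheritParams as_abundance_table
#' @return an [as_abundance_table()] object.
#' @export
read_abundance_table <- function(path, tolerance = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as_abundance_table(utils::read.csv(path, stringsAsFactors = FALSE),
                     tolerance = tolerance)
}

#' Write an abundance table to CSV
#'
#' @param x abundance table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  out <- as.data.frame(x)
  out$rel_biomass <- sprintf("%.17g", out$rel_biomass)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# sample id used throughout: grassland/site/quadrat/year
sample_id <- function(abund) {
  paste(abund$grassland, abund$site, abund$quadrat, abund$year, sep = "/")
}

#' Carry single-year trait values over to missing years
#'
#' Species whose traits were measured in only one of the study years keep
#' that value in the other year (as field studies do when a year's
#' measurements are lost). Carried records are marked in the
#' `carried` column of the result.
#'
#' @param traits trait table.
#' @param years integer vector of years the completed table must cover;
#'   defaults to the years present in `traits`.
#' @return data.frame like `traits` with a logical `carried` column.
#' @export
carry_over_traits <- function(traits, years = NULL) {
  stopifnot(inherits(traits, "trait_table"))
  if (is.null(years)) years <- sort(unique(traits$year))
  years <- as.integer(years)
  df <- as.data.frame(traits)
  df$carried <- FALSE
  key <- paste(df$grassland, df$species, df$trait, sep = "\r")
  extra <- lapply(split(df, key), function(rec) {
    miss <- setdiff(years, rec$year)
    if (length(miss) == 0 || nrow(rec) == 0) return(NULL)
    # carry the (single) measured value into each missing year
    if (length(unique(rec$value)) == 1 || nrow(rec) == 1) {
      carried_value <- rec$value[1]
    } else {
      carried_value <- mean(rec$value)
    }
    out <- rec[rep(1, length(miss)), , drop = FALSE]
    out$year <- miss
    out$value <- carried_value
    out$carried <- TRUE
    out
  })
  extra <- do.call(rbind, extra)
  out <- rbind(df, extra)
  out <- out[order(out$grassland, out$year, out$species, out$trait), ]
  rownames(out) <- NULL
  attr(out, "trait_levels") <- attr(traits, "trait_levels")
  out
}

#' Per-sample trait coverage
#'
#' Fraction of each sample's relative biomass contributed by species having
#' all requested traits in that year (single-year values carried over).
#'
#' @param abund abundance table.
#' @param traits trait table.
#' @param trait_names traits a species must have to count as covered;
#'   defaults to the table's trait levels.
#' @return data.frame `grassland, site, quadrat, year, coverage`.
#' @export
trait_coverage <- function(abund, traits, trait_names = NULL) {
  stopifnot(inherits(abund, "abundance_table"), inherits(traits, "trait_table"))
  if (is.null(trait_names)) trait_names <- attr(traits, "trait_levels")
  completed <- carry_over_traits(traits, years = sort(unique(abund$year)))
  completed <- completed[completed$trait %in% trait_names, , drop = FALSE]
  n_traits <- tapply(completed$trait,
                     paste(completed$grassland, completed$year,
                           completed$species, sep = "\r"),
                     function(tr) length(unique(tr)))
  covered_key <- names(n_traits)[n_traits == length(trait_names)]
  key <- paste(abund$grassland, abund$year, abund$species, sep = "\r")
  ok <- key %in% covered_key
  id <- sample_id(abund)
  cov <- tapply(abund$rel_biomass * ok, id, sum)
  tot <- tapply(abund$rel_biomass, id, sum)
  meta <- unique(data.frame(grassland = abund$grassland, site = abund$site,
                            quadrat = abund$quadrat, year = abund$year,
                            id = id, stringsAsFactors = FALSE))
  meta$coverage <- as.numeric(cov[meta$id]) / as.numeric(tot[meta$id])
  meta$id <- NULL
  rownames(meta) <- NULL
  meta[order(meta$grassland, meta$site, meta$quadrat, meta$year), ]
}

#' Validate a trait + abundance dataset
#'
#' Cross-checks the two tables: warns about species present in the surveys
#' but never measured for traits, warns where a single-year trait value is
#' carried over, and flags an error for every sample whose trait-covered
#' biomass falls below `coverage_threshold`.
#'
#' @param traits trait table.
#' @param abund abundance table.
#' @param coverage_threshold minimum acceptable covered biomass fraction
#'   per sample (default 0.80).
#' @param trait_names traits required for a species to count as covered.
#' @return data.frame of findings (`severity`, `code`, `message`,
#'   `location`) with class `validation_report`; attribute `accepted` is
#'   TRUE iff there are no error rows.
#' @export
validate_dataset <- function(traits, abund, coverage_threshold = 0.8,
                             trait_names = NULL) {
  stopifnot(inherits(abund, "abundance_table"), inherits(traits, "trait_table"))
  if (is.null(trait_names)) trait_names <- attr(traits, "trait_levels")
  findings <- list()
  add <- function(severity, code, msg, location) {
    findings[[length(findings) + 1]] <<- data.frame(
      severity = severity, code = code, message = msg, location = location,
      stringsAsFactors = FALSE)
  }
  years <- sort(unique(abund$year))

  # species surveyed but never trait-measured in their grassland
  trait_sp <- unique(paste(traits$grassland, traits$species, sep = "\r"))
  ab_sp <- unique(abund[abund$rel_biomass > 0, c("grassland", "species")])
  missing <- ab_sp[!(paste(ab_sp$grassland, ab_sp$species, sep = "\r") %in% trait_sp), ]
  for (i in seq_len(nrow(missing))) {
    add("warning", "missing_traits",
        sprintf("species '%s' has no trait records in grassland '%s'",
                missing$species[i], missing$grassland[i]),
        missing$grassland[i])
  }

  # single-year trait values that will be carried over
  one_year <- stats::aggregate(year ~ grassland + species + trait,
                               data = as.data.frame(traits),
                               FUN = function(y) length(unique(y)))
  names(one_year)[names(one_year) == "year"] <- "n_years"
  short <- one_year[one_year$n_years < length(years), , drop = FALSE]
  short <- unique(short[, c("grassland", "species")])
  for (i in seq_len(nrow(short))) {
    add("warning", "carry_over",
        sprintf("species '%s' (grassland '%s'): single-year trait, value carried over",
                short$species[i], short$grassland[i]),
        short$grassland[i])
  }

  # coverage per sample
  cov <- trait_coverage(abund, traits, trait_names)
  low <- cov[cov$coverage < coverage_threshold, , drop = FALSE]
  for (i in seq_len(nrow(low))) {
    loc <- paste(low$grassland[i], low$site[i], low$quadrat[i], low$year[i],
                 sep = "/")
    add("error", "coverage",
        sprintf("trait-covered biomass %.3f below threshold %.2f in sample %s",
                low$coverage[i], coverage_threshold, loc),
        loc)
  }

  report <- if (length(findings) > 0) {
    do.call(rbind, findings)
  } else {
    data.frame(severity = character(), code = character(),
               message = character(), location = character(),
               stringsAsFactors = FALSE)
  }
  rownames(report) <- NULL
  attr(report, "accepted") <- !any(report$severity == "error")
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  n_err <- sum(x$severity == "error")
  n_warn <- sum(x$severity == "warning")
  cat(sprintf("Dataset validation report: %d error(s), %d warning(s); %s\n",
              n_err, n_warn,
              if (attr(x, "accepted")) "dataset accepted" else "dataset rejected"))
  if (nrow(x) > 0) {
    print.data.frame(as.data.frame(x), right = FALSE)
  }
  invisible(x)
}
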