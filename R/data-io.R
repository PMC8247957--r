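#' Read the three core input tables
#'
#' Reads and validates the species, site, and survey CSV files that every
#' downstream stage consumes. Schemas:
#' \itemize{
#'   \item species.csv: \code{species_id,sti_c}
#'   \item sites.csv: \code{site_id,lon,lat,protected,pa_area_km2}
#'   \item surveys.csv: \code{site_id,year,species_id,count} (\code{count}
#'     may be empty for occurrence-only data)
#' }
#' Duplicate \code{(site_id, year, species_id)} survey rows are collapsed to a
#' single occurrence with abundances summed; long-format exports commonly
#' repeat keys, so duplicates are merged rather than rejected.
#'
#' @param species_path,sites_path,surveys_path paths to the CSV files.
#' @return a list with validated data frames \code{species}, \code{sites} and
#'   \code{surveys}.
#' @export
read_tables <- function(species_path, sites_path, surveys_path) {
  species <- read_species(species_path)
  sites <- read_sites(sites_path)
  surveys <- read_surveys(surveys_path, species = species, sites = sites)
  list(species = species, sites = sites, surveys = surveys)
}

#' @rdname read_tables
#' @export
read_species <- function(species_path) {
  df <- utils::read.csv(species_path, stringsAsFactors = FALSE)
  require_columns(df, c("species_id", "sti_c"), species_path)
  validate_species(df)
}

#' @rdname read_tables
#' @export
read_sites <- function(sites_path) {
  df <- utils::read.csv(sites_path, stringsAsFactors = FALSE)
  require_columns(df, c("site_id", "lon", "lat", "protected", "pa_area_km2"),
                  sites_path)
  validate_sites(df)
}

#' @rdname read_tables
#' @param species optional validated species table used for referential checks.
#' @param sites optional validated site table used for referential checks.
#' @export
read_surveys <- function(surveys_path, species = NULL, sites = NULL) {
  df <- utils::read.csv(surveys_path, stringsAsFactors = FALSE)
  require_columns(df, c("site_id", "year", "species_id"), surveys_path)
  if (!"count" %in% names(df)) df$count <- NA_real_
  validate_surveys(df, species = species, sites = sites)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("schema error in '", path, "': missing required column(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

check_numeric <- function(x, what) {
  xn <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(xn))
  if (length(bad) > 0) {
    stop("parse error: non-numeric ", what, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  xn
}

#' Validate a species table
#'
#' @param df data frame with \code{species_id} and \code{sti_c}.
#' @return the validated data frame (STI coerced to numeric).
#' @export
validate_species <- function(df) {
  df$species_id <- as.character(df$species_id)
  df$sti_c <- check_numeric(df$sti_c, "sti_c")
  if (anyNA(df$sti_c) || any(!is.finite(df$sti_c))) {
    stop("species table: sti_c must be finite for every species", call. = FALSE)
  }
  dup <- df$species_id[duplicated(df$species_id)]
  if (length(dup) > 0) {
    stop("species table: duplicated species_id ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  df
}

#' Validate a site table
#'
#' Enforces coordinate ranges (lon in [-180, 180], lat in [-90, 90]),
#' protected in {0, 1}, nonnegative protected-area surface, and the
#' consistency rule protected = 0 => pa_area_km2 = 0.
#'
#' @param df data frame with the sites.csv schema.
#' @return the validated data frame.
#' @export
validate_sites <- function(df) {
  df$site_id <- as.character(df$site_id)
  df$lon <- check_numeric(df$lon, "lon")
  df$lat <- check_numeric(df$lat, "lat")
  df$pa_area_km2 <- check_numeric(df$pa_area_km2, "pa_area_km2")
  df$protected <- as.integer(df$protected)
  bad_lat <- which(is.na(df$lat) | df$lat < -90 | df$lat > 90)
  if (length(bad_lat) > 0) {
    stop("site table: latitude out of range [-90, 90] at row(s) ",
         paste(utils::head(bad_lat, 5), collapse = ", "), call. = FALSE)
  }
  bad_lon <- which(is.na(df$lon) | df$lon < -180 | df$lon > 180)
  if (length(bad_lon) > 0) {
    stop("site table: longitude out of range [-180, 180] at row(s) ",
         paste(utils::head(bad_lon, 5), collapse = ", "), call. = FALSE)
  }
  if (any(!df$protected %in% c(0L, 1L))) {
    stop("site table: protected must be 0 or 1", call. = FALSE)
  }
  if (any(is.na(df$pa_area_km2) | df$pa_area_km2 < 0)) {
    stop("site table: pa_area_km2 must be nonnegative", call. = FALSE)
  }
  bad_pa <- which(df$protected == 0L & df$pa_area_km2 > 0)
  if (length(bad_pa) > 0) {
    stop("site table: unprotected sites must have pa_area_km2 = 0 (row(s) ",
         paste(utils::head(bad_pa, 5), collapse = ", "), ")", call. = FALSE)
  }
  dup <- df$site_id[duplicated(df$site_id)]
  if (length(dup) > 0) {
    stop("site table: duplicated site_id ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Validate a survey table
#'
#' Collapses duplicate (site, year, species) rows to one occurrence, summing
#' abundances, and checks referential integrity against the species and site
#' tables when supplied. Counts, when present, must be >= 1.
#'
#' @param df long-format survey data frame.
#' @param species,sites optional reference tables.
#' @return validated, de-duplicated data frame sorted by site, year, species.
#' @export
validate_surveys <- function(df, species = NULL, sites = NULL) {
  df$site_id <- as.character(df$site_id)
  df$species_id <- as.character(df$species_id)
  df$year <- as.integer(check_numeric(df$year, "year"))
  if (anyNA(df$year)) stop("survey table: year must be an integer", call. = FALSE)
  df$count <- check_numeric(df$count, "count")
  if (any(!is.na(df$count) & df$count < 1)) {
    stop("survey table: counts must be >= 1 when present", call. = FALSE)
  }
  if (!is.null(species)) {
    unknown <- setdiff(unique(df$species_id), species$species_id)
    if (length(unknown) > 0) {
      stop("survey table: unknown species_id ",
           paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(sites)) {
    unknown <- setdiff(unique(df$site_id), sites$site_id)
    if (length(unknown) > 0) {
      stop("survey table: unknown site_id ",
           paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
    }
  }
  key <- paste(df$site_id, df$year, df$species_id, sep = "\r")
  if (anyDuplicated(key)) {
    counts <- tapply(df$count, key, function(x) {
      if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
    })
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$count <- as.numeric(counts[paste(df$site_id, df$year, df$species_id,
                                        sep = "\r")])
  }
  df <- df[order(df$site_id, df$year, df$species_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write the core tables back to CSV
#'
#' Inverse of [read_tables()]; round-trips exactly (occurrence sets and
#' abundances preserved).
#'
#' @param tables list with \code{species}, \code{sites}, \code{surveys}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(species = file.path(dir, "species.csv"),
             sites = file.path(dir, "sites.csv"),
             surveys = file.path(dir, "surveys.csv"))
  utils::write.csv(tables$species, paths["species"], row.names = FALSE)
  utils::write.csv(tables$sites, paths["sites"], row.names = FALSE)
  utils::write.csv(tables$surveys, paths["surveys"], row.names = FALSE)
  invisible(paths)
}

#' Read a temperature table
#'
#' Accepts either monthly records (\code{site_id,year,month,temp_c}) or
#' pre-aggregated winter means (\code{site_id,year,winter_temp_c}).
#'
#' @param path CSV path.
#' @return data frame; attribute \code{"aggregated"} says which form was read.
#' @export
read_temperature <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("winter_temp_c" %in% names(df)) {
    require_columns(df, c("site_id", "year", "winter_temp_c"), path)
    df$winter_temp_c <- check_numeric(df$winter_temp_c, "winter_temp_c")
    aggregated <- TRUE
  } else {
    require_columns(df, c("site_id", "year", "month", "temp_c"), path)
    df$month <- as.integer(df$month)
    df$temp_c <- check_numeric(df$temp_c, "temp_c")
    aggregated <- FALSE
  }
  df$site_id <- as.character(df$site_id)
  df$year <- as.integer(df$year)
  attr(df, "aggregated") <- aggregated
  df
}
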