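#' Apply the survey/site inclusion rules
#'
#' Reproduces the long-term monitoring inclusion criteria: count events with
#' fewer than 2 species are removed first (a single-species survey has no
#' defined community spread, so it can never enter the analysis and cannot
#' count toward site inclusion); sites are then retained only if they have at
#' least \code{min_counts} surviving count events and at least one count in
#' each decade bin of the study window. With the default 1993--2017 window the
#' bins are 1993--1999, 2000--2009 and 2010--2017 (the window truncates the
#' 1990s; the bins partition the window).
#'
#' @param surveys long-format survey table (one row per site, year, species).
#' @param study_start,study_end first and last calendar year retained.
#' @param min_species minimum species per count event (default 2).
#' @param min_counts minimum count events per site (default 5).
#' @return list with the filtered \code{surveys} and a \code{report} of class
#'   \code{filter_report} tallying every exclusion; each excluded survey or
#'   site appears in exactly one tally.
#' @export
filter_sites_and_surveys <- function(surveys, study_start = 1993,
                                     study_end = 2017, min_species = 2,
                                     min_counts = 5) {
  stopifnot(study_start < study_end)
  survey_key <- function(df) paste(df$site_id, df$year, sep = "\r")
  n_surveys_in <- length(unique(survey_key(surveys)))
  n_sites_in <- length(unique(surveys$site_id))

  in_window <- surveys$year >= study_start & surveys$year <= study_end
  n_out_window <- length(unique(survey_key(surveys[!in_window, , drop = FALSE])))
  surveys <- surveys[in_window, , drop = FALSE]

  # drop count events with too few species
  key <- survey_key(surveys)
  richness <- table(key)
  sparse_keys <- names(richness)[richness < min_species]
  surveys_rich <- surveys[!key %in% sparse_keys, , drop = FALSE]

  # site inclusion on the surviving count events
  ev <- unique(surveys_rich[, c("site_id", "year")])
  bins <- decade_bins(study_start, study_end)
  ev$bin <- findInterval(ev$year, vapply(bins, `[`, numeric(1), 1))
  n_counts <- table(ev$site_id)
  few_count_sites <- names(n_counts)[n_counts < min_counts]
  enough <- setdiff(names(n_counts), few_count_sites)
  bin_cover <- tapply(ev$bin[ev$site_id %in% enough],
                      ev$site_id[ev$site_id %in% enough],
                      function(b) length(unique(b)))
  missing_decade_sites <- names(bin_cover)[bin_cover < length(bins)]
  kept_sites <- setdiff(enough, missing_decade_sites)

  out <- surveys_rich[surveys_rich$site_id %in% kept_sites, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    stop("no sites satisfy the inclusion rules (>=", min_counts,
         " counts, one per decade bin, >=", min_species,
         " species per count)", call. = FALSE)
  }

  dropped_at_excluded <- unique(surveys_rich[
    !surveys_rich$site_id %in% kept_sites, c("site_id", "year")])
  report <- structure(list(
    n_sites_in = n_sites_in,
    n_sites_kept = length(kept_sites),
    n_surveys_in = n_surveys_in,
    n_surveys_kept = length(unique(survey_key(out))),
    surveys_outside_window = n_out_window,
    surveys_few_species = length(sparse_keys),
    surveys_at_excluded_sites = nrow(dropped_at_excluded),
    sites_few_counts = length(few_count_sites),
    sites_missing_decade = length(missing_decade_sites),
    study_start = study_start, study_end = study_end,
    min_species = min_species, min_counts = min_counts
  ), class = "filter_report")

  list(surveys = out, report = report)
}

# decade bins partitioning [start, end]; with 1993-2017:
# 1993-1999, 2000-2009, 2010-2017
decade_bins <- function(study_start, study_end) {
  starts <- unique(c(study_start,
                     seq(ceiling(study_start / 10) * 10,
                         floor(study_end / 10) * 10, by = 10)))
  starts <- starts[starts <= study_end]
  lapply(seq_along(starts), function(i) {
    c(starts[i], if (i < length(starts)) starts[i + 1] - 1 else study_end)
  })
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Survey inclusion filter (", x$study_start, "-", x$study_end, ")\n",
      sep = "")
  cat(sprintf("  sites:   %d in, %d kept\n", x$n_sites_in, x$n_sites_kept))
  cat(sprintf("  surveys: %d in, %d kept\n", x$n_surveys_in, x$n_surveys_kept))
  cat(sprintf("  excluded surveys: %d outside window, %d with <%d species, %d at excluded sites\n",
              x$surveys_outside_window, x$surveys_few_species, x$min_species,
              x$surveys_at_excluded_sites))
  cat(sprintf("  excluded sites:   %d with <%d counts, %d missing a decade bin\n",
              x$sites_few_counts, x$min_counts, x$sites_missing_decade))
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report a \code{filter_report}.
#' @param path optional file to write.
#' @return the JSON string, invisibly when written to file.
#' @export
filter_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
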