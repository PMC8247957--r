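#' Winter temperature per site and count year
#'
#' Counts take place in January, so the winter attributed to count year y is
#' the mean of the monthly means for November and December of year y - 1 and
#' January of year y.
#'
#' @param monthly data frame \code{site_id,year,month,temp_c} of monthly mean
#'   temperatures.
#' @param years count years to aggregate; default: every year for which all
#'   three winter months are available at a site.
#' @return data frame \code{site_id,year,winter_temp_c}. When \code{years} is
#'   supplied explicitly, a missing winter month raises an error naming the
#'   site and month.
#' @export
winter_temperature <- function(monthly, years = NULL) {
  stopifnot(all(c("site_id", "year", "month", "temp_c") %in% names(monthly)))
  explicit <- !is.null(years)
  # month of winter(y): Nov(y-1), Dec(y-1), Jan(y) -> index by count year
  count_year <- ifelse(monthly$month %in% c(11L, 12L),
                       monthly$year + 1L,
                       ifelse(monthly$month == 1L, monthly$year, NA_integer_))
  w <- monthly[!is.na(count_year), , drop = FALSE]
  w$count_year <- count_year[!is.na(count_year)]
  if (explicit) w <- w[w$count_year %in% years, , drop = FALSE]

  key <- paste(w$site_id, w$count_year, sep = "\r")
  n_months <- tapply(w$month, key, function(m) length(unique(m)))
  mean_t <- tapply(w$temp_c, key, mean)
  complete <- names(n_months)[n_months == 3L]

  if (explicit) {
    want <- as.vector(outer(unique(monthly$site_id), years, paste, sep = "\r"))
    missing_keys <- setdiff(want, complete)
    if (length(missing_keys) > 0) {
      parts <- strsplit(missing_keys[1], "\r", fixed = TRUE)[[1]]
      have <- sort(unique(w$month[key == missing_keys[1]]))
      miss <- setdiff(c(11L, 12L, 1L), have)
      stop("missing winter month(s) ", paste(miss, collapse = ", "),
           " for site '", parts[1], "', count year ", parts[2],
           " (", length(missing_keys), " incomplete site-years)",
           call. = FALSE)
    }
  }

  parts <- strsplit(complete, "\r", fixed = TRUE)
  out <- data.frame(
    site_id = vapply(parts, `[`, character(1), 1),
    year = as.integer(vapply(parts, `[`, character(1), 2)),
    winter_temp_c = as.numeric(mean_t[complete])
  )
  out <- out[order(out$site_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}
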