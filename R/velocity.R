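#' Kilometers per decimal degree of latitude
#'
#' Average conversion used to express latitudinal displacement in kilometers.
#' @export
KM_PER_DEGREE <- 111.128

#' Latitudinal gradient of a response
#'
#' Ordinary least-squares slope of a response on latitude (deg C per decimal
#' degree): the spatial counterpart of a temporal trend, used to convert
#' trends to displacement velocities.
#'
#' @param records data frame with \code{lat} and the response column.
#' @param response response column name.
#' @return list of class \code{gradient_fit}: \code{response, slope, se, n}.
#' @export
fit_latitudinal_gradient <- function(records, response) {
  lat <- records$lat
  y <- records[[response]]
  keep <- is.finite(lat) & is.finite(y)
  lat <- lat[keep]; y <- y[keep]
  if (length(unique(lat)) < 3)
    stop("latitudinal gradient needs >=3 distinct latitudes", call. = FALSE)
  m <- stats::lm(y ~ lat)
  s <- summary(m)$coefficients
  structure(list(response = response, slope = unname(s["lat", "Estimate"]),
                 se = unname(s["lat", "Std. Error"]), n = length(y)),
            class = "gradient_fit")
}

#' Convert a temporal trend to a latitudinal displacement velocity
#'
#' velocity (km/yr) = |trend (deg C/yr)| / |gradient (deg C/degree)| x
#' 111.128 km/degree. Velocities are reported as positive poleward
#' displacement (the convention when a warming trend meets a poleward-cooling
#' gradient); the sign convention makes the conversion invariant to
#' simultaneous sign flips of trend and gradient.
#'
#' @param temporal_trend deg C per year.
#' @param gradient deg C per decimal degree of latitude (nonzero).
#' @param horizon_years horizon for the cumulative displacement.
#' @param response label carried through to the output.
#' @return list of class \code{velocity_estimate}: \code{velocity} (km/yr)
#'   and \code{cumulative_km} = velocity x horizon.
#' @export
trend_to_velocity <- function(temporal_trend, gradient, horizon_years = 25,
                              response = "cti") {
  if (!is.finite(gradient) || gradient == 0)
    stop("velocity undefined: zero latitudinal gradient", call. = FALSE)
  v <- abs(temporal_trend) / abs(gradient) * KM_PER_DEGREE
  structure(list(response = response, velocity = v,
                 cumulative_km = v * horizon_years,
                 horizon_years = horizon_years),
            class = "velocity_estimate")
}

#' Climatic debt from temperature and community velocities
#'
#' debt (km/yr) = temperature velocity - CTI velocity: the displacement the
#' community failed to realize. Negative debt (community overshoot) is
#' allowed and flagged.
#'
#' @param v_temp,v_cti velocities in km/yr (numbers or
#'   \code{velocity_estimate}s).
#' @param horizon_years study horizon for the cumulative debt.
#' @param stratum label (e.g. "inside", "outside", "overall").
#' @return list of class \code{debt_estimate}: \code{debt},
#'   \code{cumulative_km} (= debt x horizon, exact), \code{overshoot} flag.
#' @export
climatic_debt <- function(v_temp, v_cti, horizon_years = 25,
                          stratum = "overall") {
  vt <- if (inherits(v_temp, "velocity_estimate")) v_temp$velocity else v_temp
  vc <- if (inherits(v_cti, "velocity_estimate")) v_cti$velocity else v_cti
  debt <- vt - vc
  structure(list(stratum = stratum, v_temp = vt, v_cti = vc, debt = debt,
                 cumulative_km = debt * horizon_years,
                 horizon_years = horizon_years, overshoot = debt < 0),
            class = "debt_estimate")
}

#' Classify the colonization/extirpation scenario
#'
#' Maps the signs and significance of the CTI and CTI_SD temporal trends onto
#' the four theoretical colonization/extirpation scenarios:
#' \enumerate{
#'   \item no thermal adjustment (CTI trend not significant); a significantly
#'     negative CTI trend is also labeled 1, with a cooling-adjustment flag;
#'   \item CTI up, CTI_SD significantly down: extirpation-dominated
#'     (cold-dwelling species leave);
#'   \item CTI up, CTI_SD significantly up: colonization-dominated
#'     (warm-dwelling species arrive);
#'   \item CTI up, CTI_SD unchanged: balanced colonization and extirpation.
#' }
#' Scenario 1's row is an explicit convention completing the decision table
#' by elimination.
#'
#' @param cti_trend,cti_sd_trend lists or one-row data frames with
#'   \code{estimate} and \code{p} (two-sided).
#' @param alpha significance level (default 0.05, two-sided).
#' @return list of class \code{scenario_label}: \code{label} in 1:4,
#'   \code{cooling} flag, \code{alpha}.
#' @export
classify_scenario <- function(cti_trend, cti_sd_trend, alpha = 0.05) {
  get <- function(x, f) {
    v <- x[[f]]
    if (is.null(v) || is.na(v)) stop("classify_scenario: missing ", f,
                                     call. = FALSE)
    as.numeric(v)[1]
  }
  cti_est <- get(cti_trend, "estimate"); cti_p <- get(cti_trend, "p")
  sd_est <- get(cti_sd_trend, "estimate"); sd_p <- get(cti_sd_trend, "p")
  cooling <- FALSE
  if (cti_p >= alpha) {
    label <- 1L
  } else if (cti_est < 0) {
    label <- 1L
    cooling <- TRUE
  } else if (sd_p < alpha && sd_est < 0) {
    label <- 2L
  } else if (sd_p < alpha && sd_est > 0) {
    label <- 3L
  } else {
    label <- 4L
  }
  structure(list(label = label, cooling = cooling, alpha = alpha,
                 cti = c(estimate = cti_est, p = cti_p),
                 cti_sd = c(estimate = sd_est, p = sd_p)),
            class = "scenario_label")
}

#' Relative difference between two quantities, in percent
#'
#' Two conventions used when comparing strata:
#' \itemize{
#'   \item \code{"share-of-larger"}: (a - b) / a x 100 -- "the shift was X%
#'     larger in a than in b";
#'   \item \code{"relative-to-reference"}: (b - a) / b x 100 -- "a is X%
#'     lower than the reference b".
#' }
#'
#' @param a,b the two quantities (denominators must be nonzero).
#' @param mode which convention.
#' @return percentage.
#' @export
relative_difference <- function(a, b,
                                mode = c("share-of-larger",
                                         "relative-to-reference")) {
  mode <- match.arg(mode)
  denom <- if (mode == "share-of-larger") a else b
  if (!is.finite(denom) || denom == 0)
    stop("relative_difference: zero denominator", call. = FALSE)
  if (mode == "share-of-larger") (a - b) / a * 100 else (b - a) / b * 100
}

#' Assemble the stratum-level debt table
#'
#' Combines a single study-wide temperature velocity with per-stratum CTI
#' velocities (a single temperature trend is appropriate when warming does
#' not differ between strata) and attaches scenario labels.
#'
#' @param v_temp temperature velocity (km/yr).
#' @param v_cti_by_stratum named numeric vector of CTI velocities.
#' @param scenarios optional named list of \code{scenario_label}s.
#' @param horizon_years study horizon.
#' @return data frame with one row per stratum
#'   (\code{stratum,v_temp_km_yr,v_cti_km_yr,debt_km_yr,cumulative_km,horizon_yr,scenario}).
#' @export
debt_table <- function(v_temp, v_cti_by_stratum, scenarios = NULL,
                       horizon_years = 25) {
  rows <- lapply(names(v_cti_by_stratum), function(s) {
    de <- climatic_debt(v_temp, v_cti_by_stratum[[s]], horizon_years, s)
    data.frame(stratum = s, v_temp_km_yr = de$v_temp,
               v_cti_km_yr = de$v_cti, debt_km_yr = de$debt,
               cumulative_km = de$cumulative_km, horizon_yr = horizon_years,
               scenario = if (!is.null(scenarios) && s %in% names(scenarios))
                 scenarios[[s]]$label else NA_integer_)
  })
  do.call(rbind, rows)
}
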