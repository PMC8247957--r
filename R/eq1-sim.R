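#' Simulate site-year data directly from the trend model
#'
#' Generates a balanced site-by-year panel from the Gaussian mixed model the
#' trend stage fits: response = mu + beta_year * year_c + beta_pa * protected
#' + beta_int * year_c * protected + site effect + spatially structured
#' noise. Site effects are iid Normal(0, sigma_site^2). Two spatial modes:
#' \itemize{
#'   \item \code{"residual"} (default): residuals have SD
#'     \code{sigma_resid} and are correlated \code{exp(-d / rho)} across
#'     sites within a year (independent between years) -- exponential
#'     correlation on the residual process;
#'   \item \code{"field"}: residuals are iid and a static site-level
#'     Gaussian random field with SD \code{spatial_sd} and correlation
#'     \code{exp(-d / rho)} is added -- the structure the spatial trend
#'     model fits.
#' }
#' Distances d are Euclidean in decimal degrees. Used as the generative
#' oracle for parameter-recovery checks.
#'
#' @param n_sites,n_years panel dimensions.
#' @param mu,beta_year,beta_pa,beta_int fixed-effect values.
#' @param sigma_site,sigma_resid standard deviations.
#' @param rho exponential spatial correlation range (0 = independence).
#' @param spatial_mode \code{"residual"} or \code{"field"} (see above).
#' @param spatial_sd SD of the static field (mode \code{"field"} only).
#' @param extent lon/lat box for the site coordinates.
#' @param p_pa fraction of sites protected.
#' @param year_start first calendar year.
#' @param seed integer seed.
#' @return data frame \code{site_id,lon,lat,protected,year,y} plus the true
#'   parameters in attribute \code{"truth"}.
#' @export
simulate_trend_data <- function(n_sites = 200, n_years = 25, mu = 5,
                                beta_year = 0.01, beta_pa = 0.3,
                                beta_int = 0.004, sigma_site = 0.5,
                                sigma_resid = 0.3, rho = 2,
                                spatial_mode = c("residual", "field"),
                                spatial_sd = 0.5,
                                extent = list(lon_min = -10, lon_max = 30,
                                              lat_min = 35, lat_max = 65),
                                p_pa = 0.5, year_start = 1993, seed = 1) {
  spatial_mode <- match.arg(spatial_mode)
  set.seed(seed)
  lon <- stats::runif(n_sites, extent$lon_min, extent$lon_max)
  lat <- stats::runif(n_sites, extent$lat_min, extent$lat_max)
  protected <- stats::rbinom(n_sites, 1, p_pa)
  u_site <- stats::rnorm(n_sites, 0, sigma_site)
  years <- year_start:(year_start + n_years - 1)
  year_c <- years - year_start

  u_sp <- 0
  if (rho > 0) {
    D <- as.matrix(stats::dist(cbind(lon, lat)))
    L <- chol(exp(-D / rho) + diag(1e-10, n_sites))
  }
  if (rho > 0 && spatial_mode == "residual") {
    eps <- sigma_resid *
      crossprod(L, matrix(stats::rnorm(n_sites * n_years), n_sites, n_years))
  } else {
    if (rho > 0 && spatial_sd > 0)
      u_sp <- spatial_sd * drop(crossprod(L, stats::rnorm(n_sites)))
    eps <- matrix(stats::rnorm(n_sites * n_years, 0, sigma_resid),
                  n_sites, n_years)
  }

  grid_y <- mu + outer(u_site + u_sp + beta_pa * protected,
                       rep(1, n_years)) +
    outer(rep(1, n_sites), beta_year * year_c) +
    outer(beta_int * protected, year_c) + eps

  out <- data.frame(
    site_id = rep(sprintf("s%04d", seq_len(n_sites)), times = n_years),
    lon = rep(lon, times = n_years), lat = rep(lat, times = n_years),
    protected = rep(protected, times = n_years),
    year = rep(years, each = n_sites),
    y = as.vector(grid_y)
  )
  attr(out, "truth") <- c(mu = mu, beta_year = beta_year, beta_pa = beta_pa,
                          beta_int = beta_int, sigma_site = sigma_site,
                          sigma_resid = sigma_resid, rho = rho,
                          spatial_sd = if (spatial_mode == "field")
                            spatial_sd else 0)
  out
}
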