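#' Build moving-window grid cells
#'
#' Places square cells (default 5 x 5 degrees) on a 1-degree lattice over an
#' extent, keeping every position whose full square lies inside the extent.
#' A site belongs to a cell iff \code{lower-left <= coordinate < lower-left +
#' size} (half-open, so a site on a cell's upper edge belongs to the adjacent
#' cell). Cells with fewer than \code{min_sites} member sites are dropped to
#' avoid unstable fits at the edge of the study area.
#'
#' @param sites site table with \code{site_id,lon,lat,protected,pa_area_km2}.
#' @param extent list/vector with \code{lon_min,lon_max,lat_min,lat_max};
#'   default: bounding box of the sites.
#' @param cell_size cell width and height in degrees.
#' @param step lattice step in degrees between neighboring cell origins.
#' @param min_sites minimum member sites for a cell to be retained.
#' @return data frame of retained cells
#'   (\code{cell_id,lon0,lat0,n_sites}) with a list column \code{members} of
#'   member site ids.
#' @export
build_cells <- function(sites, extent = NULL, cell_size = 5, step = 1,
                        min_sites = 15) {
  if (is.null(extent)) {
    extent <- c(lon_min = min(sites$lon), lon_max = max(sites$lon),
                lat_min = min(sites$lat), lat_max = max(sites$lat))
  }
  extent <- as.list(extent)
  if (extent$lon_max - extent$lon_min < cell_size ||
      extent$lat_max - extent$lat_min < cell_size)
    stop("extent too small for any ", cell_size, "-degree cell", call. = FALSE)
  lon0 <- seq(extent$lon_min, extent$lon_max - cell_size, by = step)
  lat0 <- seq(extent$lat_min, extent$lat_max - cell_size, by = step)
  grid <- expand.grid(lon0 = lon0, lat0 = lat0)
  members <- lapply(seq_len(nrow(grid)), function(i) {
    inx <- sites$lon >= grid$lon0[i] & sites$lon < grid$lon0[i] + cell_size &
      sites$lat >= grid$lat0[i] & sites$lat < grid$lat0[i] + cell_size
    sites$site_id[inx]
  })
  grid$n_sites <- lengths(members)
  keep <- grid$n_sites >= min_sites
  if (!any(keep))
    stop("no cells retain >= ", min_sites, " sites", call. = FALSE)
  out <- grid[keep, , drop = FALSE]
  out$cell_id <- sprintf("c%+04d%+04d", as.integer(round(out$lon0)),
                         as.integer(round(out$lat0)))
  out$members <- members[keep]
  rownames(out) <- NULL
  attr(out, "cell_size") <- cell_size
  out[, c("cell_id", "lon0", "lat0", "n_sites", "members")]
}

#' Protected-area surface proportion of a cell
#'
#' Sum of the member protected sites' PA surfaces divided by the cell's
#' inland surface. On synthetic data the inland surface defaults to the full
#' cell area (approximated on the sphere as
#' 111.128^2 x size^2 x cos(mid-latitude) km^2); supply \code{land_km2} for
#' realistic coastlines. The raw ratio is clipped to [0, 1] with a warning
#' (overlapping PA polygons can overshoot).
#'
#' @param cell one row of [build_cells()] output.
#' @param sites site table.
#' @param land_km2 inland surface of the cell; NULL for the full cell area.
#' @param cell_size cell size in degrees (used for the default area).
#' @return proportion in [0, 1].
#' @export
pa_surface_proportion <- function(cell, sites, land_km2 = NULL,
                                  cell_size = 5) {
  if (is.null(land_km2)) {
    mid_lat <- cell$lat0 + cell_size / 2
    land_km2 <- (KM_PER_DEGREE * cell_size)^2 * cos(mid_lat * pi / 180)
  }
  if (!is.finite(land_km2) || land_km2 <= 0)
    stop("cell ", cell$cell_id, ": inland surface must be positive",
         call. = FALSE)
  ids <- cell$members[[1]]
  s <- sites[sites$site_id %in% ids & sites$protected == 1, , drop = FALSE]
  p <- sum(s$pa_area_km2) / land_km2
  if (p > 1) {
    warning("cell ", cell$cell_id, ": PA surface exceeds inland surface; ",
            "proportion clipped to 1", call. = FALSE)
    p <- 1
  }
  p
}

#' Fit per-cell temporal trends and derive velocities and debt
#'
#' For every retained cell, fits one mixed model per response (winter
#' temperature, CTI, CTI_SD) of the member sites' series on year (site random
#' intercept; optional exponential spatial correlation), converts the
#' temperature and CTI trends to km/yr using the study-wide latitudinal
#' gradients (a single south-north gradient; per-cell gradients are unstable
#' at this cell size), and computes the per-cell climatic debt. Cells whose
#' model fails to converge are flagged and excluded from downstream
#' regressions rather than silently zeroed.
#'
#' @param cells output of [build_cells()].
#' @param sites site table.
#' @param indices community index table ([build_indices()]).
#' @param winter winter temperature table (\code{site_id,year,winter_temp_c}).
#' @param grad_temp,grad_cti study-wide latitudinal gradients (deg C/degree).
#' @param spatial \code{"none"} (default; cells are small) or \code{"exp"}.
#' @param land_km2 per-cell inland surface passed to
#'   [pa_surface_proportion()]; NULL uses the full spherical cell area.
#' @return the cell table with columns
#'   \code{pa_proportion,temp_trend,temp_p,cti_trend,cti_p,cti_sd_trend,cti_sd_p,v_temp,v_cti,debt,flags}.
#' @export
fit_cell_trends <- function(cells, sites, indices, winter, grad_temp,
                            grad_cti, spatial = c("none", "exp"),
                            land_km2 = NULL) {
  spatial <- match.arg(spatial)
  site_xy <- sites[, c("site_id", "lon", "lat")]
  cell_size <- attr(cells, "cell_size")
  if (is.null(cell_size)) cell_size <- 5

  fit_slope <- function(df, col) {
    if (nrow(df) == 0 || length(unique(df$site_id)) < 2 ||
        length(unique(df$year)) < 2) {
      return(c(NA_real_, NA_real_))
    }
    sp <- trend_spec(col, spatial = spatial, protection = FALSE)
    f <- tryCatch(fit_trend_model(df, sp), error = function(e) NULL)
    if (is.null(f) || !f$converged) return(c(NA_real_, NA_real_))
    row <- f$coefficients[f$coefficients$term == "year_c", ]
    c(row$estimate, row$p)
  }

  res <- lapply(seq_len(nrow(cells)), function(i) {
    ids <- cells$members[[i]]
    idx <- merge(indices[indices$site_id %in% ids, ], site_xy, by = "site_id")
    tmp <- merge(winter[winter$site_id %in% ids, ], site_xy, by = "site_id")
    tt <- fit_slope(tmp, "winter_temp_c")
    ct <- fit_slope(idx, "cti")
    sdt <- fit_slope(idx, "cti_sd")
    flags <- character(0)
    if (anyNA(c(tt[1], ct[1], sdt[1]))) flags <- c(flags, "fit-failed")
    v_temp <- if (is.na(tt[1])) NA_real_ else
      abs(tt[1]) / abs(grad_temp) * KM_PER_DEGREE * sign_keep(tt[1])
    v_cti <- if (is.na(ct[1])) NA_real_ else
      abs(ct[1]) / abs(grad_cti) * KM_PER_DEGREE * sign_keep(ct[1])
    data.frame(temp_trend = tt[1], temp_p = tt[2], cti_trend = ct[1],
               cti_p = ct[2], cti_sd_trend = sdt[1], cti_sd_p = sdt[2],
               v_temp = v_temp, v_cti = v_cti, debt = v_temp - v_cti,
               flags = paste(flags, collapse = ";"))
  })
  out <- cbind(cells, do.call(rbind, res))
  out$pa_proportion <- vapply(seq_len(nrow(out)), function(i) {
    pa_surface_proportion(out[i, ], sites, land_km2 = land_km2,
                          cell_size = cell_size)
  }, numeric(1))
  out
}

# per-cell velocities keep the trend's sign so that debt = v_temp - v_cti can
# be negative where communities overshoot local warming
sign_keep <- function(x) if (x < 0) -1 else 1

#' Regress per-cell community change on protected-area coverage
#'
#' Ordinary least squares of a per-cell response (CTI spatial shift in km/yr,
#' climatic debt in km/yr, or CTI_SD trend in deg C/yr) on
#' ln(PA-surface proportion), the temperature spatial shift (km/yr), and
#' their interaction. Cells with zero PA proportion get
#' \code{ln(p + delta)} with delta = half the smallest positive proportion
#' (flagged in the output): the handling of zero-PA cells is explicit and
#' sensitivity-testable.
#'
#' @param cells populated cell table from [fit_cell_trends()].
#' @param response one of \code{"cti_shift"}, \code{"debt"},
#'   \code{"cti_sd_trend"}.
#' @return list of class \code{cell_regression}: coefficient table
#'   (intercept, log-PA, temperature shift, interaction), n_cells, delta.
#' @export
regress_on_pa <- function(cells, response = c("cti_shift", "debt",
                                              "cti_sd_trend")) {
  response <- match.arg(response)
  y <- switch(response, cti_shift = cells$v_cti, debt = cells$debt,
              cti_sd_trend = cells$cti_sd_trend)
  keep <- is.finite(y) & is.finite(cells$v_temp) & cells$flags == ""
  d <- data.frame(y = y[keep], pa = cells$pa_proportion[keep],
                  v_temp = cells$v_temp[keep])
  if (nrow(d) < 10)
    stop("regress_on_pa needs >= 10 retained cells", call. = FALSE)
  delta <- 0
  if (any(d$pa == 0)) {
    pos <- d$pa[d$pa > 0]
    if (length(pos) == 0)
      stop("all cells have zero PA proportion", call. = FALSE)
    delta <- min(pos) / 2
  }
  d$log_pa <- log(d$pa + delta)
  if (length(unique(d$log_pa)) < 2)
    warning("PA proportion constant across cells; rank-deficient design",
            call. = FALSE)
  m <- stats::lm(y ~ log_pa * v_temp, data = d)
  s <- summary(m)$coefficients
  coefs <- data.frame(term = c("intercept", "log_pa", "temp_shift",
                               "log_pa:temp_shift")[seq_len(nrow(s))],
                      estimate = s[, "Estimate"], se = s[, "Std. Error"],
                      z = s[, "t value"], p = s[, "Pr(>|t|)"],
                      row.names = NULL)
  structure(list(response = response, coefficients = coefs,
                 n_cells = nrow(d), delta_zero_pa = delta, model = m),
            class = "cell_regression")
}

#' Protected-area coverage versus location
#'
#' Least-squares fit of the per-cell PA-surface proportion on cell-center
#' latitude, longitude and their interaction, to describe where the protected
#' estate sits within the study region.
#'
#' @param cells populated cell table.
#' @return coefficient data frame (intercept, lat, lon, lat:lon).
#' @export
pa_vs_location <- function(cells) {
  cs <- attr(cells, "cell_size")
  if (is.null(cs)) cs <- 5
  d <- data.frame(pa = cells$pa_proportion,
                  lat = cells$lat0 + cs / 2, lon = cells$lon0 + cs / 2)
  m <- stats::lm(pa ~ lat * lon, data = d)
  s <- summary(m)$coefficients
  data.frame(term = rownames(s), estimate = s[, "Estimate"],
             se = s[, "Std. Error"], t = s[, "t value"],
             p = s[, "Pr(>|t|)"], row.names = NULL)
}

#' Flatten a populated cell table for CSV output
#'
#' @param cells populated cell table.
#' @param path optional CSV path.
#' @return data frame without the list column, invisibly when written.
#' @export
cells_csv <- function(cells, path = NULL) {
  out <- cells[, setdiff(names(cells), "members")]
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
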