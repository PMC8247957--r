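#' Build a climatology grid
#'
#' A regular lon/lat grid of long-term mean January temperatures used to
#' compute species temperature indices. Cells are stored long-format with one
#' row per cell center.
#'
#' @param lon,lat strictly monotone axis vectors of cell-center coordinates.
#' @param values matrix of temperatures, \code{length(lon)} rows by
#'   \code{length(lat)} columns; NA marks missing cells (e.g. sea).
#' @return object of class \code{climatology_grid}: data frame
#'   \code{lon,lat,temp_c} plus axis attributes.
#' @export
climatology_grid <- function(lon, lat, values) {
  stopifnot(is.matrix(values), nrow(values) == length(lon),
            ncol(values) == length(lat))
  if (any(diff(lon) <= 0) && any(diff(lon) >= 0))
    stop("climatology: lon axis must be strictly monotone", call. = FALSE)
  if (any(diff(lat) <= 0) && any(diff(lat) >= 0))
    stop("climatology: lat axis must be strictly monotone", call. = FALSE)
  if (!any(is.finite(values)))
    stop("climatology: no finite cells", call. = FALSE)
  df <- data.frame(lon = rep(lon, times = length(lat)),
                   lat = rep(lat, each = length(lon)),
                   temp_c = as.vector(values))
  structure(df, class = c("climatology_grid", "data.frame"),
            lon_axis = lon, lat_axis = lat)
}

#' Read a climatology grid from a long-format CSV
#'
#' Expects columns \code{lon,lat,temp_c} with one row per cell center of a
#' regular grid.
#'
#' @param path CSV path.
#' @return a \code{climatology_grid}.
#' @export
read_climatology <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("lon", "lat", "temp_c"), path)
  lon <- sort(unique(df$lon))
  lat <- sort(unique(df$lat))
  m <- matrix(NA_real_, length(lon), length(lat))
  m[cbind(match(df$lon, lon), match(df$lat, lat))] <- df$temp_c
  climatology_grid(lon, lat, m)
}

#' Construct a species range mask
#'
#' A range mask selects the climatology cells covered by a species'
#' nonbreeding distribution, either directly (cell indices) or by a lon/lat
#' polygon rasterized by the cell-center-in-polygon rule (deterministic and
#' resolution-stable).
#'
#' @param species_id species identifier.
#' @param cells integer indices of climatology rows, or NULL when a polygon
#'   is given.
#' @param polygon two-column matrix of polygon vertices (lon, lat), or NULL.
#' @param climatology a \code{climatology_grid} (required with a polygon).
#' @return object of class \code{range_mask} holding the resolved cell indices.
#' @export
range_mask <- function(species_id, cells = NULL, polygon = NULL,
                       climatology = NULL) {
  if (is.null(cells)) {
    if (is.null(polygon) || is.null(climatology))
      stop("range_mask: supply either cells or polygon + climatology",
           call. = FALSE)
    inside <- mgcv::in.out(rbind(as.matrix(polygon), polygon[1, ]),
                           cbind(climatology$lon, climatology$lat))
    cells <- which(inside)
  }
  cells <- sort(unique(as.integer(cells)))
  if (length(cells) == 0)
    stop("range mask for '", species_id,
         "' is empty after rasterization", call. = FALSE)
  structure(list(species_id = species_id, cells = cells),
            class = "range_mask")
}

#' Species temperature index from a range mask and climatology
#'
#' The STI is the long-term mean January temperature across the cells of the
#' species' nonbreeding range. Cells with missing climatology values are
#' excluded from both numerator and denominator. The default is the
#' unweighted cell mean; \code{weighting = "cos-latitude"} weights each cell
#' by the cosine of its latitude (approximate area weighting on a regular
#' lon/lat grid).
#'
#' @param mask a \code{range_mask}.
#' @param climatology a \code{climatology_grid}.
#' @param weighting \code{"equal"} (default) or \code{"cos-latitude"}.
#' @return data frame row: \code{species_id, sti_c, n_cells, source}.
#' @export
compute_sti <- function(mask, climatology,
                        weighting = c("equal", "cos-latitude")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(mask, "range_mask"))
  vals <- climatology$temp_c[mask$cells]
  lat <- climatology$lat[mask$cells]
  keep <- is.finite(vals)
  if (!any(keep))
    stop("range of '", mask$species_id,
         "' is outside the climatology domain (no finite cells)",
         call. = FALSE)
  w <- if (weighting == "equal") rep(1, sum(keep)) else cos(lat[keep] * pi / 180)
  data.frame(species_id = mask$species_id,
             sti_c = sum(w * vals[keep]) / sum(w),
             n_cells = sum(keep),
             source = paste0("climatology:", weighting),
             stringsAsFactors = FALSE)
}

#' Remove part of a range from a mask
#'
#' Drops cells whose centers fall inside an exclusion polygon (e.g. removing
#' a subrange whose climate the study populations never experience).
#'
#' @param mask a \code{range_mask}.
#' @param polygon exclusion polygon, two-column (lon, lat) matrix.
#' @param climatology the \code{climatology_grid} the mask indexes.
#' @return a new \code{range_mask}; errors if nothing survives.
#' @export
exclude_subrange <- function(mask, polygon, climatology) {
  stopifnot(inherits(mask, "range_mask"))
  pts <- cbind(climatology$lon[mask$cells], climatology$lat[mask$cells])
  inside <- mgcv::in.out(rbind(as.matrix(polygon), polygon[1, ]), pts)
  keep <- mask$cells[!inside]
  if (length(keep) == 0)
    stop("range of '", mask$species_id,
         "' is empty after exclusion", call. = FALSE)
  range_mask(mask$species_id, cells = keep)
}
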