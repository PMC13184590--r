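#' Regular latitude-longitude grid
#'
#' Cell-centered regular grid, latitude ascending, coordinates in degrees.
#' The default 36 x 72 layout gives 5-degree cells, a desk-scale stand-in for
#' the 2 x 2.5 degree grids used by global chemical transport models.
#'
#' @param nlat,nlon number of latitude / longitude cells.
#' @return an object of class `pah_grid` with cell-center coordinate vectors
#'   `lat`, `lon` and spacings `dlat`, `dlon`.
#' @export
pah_grid <- function(nlat = 36L, nlon = 72L) {
  stopifnot(nlat >= 4, nlon >= 4)
  dlat <- 180 / nlat
  dlon <- 360 / nlon
  structure(
    list(
      lat = seq(-90 + dlat / 2, 90 - dlat / 2, by = dlat),
      lon = seq(-180 + dlon / 2, 180 - dlon / 2, by = dlon),
      dlat = dlat, dlon = dlon
    ),
    class = "pah_grid"
  )
}

#' @export
print.pah_grid <- function(x, ...) {
  cat(sprintf("<pah_grid> %d x %d cells (%.2f x %.2f degrees)\n",
              length(x$lat), length(x$lon), x$dlat, x$dlon))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
}

#' Spherical cell areas
#'
#' @param grid a [pah_grid()].
#' @param earth_radius_m Earth radius in metres.
#' @return matrix (nlat x nlon) of cell areas in m^2.
#' @export
cell_areas <- function(grid, earth_radius_m = 6.371e6) {
  lat0 <- (grid$lat - grid$dlat / 2) * pi / 180
  lat1 <- (grid$lat + grid$dlat / 2) * pi / 180
  band <- earth_radius_m^2 * (grid$dlon * pi / 180) * (sin(lat1) - sin(lat0))
  matrix(band, nrow = length(grid$lat), ncol = length(grid$lon))
}

# cos(latitude) weights replicated across longitudes, for area-weighted means
lat_weights <- function(grid) {
  matrix(cos(grid$lat * pi / 180), length(grid$lat), length(grid$lon))
}
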