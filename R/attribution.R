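#' Fire-attributed concentration field
#'
#' Differences a baseline against a no-wildfire (NoWF) counterfactual:
#' `absolute = baseline - nowf` cell-by-cell, and
#' `percent = 100 * absolute / baseline` where the baseline is positive.
#' Cells with zero baseline carry an explicit `undefined` flag rather than a
#' silent NaN.
#'
#' @param baseline,nowf annual-mean `pah_state`s on the same grid/species.
#' @param species optional species subset.
#' @param phase aggregation passed to [state_total()].
#' @return object of class `pah_attribution` with matrices `absolute`,
#'   `percent`, logical `undefined`, and the grid.
#' @export
fire_contribution <- function(baseline, nowf, species = NULL, phase = "all") {
  if (!grids_identical(baseline$grid, nowf$grid) ||
      !identical(baseline$species, nowf$species)) {
    stop("baseline and NoWF states do not match")
  }
  b <- state_total(baseline, species, phase)
  n <- state_total(nowf, species, phase)
  absolute <- b - n
  undefined <- b <= 0
  percent <- matrix(NA_real_, nrow(b), ncol(b))
  percent[!undefined] <- 100 * absolute[!undefined] / b[!undefined]
  structure(list(absolute = absolute, percent = percent, undefined = undefined,
                 grid = baseline$grid, species = species, phase = phase),
            class = "pah_attribution")
}

#' Region mask
#'
#' @param name region label.
#' @param mask logical matrix (nlat x nlon) with at least one `TRUE` cell.
#' @param grid the [pah_grid()].
#' @return object of class `pah_region`.
#' @export
region_mask <- function(name, mask, grid) {
  stopifnot(is.logical(mask),
            identical(dim(mask), c(length(grid$lat), length(grid$lon))))
  if (!any(mask)) stop("region mask has no cells")
  structure(list(name = name, mask = mask, grid = grid), class = "pah_region")
}

# rectangular lat/lon box -> logical mask (lon box may wrap the dateline)
box_mask <- function(grid, lat_range, lon_range) {
  in_lat <- grid$lat >= lat_range[1] & grid$lat <= lat_range[2]
  in_lon <- if (lon_range[1] <= lon_range[2]) {
    grid$lon >= lon_range[1] & grid$lon <= lon_range[2]
  } else {
    grid$lon >= lon_range[1] | grid$lon <= lon_range[2]
  }
  outer(in_lat, in_lon, FUN = "&")
}

#' Area-weighted mean of a gridded field
#'
#' Weights proportional to cos(latitude), i.e. to cell area on a regular
#' lat-lon grid.
#'
#' @param field matrix (nlat x nlon); `NA` cells are dropped.
#' @param mask logical matrix or a `pah_region`; default all cells.
#' @param grid the [pah_grid()].
#' @return scalar.
#' @export
area_weighted_mean <- function(field, mask = NULL, grid) {
  if (inherits(mask, "pah_region")) mask <- mask$mask
  if (is.null(mask)) mask <- matrix(TRUE, nrow(field), ncol(field))
  if (!any(mask)) stop("empty mask")
  w <- lat_weights(grid)
  keep <- mask & !is.na(field)
  sum(field[keep] * w[keep]) / sum(w[keep])
}

# area-weighted global sum surrogate (weights only, used for shares)
area_weighted_sum <- function(field, grid) {
  w <- lat_weights(grid)
  sum(field * w, na.rm = TRUE)
}

#' Phase and degradation-class composition of a state
#'
#' Gas and particle fractions are computed over the parent species (they sum
#' to 1); the NPAH/DNPAH fractions are shares of the grand total including
#' the diagnosed product mass.  All sums are area-weighted.
#'
#' @param state a `pah_state`.
#' @return list with `gas_fraction`, `particle_fraction`, `npah_fraction`,
#'   `dnpah_fraction`.
#' @export
phase_fractions <- function(state) {
  g <- area_weighted_sum(state_total(state, phase = "gas"), state$grid)
  p <- area_weighted_sum(state_total(state, phase = "particle"), state$grid)
  np <- area_weighted_sum(state_total(state, phase = "npah"), state$grid)
  dn <- area_weighted_sum(state_total(state, phase = "dnpah"), state$grid)
  parent_tot <- g + p
  if (parent_tot <= 0) stop("zero total burden")
  list(gas_fraction = g / parent_tot,
       particle_fraction = p / parent_tot,
       npah_fraction = np / (parent_tot + np + dn),
       dnpah_fraction = dn / (parent_tot + np + dn))
}

#' Composition of the fire-attributed mixture
#'
#' [phase_fractions()] applied to the baseline-minus-NoWF difference state.
#'
#' @param baseline,nowf matching `pah_state`s.
#' @export
fire_phase_fractions <- function(baseline, nowf) {
  phase_fractions(state_combine(baseline, nowf, `-`))
}

#' Land-mean meteorological differences between two periods
#'
#' For each driver variable: time-mean(a) minus time-mean(b), then
#' area-weighted over land cells (caller passes the later period first for a
#' "later minus earlier" orientation).
#'
#' @param fields_a,fields_b [environment_fields()] on the same grid.
#' @param land logical matrix; defaults to `fields_a$land_mask`.
#' @return named vector of deltas (temperature K, oc/bc ug m^-3, ...).
#' @export
meteorology_difference <- function(fields_a, fields_b, land = NULL) {
  if (!grids_identical(fields_a$grid, fields_b$grid)) stop("grid mismatch")
  if (is.null(land)) land <- fields_a$land_mask
  if (!any(land)) stop("empty land mask")
  vars <- c("temperature", "oc", "bc", "oh", "o3", "no3")
  vapply(vars, function(v) {
    da <- apply(fields_a[[v]], c(2, 3), mean)
    db <- apply(fields_b[[v]], c(2, 3), mean)
    area_weighted_mean(da - db, land, fields_a$grid)
  }, numeric(1))
}

#' Regional fire-contribution summary
#'
#' @param attribution a [fire_contribution()] result.
#' @param regions named list of `pah_region` or logical masks.
#' @return data.frame (region, absolute, percent): area-weighted regional
#'   mean fire-attributed concentration and area-weighted mean percent
#'   contribution over defined cells.
#' @export
regional_summary <- function(attribution, regions) {
  rows <- lapply(names(regions), function(nm) {
    m <- regions[[nm]]
    if (inherits(m, "pah_region")) m <- m$mask
    data.frame(
      region = nm,
      absolute = area_weighted_mean(attribution$absolute, m, attribution$grid),
      percent = area_weighted_mean(attribution$percent, m & !attribution$undefined,
                                   attribution$grid),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
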