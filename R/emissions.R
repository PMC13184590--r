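#' The eight emission sectors
#'
#' Sector set of the emulated global PAH emission inventory.
#' @export
PAH_SECTORS <- c("residential", "agricultural", "industrial_processes",
                 "industrial_combustion", "transportation", "commercial",
                 "fires", "electric_generation")

#' Construct an emission inventory
#'
#' Dense sector x species x month x lat x lon array of emission masses
#' (kg per cell per month).
#'
#' @param values 5-D array with dims (sector, species, month, lat, lon);
#'   sector and species dimnames are required.
#' @param grid the [pah_grid()] the values live on.
#' @param year free-text year label (e.g. "low", "high", "2019").
#' @return an object of class `pah_inventory`.
#' @export
emission_inventory <- function(values, grid, year = "unlabelled") {
  stopifnot(length(dim(values)) == 5L)
  dn <- dimnames(values)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]])) {
    stop("values must carry sector and species dimnames")
  }
  inv <- structure(list(values = values, grid = grid, year = year,
                        sectors = dn[[1]], species = dn[[2]]),
                   class = "pah_inventory")
  validate_inventory(inv)
  inv
}

validate_inventory <- function(inv) {
  v <- inv$values
  if (!all(is.finite(v))) stop("inventory values must be finite")
  if (any(v < 0)) stop("inventory values must be >= 0")
  if (!setequal(inv$sectors, PAH_SECTORS)) {
    stop("inventory must contain exactly the 8 sectors")
  }
  d <- dim(v)
  if (d[3] != 12L) stop("inventory must have 12 months")
  if (d[4] != length(inv$grid$lat) || d[5] != length(inv$grid$lon)) {
    stop("inventory grid dimensions do not match the grid")
  }
  invisible(inv)
}

#' @export
print.pah_inventory <- function(x, ...) {
  cat(sprintf("<pah_inventory> year=%s, %d species, grid %d x %d, total %.4g kg/yr\n",
              x$year, length(x$species), length(x$grid$lat), length(x$grid$lon),
              sum(x$values)))
  invisible(x)
}

# annual per-species totals for one sector (named vector, kg)
sector_annual_totals <- function(inv, sector) {
  apply(inv$values[sector, , , , , drop = FALSE], 2, sum)
}

#' Total fire-derived PAH emission excluding naphthalene
#'
#' Annual fires-sector emission summed over all species except NAP, all
#' months and all cells.
#'
#' @param inv a `pah_inventory`.
#' @return scalar mass (kg).
#' @export
total_fire_pah_excluding_nap <- function(inv) {
  tot <- sector_annual_totals(inv, "fires")
  sum(tot[setdiff(names(tot), "NAP")])
}

#' Fractional fire-sector contribution of each species within a subset
#'
#' f_i = E_i / sum(E) over the subset, using annual fires-sector totals.
#'
#' @param inv a `pah_inventory`.
#' @param subset character vector of species abbreviations.
#' @return named numeric vector summing to 1.
#' @export
species_fractions <- function(inv, subset) {
  if (length(subset) == 0L) stop("subset must be non-empty")
  stopifnot(all(subset %in% inv$species))
  tot <- sector_annual_totals(inv, "fires")[subset]
  s <- sum(tot)
  if (s <= 0) stop("no basis for fractions: subset fire emission total is zero")
  tot / s
}

#' Redistribute fire-sector PAH speciation toward light aromatics
#'
#' Adjusts the fires sector so that it emits only two-, three- and four-ring
#' parent PAHs, reflecting the observation that lower-temperature biomass
#' combustion favours light aromatics:
#' * NAP (the only two-ring species) is held constant cell-by-cell;
#' * five- and six-ring fire emissions are set to zero;
#' * each three-/four-ring species i is rescaled so its annual fire total
#'   becomes `E'_i = f_i * E_total`, where `f_i` is its original fractional
#'   contribution within the three-/four-ring group and `E_total` the
#'   original total fire PAH emission excluding NAP.
#'
#' The total fire PAH emission excluding NAP is conserved, within-group
#' relative proportions are preserved, and each species keeps its original
#' monthly/spatial fire pattern (scaled uniformly).  Non-fire sectors are
#' returned untouched.
#'
#' @param inv a `pah_inventory` of parent species.
#' @param registry a `pah_registry` providing ring counts.
#' @return the adjusted `pah_inventory`.
#' @export
redistribute_fire_speciation <- function(inv, registry = default_species_registry()) {
  stopifnot(all(inv$species %in% registry$abbreviation))
  rings <- registry[inv$species, "ring_count"]
  group <- inv$species[rings %in% c(3L, 4L)]
  heavy <- inv$species[rings %in% c(5L, 6L)]
  tot <- sector_annual_totals(inv, "fires")
  if (sum(tot[group]) <= 0) {
    stop("cannot form fractions: all three-/four-ring fire emissions are zero")
  }
  f <- species_fractions(inv, group)
  e_total <- total_fire_pah_excluding_nap(inv)
  out <- inv
  for (sp in heavy) out$values["fires", sp, , , ] <- 0
  for (sp in group) {
    if (tot[sp] > 0) {
      out$values["fires", sp, , , ] <-
        inv$values["fires", sp, , , ] * (f[sp] * e_total / tot[sp])
    }
  }
  out
}

#' Zero out all fire emissions (no-wildfire scenario)
#'
#' @param inv a `pah_inventory`.
#' @return inventory with an all-zero fires sector; other sectors untouched.
#' @export
zero_fire_emissions <- function(inv) {
  inv$values["fires", , , , ] <- 0
  inv
}

# inventory restricted to the fires sector (all other sectors zero)
fires_only <- function(inv) {
  out <- inv
  out$values[setdiff(inv$sectors, "fires"), , , , ] <- 0
  out
}

#' Ring-size composition of each sector
#'
#' Annual emission fractions contributed by 3-, 4-, 5- and 6-ring parents in
#' each sector, excluding listed species (by default NAP, the sole two-ring
#' parent).  Sectors with zero total report `NA` fractions and are flagged.
#'
#' @param inv a `pah_inventory`.
#' @param registry a `pah_registry` providing ring counts.
#' @param exclude species abbreviations to leave out.
#' @return data.frame with columns sector, ring_3..ring_6, defined.
#' @export
sector_ring_composition <- function(inv, registry = default_species_registry(),
                                    exclude = "NAP") {
  keep <- setdiff(inv$species, exclude)
  rings <- registry[keep, "ring_count"]
  out <- data.frame(sector = inv$sectors, ring_3 = NA_real_, ring_4 = NA_real_,
                    ring_5 = NA_real_, ring_6 = NA_real_, defined = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(inv$sectors)) {
    tot <- sector_annual_totals(inv, inv$sectors[i])[keep]
    s <- sum(tot)
    if (s > 0) {
      by_ring <- vapply(3:6, function(r) sum(tot[rings == r]) / s, numeric(1))
      out[i, c("ring_3", "ring_4", "ring_5", "ring_6")] <- by_ring
      out$defined[i] <- TRUE
    }
  }
  out
}

#' Inventory CSV round trip
#'
#' Long-format CSV (sector, species, month, lat, lon, kg); zero cells are
#' omitted on write and densified on read.
#'
#' @param inv a `pah_inventory`.
#' @param path CSV path.
#' @export
write_inventory_csv <- function(inv, path) {
  idx <- which(inv$values != 0, arr.ind = TRUE)
  dt <- data.table::data.table(
    sector = inv$sectors[idx[, 1]],
    species = inv$species[idx[, 2]],
    month = idx[, 3],
    lat = inv$grid$lat[idx[, 4]],
    lon = inv$grid$lon[idx[, 5]],
    kg = inv$values[idx],
    year = inv$year
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_inventory_csv
#' @param grid the [pah_grid()] to densify onto.
#' @param species the full species set (columns absent from the file become zero).
#' @export
read_inventory_csv <- function(path, grid, species) {
  dt <- data.table::fread(path, data.table = FALSE)
  vals <- array(0, dim = c(length(PAH_SECTORS), length(species), 12L,
                           length(grid$lat), length(grid$lon)),
                dimnames = list(PAH_SECTORS, species, NULL, NULL, NULL))
  i1 <- match(dt$sector, PAH_SECTORS)
  i2 <- match(dt$species, species)
  i4 <- match_coord(dt$lat, grid$lat)
  i5 <- match_coord(dt$lon, grid$lon)
  if (anyNA(i1) || anyNA(i2) || anyNA(i4) || anyNA(i5)) {
    stop("inventory CSV contains sectors/species/coordinates outside the target layout")
  }
  vals[cbind(i1, i2, dt$month, i4, i5)] <- dt$kg
  emission_inventory(vals, grid, year = if (nrow(dt) > 0) dt$year[1] else "unlabelled")
}

match_coord <- function(x, centers) {
  i <- findInterval(x, centers - (centers[2] - centers[1]) / 2,
                    rightmost.closed = FALSE)
  i[i < 1L | i > length(centers)] <- NA_integer_
  # guard against float jitter in written coordinates
  bad <- !is.na(i) & abs(centers[pmax(i, 1L)] - x) > (centers[2] - centers[1])
  i[bad] <- NA_integer_
  i
}
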