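#' Synthetic-world configuration
#'
#' Parameters of the seeded generator that emulates the structure of the
#' real inputs: a gridded sector/species/month emission inventory with fire
#' emissions concentrated in four fire-prone regions, PM and oxidant
#' enhancements co-located with fires, and noisy site observations.  The
#' defaults are a stated world, not tuning knobs: fire emissions are ~4.5%
#' of the annual total in the low-fire year (the real regime is 4-6%), the
#' high-fire year scales fire mass by 1.3 (the observed dry-matter-burned
#' ratio between the chosen high and low fire years), and observation noise
#' is multiplicative lognormal because concentrations are positive and span
#' orders of magnitude.
#'
#' @param nlat,nlon grid shape (default 36 x 72, 5-degree cells).
#' @param seed integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @param fire_regions list of regions: name, lat/lon box, peak month.
#' @param fire_intensity_scale multiplier on fire emissions.
#' @param hotspots anthropogenic emission hotspot boxes with weights.
#' @param pm_enhancement peak fire-driven PM addition (ug m^-3).
#' @param oxidant_enhancement scale of fire-driven oxidant enhancements.
#' @param n_obs number of synthetic observation sites.
#' @param obs_sigma lognormal sigma of multiplicative observation noise.
#' @param fire_year_factor high-fire-year multiplier on fire emissions.
#' @return list of class `pah_synth_config`.
#' @export
synthetic_config <- function(nlat = 36L, nlon = 72L, seed = 1L,
                             fire_regions = default_fire_regions(),
                             fire_intensity_scale = 1,
                             hotspots = default_hotspots(),
                             pm_enhancement = 8,
                             oxidant_enhancement = 1,
                             n_obs = 150L, obs_sigma = 0.4,
                             fire_year_factor = 1.3) {
  stopifnot(nlat >= 4, nlon >= 4, fire_intensity_scale >= 0,
            pm_enhancement >= 0, oxidant_enhancement >= 0,
            n_obs >= 1, obs_sigma >= 0, fire_year_factor > 0)
  structure(list(nlat = as.integer(nlat), nlon = as.integer(nlon),
                 seed = as.integer(seed), fire_regions = fire_regions,
                 fire_intensity_scale = fire_intensity_scale,
                 hotspots = hotspots, pm_enhancement = pm_enhancement,
                 oxidant_enhancement = oxidant_enhancement,
                 n_obs = as.integer(n_obs), obs_sigma = obs_sigma,
                 fire_year_factor = fire_year_factor),
            class = "pah_synth_config")
}

#' Default fire-prone regions
#'
#' Four boxes loosely standing for Australia, sub-Saharan Africa, Siberia
#' and Canada, with dry-season peak months.  They exercise the
#' regional-summary code path; they are not the real region polygons.
#' @export
default_fire_regions <- function() {
  list(
    australia = list(lat = c(-38, -12), lon = c(113, 153), peak_month = 12L),
    subsaharan_africa = list(lat = c(-15, 10), lon = c(-10, 40), peak_month = 8L),
    siberia = list(lat = c(50, 68), lon = c(80, 140), peak_month = 7L),
    canada = list(lat = c(50, 65), lon = c(-125, -90), peak_month = 7L)
  )
}

#' Default anthropogenic hotspots
#' @export
default_hotspots <- function() {
  list(
    east_asia = list(lat = c(25, 42), lon = c(100, 122), weight = 3),
    south_asia = list(lat = c(8, 30), lon = c(68, 90), weight = 2),
    europe = list(lat = c(42, 58), lon = c(-5, 30), weight = 1.5),
    north_america = list(lat = c(32, 45), lon = c(-95, -70), weight = 1.5)
  )
}

# run code with a locally-seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# annual sector totals (kg/yr) and ring-class mass fractions of the stated world
synth_sector_spec <- function() {
  list(
    totals = c(residential = 2.2e8, agricultural = 3.0e7,
               industrial_processes = 6.0e7, industrial_combustion = 4.0e7,
               transportation = 5.0e7, commercial = 1.5e7,
               fires = 2.0e7, electric_generation = 1.0e7),
    # fractions over ring classes 2,3,4,5,6; transportation skews heavy,
    # fires sit within the anthropogenic range (the inventory being emulated
    # shows no distinct fire speciation)
    ring_frac = rbind(
      residential = c(0.45, 0.25, 0.15, 0.10, 0.05),
      agricultural = c(0.50, 0.25, 0.15, 0.07, 0.03),
      industrial_processes = c(0.35, 0.25, 0.20, 0.12, 0.08),
      industrial_combustion = c(0.40, 0.22, 0.18, 0.12, 0.08),
      transportation = c(0.30, 0.20, 0.20, 0.18, 0.12),
      commercial = c(0.40, 0.25, 0.18, 0.10, 0.07),
      fires = c(0.45, 0.22, 0.15, 0.11, 0.07),
      electric_generation = c(0.38, 0.22, 0.18, 0.13, 0.09)
    )
  )
}

# circular unimodal seasonal profile peaking at `peak`, sums to 12
seasonal_profile <- function(peak, width = 1.8) {
  m <- 1:12
  d <- pmin(abs(m - peak), 12 - abs(m - peak))
  p <- exp(-d^2 / (2 * width^2))
  12 * p / sum(p)
}

#' Generate a synthetic emission inventory
#'
#' 8 sectors x 16 parents x 12 months on the configured grid.
#' Anthropogenic sectors concentrate at hotspot boxes (residential with a
#' hemispheric winter peak), the fires sector is nonzero only inside the
#' configured fire regions with unimodal seasonal peaks and seeded lognormal
#' spatial texture.
#'
#' @param cfg a [synthetic_config()].
#' @param year "low" or "high"; the high-fire year multiplies fire emissions
#'   by `cfg$fire_year_factor`.
#' @param registry a `pah_registry`.
#' @return a `pah_inventory`.
#' @export
generate_inventory <- function(cfg, year = c("low", "high"),
                               registry = default_species_registry()) {
  year <- match.arg(year)
  grid <- pah_grid(cfg$nlat, cfg$nlon)
  parents <- parent_rows(registry)
  spec <- synth_sector_spec()
  nlat <- cfg$nlat; nlon <- cfg$nlon
  # species mass fractions per sector: ring-class fraction split evenly in class
  frac <- matrix(0, length(PAH_SECTORS), nrow(parents),
                 dimnames = list(PAH_SECTORS, parents$abbreviation))
  for (s in PAH_SECTORS) {
    for (rc in 2:6) {
      members <- parents$abbreviation[parents$ring_count == rc]
      frac[s, members] <- spec$ring_frac[s, rc - 1] / length(members)
    }
  }

  with_local_seed(cfg$seed, {
    # spatial patterns (nlat x nlon), one per sector family
    anthro <- matrix(0.02, nlat, nlon)
    for (h in cfg$hotspots) {
      m <- box_mask(grid, h$lat, h$lon)
      anthro[m] <- anthro[m] + h$weight * rlnorm(sum(m), 0, 0.5)
    }
    fire_pat <- vector("list", length(cfg$fire_regions))
    names(fire_pat) <- names(cfg$fire_regions)
    for (nm in names(cfg$fire_regions)) {
      r <- cfg$fire_regions[[nm]]
      m <- box_mask(grid, r$lat, r$lon)
      p <- matrix(0, nlat, nlon)
      p[m] <- rlnorm(sum(m), 0, 1)
      fire_pat[[nm]] <- p / sum(p)
    }

    vals <- array(0, c(length(PAH_SECTORS), nrow(parents), 12L, nlat, nlon),
                  dimnames = list(PAH_SECTORS, parents$abbreviation, NULL, NULL, NULL))
    hemis <- outer(sign(grid$lat), rep(1, nlon))  # +1 NH, -1 SH
    for (s in setdiff(PAH_SECTORS, "fires")) {
      pat <- anthro / sum(anthro)
      for (m in 1:12) {
        seas <- if (s == "residential") {
          1 + 0.6 * cos(2 * pi * (m - 1) / 12) * hemis
        } else {
          matrix(1, nlat, nlon)
        }
        field <- pat * seas
        for (i in seq_len(nrow(parents))) {
          vals[s, i, m, , ] <- spec$totals[s] * frac[s, i] * field / 12
        }
      }
    }
    fire_total <- spec$totals["fires"] * cfg$fire_intensity_scale *
      if (year == "high") cfg$fire_year_factor else 1
    nreg <- length(cfg$fire_regions)
    region_share <- if (nreg == 4L) c(0.30, 0.35, 0.20, 0.15) else rep(1 / nreg, nreg)
    for (k in seq_along(cfg$fire_regions)) {
      r <- cfg$fire_regions[[k]]
      seas <- seasonal_profile(r$peak_month)
      for (m in 1:12) {
        field <- fire_total * region_share[k] * fire_pat[[k]] * seas[m] / 12
        for (i in seq_len(nrow(parents))) {
          vals["fires", i, m, , ] <- vals["fires", i, m, , ] +
            frac["fires", i] * field
        }
      }
    }
    emission_inventory(vals, grid, year = year)
  })
}

#' Generate synthetic environment fields
#'
#' Smooth latitudinal temperature with hemispheric seasonality, background
#' PM and oxidants plus anthropogenic PM at hotspots, and - in the baseline
#' variant only - PM and oxidant enhancements proportional to the local
#' monthly fire emission.  The no-wildfire (NoWF) variant lacks the fire
#' enhancements; with zero fire emissions the two variants are identical.
#'
#' @param cfg a [synthetic_config()].
#' @param inv the `pah_inventory` whose fires sector drives the enhancements.
#' @return list with `baseline` and `nowf` [environment_fields()].
#' @export
generate_environment <- function(cfg, inv) {
  grid <- inv$grid
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  dims <- c(12L, nlat, nlon)
  latn <- grid$lat / 90

  temperature <- array(0, dims)
  for (m in 1:12) {
    seas <- 10 * cos(2 * pi * (m - 7) / 12) * tanh(grid$lat / 30)
    temperature[m, , ] <- matrix(288 - 35 * latn^2 + seas, nlat, nlon)
  }

  anthro <- apply(inv$values[setdiff(PAH_SECTORS, "fires"), , , , , drop = FALSE],
                  c(4, 5), sum)
  anthro_n <- if (max(anthro) > 0) anthro / max(anthro) else anthro
  fire_m <- apply(inv$values["fires", , , , , drop = FALSE], c(3, 4, 5), sum)
  # normalized local fire intensity: burning cells get O(1) enhancements,
  # scaled by the upper decile so co-location is material, capped at 1
  fire_n <- if (max(fire_m) > 0) {
    pmin(fire_m / stats::quantile(fire_m[fire_m > 0], 0.9), 1)
  } else fire_m

  mk <- function(base_fld, fire_add) {
    out <- array(0, dims)
    for (m in 1:12) out[m, , ] <- base_fld + fire_add * fire_n[m, , ]
    out
  }
  oc_base <- 1.2 + 5 * anthro_n
  bc_base <- 0.25 + 1 * anthro_n
  oh_base <- 1e6 * (0.4 + cos(grid$lat * pi / 180))
  oh_base <- matrix(oh_base, nlat, nlon)
  o3_base <- matrix(30, nlat, nlon)
  no3_base <- 1e7 * matrix(0.5 + 0.5 * cos(grid$lat * pi / 180), nlat, nlon)

  oxe <- cfg$oxidant_enhancement
  env_of <- function(fire) {
    environment_fields(
      grid,
      temperature = temperature,
      oc = mk(oc_base, if (fire) 0.8 * cfg$pm_enhancement else 0),
      bc = mk(bc_base, if (fire) 0.2 * cfg$pm_enhancement else 0),
      oh = mk(oh_base, if (fire) 0.5e6 * oxe else 0),
      o3 = mk(o3_base, if (fire) 10 * oxe else 0),
      no3 = if (fire) {
        out <- array(0, dims)
        for (m in 1:12) out[m, , ] <- no3_base * (1 + 2 * oxe * fire_n[m, , ])
        out
      } else mk(no3_base, 0),
      land_mask = synth_land_mask(grid, cfg)
    )
  }
  list(baseline = env_of(TRUE), nowf = env_of(FALSE))
}

# pseudo-continents plus all configured boxes
synth_land_mask <- function(grid, cfg) {
  m <- box_mask(grid, c(-55, 70), c(-165, -35)) |
    box_mask(grid, c(-35, 70), c(-15, 50)) |
    box_mask(grid, c(-45, 75), c(50, 180))
  for (b in c(cfg$fire_regions, cfg$hotspots)) {
    m <- m | box_mask(grid, b$lat, b$lon)
  }
  m
}

#' Generate synthetic site observations
#'
#' Sites are placed in randomly chosen cells with positive truth;
#' observed = truth x lognormal(0, sigma) multiplicative noise.
#'
#' @param truth matrix (nlat x nlon) of true annual-mean concentrations.
#' @param cfg a [synthetic_config()].
#' @param grid the [pah_grid()] of `truth`.
#' @param species species label written to the records.
#' @return data.frame (site_id, lat, lon, species, conc_ng_m3, urban).
#' @export
generate_observations <- function(truth, cfg, grid, species = "ALL") {
  stopifnot(all(truth >= 0))
  candidates <- which(truth > 0)
  if (length(candidates) == 0L) stop("truth field is all zero")
  with_local_seed(cfg$seed + 77L, {
    idx <- sample(candidates, cfg$n_obs, replace = cfg$n_obs > length(candidates))
    ij <- arrayInd(idx, dim(truth))
    urban_mask <- Reduce(`|`, lapply(cfg$hotspots, function(h) box_mask(grid, h$lat, h$lon)))
    noise <- rlnorm(cfg$n_obs, 0, cfg$obs_sigma)
    data.frame(
      site_id = sprintf("site_%03d", seq_len(cfg$n_obs)),
      lat = grid$lat[ij[, 1]],
      lon = grid$lon[ij[, 2]],
      species = species,
      conc_ng_m3 = truth[idx] * noise,
      urban = urban_mask[idx],
      stringsAsFactors = FALSE
    )
  })
}

#' Region masks for the synthetic fire regions
#'
#' @param grid a [pah_grid()].
#' @param cfg a [synthetic_config()].
#' @return named list of logical masks.
#' @export
default_region_masks <- function(grid, cfg = synthetic_config()) {
  lapply(cfg$fire_regions, function(r) box_mask(grid, r$lat, r$lon))
}
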