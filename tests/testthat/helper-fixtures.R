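# shared fixture builders; everything is generated in code, no files

toy_grid <- function(nlat = 4L, nlon = 4L) pah_grid(nlat, nlon)

# inventory with chosen annual fires-sector masses (kg), spread uniformly
# over months/cells, plus optional non-fire masses
toy_inventory <- function(fire_kg = c(PHEN = 4, BAP = 6, NAP = 1),
                          other_kg = c(residential = 10),
                          grid = toy_grid(),
                          species = parent_abbrevs()) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  vals <- array(0, c(length(PAH_SECTORS), length(species), 12L, nlat, nlon),
                dimnames = list(PAH_SECTORS, species, NULL, NULL, NULL))
  per_cell <- 12L * nlat * nlon
  for (sp in names(fire_kg)) {
    vals["fires", sp, , , ] <- fire_kg[[sp]] / per_cell
  }
  for (sec in names(other_kg)) {
    for (sp in species) {
      vals[sec, sp, , , ] <- other_kg[[sec]] / (per_cell * length(species))
    }
  }
  emission_inventory(vals, grid, year = "toy")
}

# random valid inventory (all 8 sectors, all parents), seeded by caller
random_inventory <- function(grid = toy_grid(), species = parent_abbrevs(),
                             sparsity = 0.5) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  n <- length(PAH_SECTORS) * length(species) * 12L * nlat * nlon
  vals <- array(rlnorm(n, 0, 1) * (runif(n) > sparsity),
                c(length(PAH_SECTORS), length(species), 12L, nlat, nlon),
                dimnames = list(PAH_SECTORS, species, NULL, NULL, NULL))
  emission_inventory(vals, grid, year = "random")
}

parent_abbrevs <- function() {
  reg <- default_species_registry()
  reg$abbreviation[reg$species_class == "parent"]
}

# spatially uniform environment with chosen scalar levels
uniform_env <- function(grid = toy_grid(), temperature = 288, oc = 5, bc = 1,
                        oh = 1e6, o3 = 30, no3 = 1e7, mixing_height = 1000,
                        k_dep_gas = 1e-6, k_dep_particle = 5e-6) {
  dims <- c(12L, length(grid$lat), length(grid$lon))
  environment_fields(grid,
                     temperature = array(temperature, dims),
                     oc = array(oc, dims), bc = array(bc, dims),
                     oh = array(oh, dims), o3 = array(o3, dims),
                     no3 = array(no3, dims),
                     mixing_height = mixing_height,
                     k_dep_gas = k_dep_gas, k_dep_particle = k_dep_particle)
}

# single-cell environment snapshot for step_cell
toy_env_cell <- function(temperature = 288, oc = 5, bc = 1, oh = 1e6,
                         o3 = 30, no3 = 1e7, k_dep_gas = 1e-6,
                         k_dep_particle = 5e-6) {
  list(temperature = temperature, oc = oc, bc = bc, oh = oh, o3 = o3,
       no3 = no3, k_dep_gas = k_dep_gas, k_dep_particle = k_dep_particle)
}

# cell state with named species vectors
toy_cell_state <- function(species, gas = 0, poc = 0, pbc = 0) {
  list(gas = setNames(rep_len(gas, length(species)), species),
       particle_oc = setNames(rep_len(poc, length(species)), species),
       particle_bc = setNames(rep_len(pbc, length(species)), species))
}

small_synth_cfg <- function(seed = 1L, ...) {
  synthetic_config(nlat = 12L, nlon = 24L, seed = seed, n_obs = 50L, ...)
}
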