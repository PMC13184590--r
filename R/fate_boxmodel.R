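#' Monthly gridded environment fields
#'
#' Prescribed driver fields for the per-cell fate model.  All gridded fields
#' are arrays with dims (12 months, nlat, nlon).
#'
#' @param grid a [pah_grid()].
#' @param temperature surface air temperature (K).
#' @param oc,bc organic-/black-carbon particulate matter (ug m^-3).
#' @param oh OH number density (molecule cm^-3).
#' @param o3 ozone mixing ratio (ppb).
#' @param no3 NO3 number density (molecule cm^-3).
#' @param mixing_height boundary-layer depth (m), scalar.
#' @param k_dep_gas,k_dep_particle first-order deposition rates (s^-1); the
#'   model collapses dry and wet removal into these two constants.
#' @param land_mask logical matrix (nlat x nlon).
#' @return object of class `pah_env`.
#' @export
environment_fields <- function(grid, temperature, oc, bc, oh, o3, no3,
                               mixing_height = 1000,
                               k_dep_gas = 1e-6, k_dep_particle = 5e-6,
                               land_mask = NULL) {
  dims <- c(12L, length(grid$lat), length(grid$lon))
  flds <- list(temperature = temperature, oc = oc, bc = bc,
               oh = oh, o3 = o3, no3 = no3)
  for (nm in names(flds)) {
    if (!identical(dim(flds[[nm]]), dims)) {
      stop("field '", nm, "' must have dims (12, nlat, nlon)")
    }
    if (any(flds[[nm]] < 0)) stop("field '", nm, "' must be >= 0")
  }
  stopifnot(mixing_height > 0, k_dep_gas >= 0, k_dep_particle >= 0)
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, length(grid$lat), length(grid$lon))
  }
  structure(c(flds, list(mixing_height = mixing_height,
                         k_dep_gas = k_dep_gas,
                         k_dep_particle = k_dep_particle,
                         land_mask = land_mask, grid = grid)),
            class = "pah_env")
}

#' Fate-model configuration
#'
#' Numerical and kinetic constants of the box model.  The ppLFER system
#' coefficients and the heterogeneous-ozonolysis constant are documented
#' package defaults (the source literature values are not reproduced here)
#' and every entry is overridable.
#'
#' @param dt_seconds integration step (s).
#' @param spinup_months number of spin-up months discarded before averaging.
#' @param c_het heterogeneous rate scale: k_het = gamma_o3 * c_het * O3_ppb (s^-1).
#' @param npah_yield,npah_loss nitro-pyrene formation yield (per NO3 reaction)
#'   and first-order product loss (s^-1).
#' @param dnpah_yield,dnpah_loss same for the sequential dinitro step.
#' @param pplfer_c0,pplfer_c1 intercept terms of the partitioning model:
#'   intercept(T) = c0 + c1 * (1000/T - 1000/298.15).
#' @param pplfer_s2 temperature-independent coefficient of the polarity
#'   descriptor.
#' @return a list of class `pah_fate_config`.
#' @export
fate_config <- function(dt_seconds = 3600, spinup_months = 2,
                        c_het = 2.5e-3,
                        npah_yield = 0.02, npah_loss = 4e-5,
                        dnpah_yield = 0.4, dnpah_loss = 1e-5,
                        pplfer_c0 = -11.7, pplfer_c1 = 0.5, pplfer_s2 = 0.2) {
  stopifnot(dt_seconds > 0, spinup_months >= 0, pplfer_c1 >= 0)
  structure(list(dt_seconds = dt_seconds, spinup_months = spinup_months,
                 c_het = c_het,
                 npah_yield = npah_yield, npah_loss = npah_loss,
                 dnpah_yield = dnpah_yield, dnpah_loss = dnpah_loss,
                 pplfer_c0 = pplfer_c0, pplfer_c1 = pplfer_c1,
                 pplfer_s2 = pplfer_s2),
            class = "pah_fate_config")
}

#' Gas-particle partition coefficient (ppLFER form)
#'
#' `log10 Kp = intercept(T) + (298.15/T) * L + s2 * S`, with
#' `intercept(T) = c0 + c1 * (1000/T - 1000/298.15)` and solute descriptors
#' `L` (`pplfer_l`) and `S` (`pplfer_s`).  With non-negative descriptors and
#' `c1 >= 0`, Kp is strictly decreasing in temperature: volatility rises
#' with warmth.
#'
#' @param species one registry row (or anything with `pplfer_l`, `pplfer_s`).
#' @param temperature_k temperature (K), vectorized; must lie in 150-350 K.
#' @param config a [fate_config()].
#' @return Kp in m^3 ug^-1.
#' @export
partition_coefficient <- function(species, temperature_k, config = fate_config()) {
  if (any(temperature_k < 150 | temperature_k > 350)) {
    stop("temperature outside physical range 150-350 K")
  }
  l <- species$pplfer_l
  s <- species$pplfer_s
  if (is.null(l) || is.null(s) || anyNA(l) || anyNA(s)) {
    stop("missing partitioning descriptors")
  }
  intercept <- config$pplfer_c0 +
    config$pplfer_c1 * (1000 / temperature_k - 1000 / 298.15)
  10^(intercept + (298.15 / temperature_k) * l + config$pplfer_s2 * s)
}

#' Particulate fraction at equilibrium
#'
#' phi = Kp * c_pm / (1 + Kp * c_pm).
#'
#' @param kp partition coefficient (m^3 ug^-1).
#' @param c_pm particulate-matter concentration (ug m^-3).
#' @return fraction in `[0, 1]`.
#' @export
particulate_fraction <- function(kp, c_pm) {
  stopifnot(all(kp >= 0), all(c_pm >= 0))
  x <- kp * c_pm
  x / (1 + x)
}

# effective heterogeneous O3 loss rate (s^-1)
k_het_o3 <- function(gamma_o3, o3_ppb, config) {
  gamma_o3 * config$c_het * o3_ppb
}

# per-species first-order loss rates in a cell; vectors over species
cell_loss_rates <- function(registry_rows, env_cell, config) {
  list(
    gas = registry_rows$k_oh * env_cell$oh +
      registry_rows$k_no3 * env_cell$no3 + env_cell$k_dep_gas,
    particle = k_het_o3(registry_rows$gamma_o3, env_cell$o3, config) +
      env_cell$k_dep_particle
  )
}

#' Advance one cell by one time step
#'
#' Analytic (exact-exponential) update: emissions enter the gas phase, gas
#' and particle pools decay at their own first-order rates, then the phases
#' are re-equilibrated instantaneously to the ppLFER particulate fraction,
#' with the particle share split between OC and BC in proportion to their
#' mass.
#'
#' @param state list with non-negative per-species vectors `gas`,
#'   `particle_oc`, `particle_bc` (ng m^-3).
#' @param env_cell list with scalars `temperature`, `oc`, `bc`, `oh`, `o3`,
#'   `no3`, `k_dep_gas`, `k_dep_particle`.
#' @param emission_rate per-species gas-phase emission rate (ng m^-3 s^-1).
#' @param dt time step (s).
#' @param registry a `pah_registry`; rows are matched to the state vectors.
#' @param config a [fate_config()].
#' @return updated state list.
#' @export
step_cell <- function(state, env_cell, emission_rate, dt,
                      registry = default_species_registry(),
                      config = fate_config()) {
  stopifnot(dt > 0)
  if (any(state$gas < 0, state$particle_oc < 0, state$particle_bc < 0)) {
    stop("negative input concentration")
  }
  sp <- names(state$gas)
  rows <- registry[sp, , drop = FALSE]
  k <- cell_loss_rates(rows, env_cell, config)
  ag <- exp(-k$gas * dt)
  gain <- ifelse(k$gas > 0, emission_rate / k$gas * (1 - ag), emission_rate * dt)
  gas1 <- state$gas * ag + gain
  part1 <- (state$particle_oc + state$particle_bc) * exp(-k$particle * dt)
  total <- gas1 + part1
  kp <- partition_coefficient(rows, env_cell$temperature, config)
  c_pm <- env_cell$oc + env_cell$bc
  phi <- particulate_fraction(kp, c_pm)
  oc_share <- if (c_pm > 0) env_cell$oc / c_pm else 0
  list(gas = (1 - phi) * total,
       particle_oc = phi * oc_share * total,
       particle_bc = phi * (1 - oc_share) * total)
}

#' Local pyrene degradation-product ratios
#'
#' Steady-state nitro-pyrene:pyrene and dinitro-pyrene:pyrene ratios from
#' the sequential kinetic pathway PYR + NO3 -> nitro-PYR -> dinitro-PYR with
#' configurable yields and product losses.  The nitration channel acts on
#' the gas-phase share of pyrene.
#'
#' @param no3 NO3 number density (molecule cm^-3); scalar or array.
#' @param phi_pyr pyrene particulate fraction (same shape as `no3`).
#' @param registry a `pah_registry` (supplies the PYR NO3 rate constant).
#' @param config a [fate_config()].
#' @return list with components `n` and `dn` (dimensionless ratios).
#' @export
pyr_product_ratios <- function(no3, phi_pyr, registry = default_species_registry(),
                               config = fate_config()) {
  k_no3_pyr <- registry["PYR", "k_no3"]
  rn <- config$npah_yield * k_no3_pyr * no3 * (1 - phi_pyr) / config$npah_loss
  rdn <- rn * config$dnpah_yield * k_no3_pyr * no3 / config$dnpah_loss
  list(n = rn, dn = rdn)
}

#' Diagnose nitro- and dinitro-PAH fields from parent concentrations
#'
#' Applies the pyrene product-to-parent ratios to every parent: the same
#' ratio is assumed across all PAHs.
#'
#' @param state a `pah_state`.
#' @param pyr_ratio_n,pyr_ratio_dn dimensionless ratios (scalars or
#'   nlat x nlon matrices).
#' @return the state with `npah` and `dnpah` fields replaced.
#' @export
diagnose_degradation_products <- function(state, pyr_ratio_n, pyr_ratio_dn) {
  stopifnot(all(pyr_ratio_n >= 0), all(pyr_ratio_dn >= 0))
  tot <- apply(state$conc, c(1, 3, 4), sum)   # (species, lat, lon)
  ns <- dim(tot)[1]
  scale_field <- function(r) {
    if (length(r) == 1L) tot * r
    else aperm(array(rep(r, ns), dim = c(dim(r), ns)), c(3, 1, 2)) * tot
  }
  state$npah <- scale_field(pyr_ratio_n)
  state$dnpah <- scale_field(pyr_ratio_dn)
  state
}

new_pah_state <- function(conc, npah, dnpah, grid, species) {
  structure(list(conc = conc, npah = npah, dnpah = dnpah,
                 grid = grid, species = species),
            class = "pah_state")
}

#' Build a concentration state from per-phase arrays
#'
#' @param grid a [pah_grid()].
#' @param species parent abbreviations.
#' @param gas,particle_oc,particle_bc arrays (species, nlat, nlon), ng m^-3;
#'   scalars are recycled.
#' @return a `pah_state` with zero product fields.
#' @export
pah_state <- function(grid, species, gas = 0, particle_oc = 0, particle_bc = 0) {
  d <- c(length(species), length(grid$lat), length(grid$lon))
  expand <- function(x) if (length(x) == 1L) array(x, d) else {stopifnot(identical(dim(x), d)); x}
  conc <- array(0, c(d[1], 3L, d[2], d[3]),
                dimnames = list(species, c("gas", "particle_oc", "particle_bc"), NULL, NULL))
  conc[, 1, , ] <- expand(gas)
  conc[, 2, , ] <- expand(particle_oc)
  conc[, 3, , ] <- expand(particle_bc)
  if (any(conc < 0)) stop("concentrations must be >= 0")
  new_pah_state(conc, array(0, d, dimnames = list(species, NULL, NULL)),
                array(0, d, dimnames = list(species, NULL, NULL)), grid, species)
}

#' @export
print.pah_state <- function(x, ...) {
  cat(sprintf("<pah_state> %d species on %d x %d grid; mean all-phase %.4g ng m^-3\n",
              length(x$species), length(x$grid$lat), length(x$grid$lon),
              mean(apply(x$conc, c(3, 4), sum))))
  invisible(x)
}

#' Aggregate a state to a single gridded field
#'
#' @param state a `pah_state`.
#' @param species subset of parent abbreviations (default all).
#' @param phase one of "all", "gas", "particle", "npah", "dnpah".
#' @return matrix (nlat x nlon), ng m^-3.
#' @export
state_total <- function(state, species = NULL, phase = "all") {
  if (is.null(species)) species <- state$species
  i <- match(species, state$species)
  stopifnot(!anyNA(i))
  out <- switch(phase,
    all = apply(state$conc[i, , , , drop = FALSE], c(3, 4), sum),
    gas = apply(state$conc[i, "gas", , , drop = FALSE], c(3, 4), sum),
    particle = apply(state$conc[i, c("particle_oc", "particle_bc"), , , drop = FALSE],
                     c(3, 4), sum),
    npah = apply(state$npah[i, , , drop = FALSE], c(2, 3), sum),
    dnpah = apply(state$dnpah[i, , , drop = FALSE], c(2, 3), sum),
    stop("unknown phase: ", phase)
  )
  dimnames(out) <- NULL
  out
}

# elementwise a - b / a + b over all state arrays
state_combine <- function(a, b, op) {
  stopifnot(identical(a$species, b$species), grids_identical(a$grid, b$grid))
  new_pah_state(op(a$conc, b$conc), op(a$npah, b$npah), op(a$dnpah, b$dnpah),
                a$grid, a$species)
}

#' Run a full scenario through the box model
#'
#' Integrates every grid cell independently (no inter-cell transport) over
#' `spinup_months` spin-up months (taken from the end of the calendar year)
#' followed by January-December, starting from zero concentrations, and
#' returns the 12-month mean state.  Within each month the driver fields are
#' constant, so the hourly analytic step reduces to a closed-form geometric
#' accumulation; the result is identical to iterating [step_cell()].
#' Nitro-/dinitro-PAH fields are diagnosed monthly from the local pyrene
#' product ratios and averaged.
#'
#' @param inv a `pah_inventory` of parent species.
#' @param env a [environment_fields()] object on the same grid.
#' @param registry a `pah_registry`.
#' @param config a [fate_config()].
#' @return annual-mean `pah_state`.
#' @export
run_scenario <- function(inv, env, registry = default_species_registry(),
                         config = fate_config()) {
  if (!grids_identical(inv$grid, env$grid)) stop("inventory/environment grid mismatch")
  species <- inv$species
  rows <- registry[species, , drop = FALSE]
  stopifnot(all(rows$species_class == "parent"))
  grid <- inv$grid
  nlat <- length(grid$lat); nlon <- length(grid$lon); ncell <- nlat * nlon
  nsp <- length(species)
  areas <- as.vector(cell_areas(grid))
  dt <- config$dt_seconds
  n_steps <- max(1L, round(MONTH_SECONDS / dt))
  spin <- config$spinup_months
  months <- c(if (spin > 0) rev(rev(rep(1:12, ceiling(spin / 12)))[seq_len(spin)]) else integer(0), 1:12)
  conv <- 1e12 / (areas * env$mixing_height * MONTH_SECONDS)  # kg/month -> ng m^-3 s^-1

  C <- matrix(0, nsp, ncell)  # total (all-phase) concentration, ng m^-3
  acc <- list(gas = matrix(0, nsp, ncell), poc = matrix(0, nsp, ncell),
              pbc = matrix(0, nsp, ncell), npah = matrix(0, nsp, ncell),
              dnpah = matrix(0, nsp, ncell))
  i_pyr <- match("PYR", species)

  for (k in seq_along(months)) {
    m <- months[k]
    tK <- as.vector(env$temperature[m, , ])
    oc <- as.vector(env$oc[m, , ]); bc <- as.vector(env$bc[m, , ])
    c_pm <- oc + bc
    oc_share <- ifelse(c_pm > 0, oc / c_pm, 0)
    oh <- as.vector(env$oh[m, , ]); o3 <- as.vector(env$o3[m, , ])
    no3 <- as.vector(env$no3[m, , ])

    intercept <- config$pplfer_c0 + config$pplfer_c1 * (1000 / tK - 1000 / 298.15)
    log_kp <- sweep(outer(rows$pplfer_l, 298.15 / tK), 2, intercept, "+") +
      config$pplfer_s2 * rows$pplfer_s
    phi <- particulate_fraction(10^log_kp, matrix(c_pm, nsp, ncell, byrow = TRUE))

    kg <- outer(rows$k_oh, oh) + outer(rows$k_no3, no3) + env$k_dep_gas
    kp <- outer(rows$gamma_o3 * config$c_het, o3) + env$k_dep_particle
    ag <- exp(-kg * dt); ap <- exp(-kp * dt)
    r <- (1 - phi) * ag + phi * ap

    em_kg <- apply(inv$values[, , m, , , drop = FALSE], c(2, 4, 5), sum)
    E <- matrix(em_kg, nsp, ncell) * matrix(conv, nsp, ncell, byrow = TRUE)
    g <- ifelse(kg > 0, E / kg * (1 - ag), E * dt)

    omr <- 1 - r
    exact <- omr > 1e-9
    rN <- r^n_steps
    sum_rn <- ifelse(exact, r * (1 - rN) / omr, n_steps)
    sum_S <- ifelse(exact, (n_steps - sum_rn) / omr, n_steps * (n_steps + 1) / 2)
    C_mean <- (C * sum_rn + g * sum_S) / n_steps
    C <- ifelse(exact, rN * C + g * (1 - rN) / omr, C + g * n_steps)

    if (k > length(months) - 12L) {
      acc$gas <- acc$gas + (1 - phi) * C_mean
      part <- phi * C_mean
      acc$poc <- acc$poc + part * matrix(oc_share, nsp, ncell, byrow = TRUE)
      acc$pbc <- acc$pbc + part * matrix(1 - oc_share, nsp, ncell, byrow = TRUE)
      ratios <- pyr_product_ratios(no3, phi[i_pyr, ], registry, config)
      acc$npah <- acc$npah + C_mean * matrix(ratios$n, nsp, ncell, byrow = TRUE)
      acc$dnpah <- acc$dnpah + C_mean * matrix(ratios$dn, nsp, ncell, byrow = TRUE)
    }
  }

  to_arr <- function(mtx) array(mtx / 12, c(nsp, nlat, nlon),
                                dimnames = list(species, NULL, NULL))
  conc <- array(0, c(nsp, 3L, nlat, nlon),
                dimnames = list(species, c("gas", "particle_oc", "particle_bc"), NULL, NULL))
  conc[, 1, , ] <- to_arr(acc$gas)
  conc[, 2, , ] <- to_arr(acc$poc)
  conc[, 3, , ] <- to_arr(acc$pbc)
  new_pah_state(conc, to_arr(acc$npah), to_arr(acc$dnpah), grid, species)
}

#' Surface burden per species
#'
#' M_i = sum over cells of concentration x cell area x mixing height,
#' converted from ng to kg.  Parents use all-phase concentrations; the
#' known-TEQ degradation products receive their parent's diagnosed
#' NPAH/DNPAH field split evenly among same-parent, same-class products.
#'
#' @param state a `pah_state`.
#' @param areas matrix of cell areas (m^2), from [cell_areas()].
#' @param mixing_height boundary-layer depth (m).
#' @param registry a `pah_registry` (defines the product species).
#' @return named vector of burdens (kg) for parents and products.
#' @export
surface_burden <- function(state, areas, mixing_height,
                           registry = default_species_registry()) {
  stopifnot(all(areas > 0), mixing_height > 0)
  vol <- areas * mixing_height                       # m^3 per cell
  tot <- apply(state$conc, c(1, 3, 4), sum)
  parents <- setNames(
    vapply(seq_along(state$species), function(i) sum(tot[i, , ] * vol), numeric(1)) * 1e-12,
    state$species)
  prod_conc <- product_concentrations(state, registry)
  products <- setNames(
    vapply(seq_len(dim(prod_conc)[1]), function(i) sum(prod_conc[i, , ] * vol), numeric(1)) * 1e-12,
    dimnames(prod_conc)[[1]])
  c(parents, products)
}

#' Concentrations of the known-TEQ degradation-product species
#'
#' Each product species inherits its parent's diagnosed class field (NPAH or
#' DNPAH), split evenly among products sharing the same parent and class.
#' Parents without registered products keep their diagnosed class mass, but
#' it maps to no named product (and so carries no TEQ downstream).
#'
#' @param state a `pah_state`.
#' @param registry a `pah_registry`.
#' @return array (product, nlat, nlon), ng m^-3.
#' @export
product_concentrations <- function(state, registry = default_species_registry()) {
  prods <- product_rows(registry)
  nlat <- length(state$grid$lat); nlon <- length(state$grid$lon)
  out <- array(0, c(nrow(prods), nlat, nlon),
               dimnames = list(prods$abbreviation, NULL, NULL))
  for (i in seq_len(nrow(prods))) {
    par <- prods$parent[i]
    if (!par %in% state$species) next
    n_sib <- sum(prods$parent == par & prods$species_class == prods$species_class[i])
    field <- if (prods$species_class[i] == "NPAH") state$npah else state$dnpah
    out[i, , ] <- field[match(par, state$species), , ] / n_sib
  }
  out
}
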