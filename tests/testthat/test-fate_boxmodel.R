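test_that("partition coefficient follows the documented linear form", {
  cfg <- fate_config()
  reg <- default_species_registry()
  # all-zero descriptors collapse to the bare intercept
  zero_sp <- list(pplfer_l = 0, pplfer_s = 0)
  for (tK in c(260, 298.15, 320)) {
    intercept <- cfg$pplfer_c0 + cfg$pplfer_c1 * (1000 / tK - 1000 / 298.15)
    expect_equal(partition_coefficient(zero_sp, tK), 10^intercept)
  }
  # hand evaluation of the shipped coefficients at the reference temperature:
  # log10 Kp(298.15) = -11.7 + L + 0.2 * S
  bap <- reg["BAP", ]
  expect_equal(log10(partition_coefficient(bap, 298.15)),
               -11.7 + bap$pplfer_l + 0.2 * bap$pplfer_s)
  expect_error(partition_coefficient(bap, 100), "range")
  expect_error(partition_coefficient(list(pplfer_l = NA, pplfer_s = 1), 298),
               "descriptors")
})

test_that("Kp decreases strictly with temperature for every species", {
  reg <- default_species_registry()
  temps <- seq(250, 320, by = 10)
  for (i in which(reg$species_class == "parent")) {
    kp <- partition_coefficient(reg[i, ], temps)
    expect_true(all(diff(kp) < 0))
  }
})

test_that("particulate fraction closed forms are exact", {
  expect_identical(particulate_fraction(0.5, 0), 0)
  expect_identical(particulate_fraction(2, 0.5), 0.5)
  expect_identical(particulate_fraction(0.01, 50), 1 / 3)
  # strictly increasing in PM load
  cpm <- seq(0, 100, by = 5)
  expect_true(all(diff(particulate_fraction(0.02, cpm)) > 0))
})

test_that("step_cell conserves an equilibrated state with no forcing", {
  species <- c("NAP", "PYR", "BAP")
  reg <- default_species_registry()
  env <- toy_env_cell(oh = 0, o3 = 0, no3 = 0, k_dep_gas = 0, k_dep_particle = 0)
  # put the state at its own partitioning equilibrium first
  kp <- vapply(species, function(sp) partition_coefficient(reg[sp, ], env$temperature),
               numeric(1))
  phi <- particulate_fraction(kp, env$oc + env$bc)
  total <- c(NAP = 2, PYR = 1, BAP = 0.5)
  st <- list(gas = (1 - phi) * total,
             particle_oc = phi * total * env$oc / (env$oc + env$bc),
             particle_bc = phi * total * env$bc / (env$oc + env$bc))
  out <- step_cell(st, env, setNames(rep(0, 3), species), dt = 3600, reg)
  expect_equal(out$gas, st$gas)
  expect_equal(out$particle_oc, st$particle_oc)
  expect_equal(out$particle_bc, st$particle_bc)
  st$gas[1] <- -1
  expect_error(step_cell(st, env, setNames(rep(0, 3), species), 3600, reg),
               "negative")
})

test_that("constant emission approaches the E/k steady state", {
  species <- "PHEN"
  reg <- default_species_registry()
  k <- 2e-5
  env <- toy_env_cell(oc = 0, bc = 0, oh = 0, o3 = 0, no3 = 0,
                      k_dep_gas = k, k_dep_particle = 0)
  e_rate <- setNames(1e-4, species)
  st <- toy_cell_state(species)
  for (i in 1:2000) st <- step_cell(st, env, e_rate, dt = 3600, reg)
  expect_equal(unname(st$gas), 1e-4 / k, tolerance = 1e-3)
})

test_that("one analytic step matches a matrix-exponential ODE oracle", {
  skip_if_not_installed("Matrix")
  species <- c("PHEN", "BAP")
  reg <- default_species_registry()
  cfg <- fate_config()
  env <- toy_env_cell()
  st <- toy_cell_state(species, gas = c(3, 0.2), poc = c(0.1, 0.8), pbc = c(0.02, 0.2))
  e_rate <- setNames(c(2e-4, 1e-5), species)
  dt <- 3600
  out <- step_cell(st, env, e_rate, dt, reg, cfg)

  for (i in seq_along(species)) {
    row <- reg[species[i], ]
    kg <- row$k_oh * env$oh + row$k_no3 * env$no3 + env$k_dep_gas
    kp <- row$gamma_o3 * cfg$c_het * env$o3 + env$k_dep_particle
    # augmented linear system d/dt (Cg, Cp, 1) with constant emission source
    a <- rbind(c(-kg, 0, e_rate[i]), c(0, -kp, 0), c(0, 0, 0))
    x0 <- c(st$gas[i], st$particle_oc[i] + st$particle_bc[i], 1)
    x1 <- as.vector(Matrix::expm(a * dt) %*% x0)
    total <- x1[1] + x1[2]
    phi <- particulate_fraction(partition_coefficient(row, env$temperature, cfg),
                                env$oc + env$bc)
    expect_equal(unname(out$gas[i]), (1 - phi) * total, tolerance = 1e-6)
    expect_equal(unname(out$particle_oc[i] + out$particle_bc[i]), phi * total,
                 tolerance = 1e-6)
  }
})

test_that("run_scenario handles degenerate and symmetric inputs", {
  grid <- toy_grid()
  inv <- toy_inventory(fire_kg = NULL, other_kg = NULL, grid = grid)
  env <- uniform_env(grid)
  out <- run_scenario(inv, env)
  expect_true(all(out$conc == 0) && all(out$npah == 0))

  inv_u <- toy_inventory(fire_kg = c(PHEN = 12, BAP = 6), other_kg = NULL, grid = grid)
  out_u <- run_scenario(inv_u, env)
  # uniform world: identical concentration everywhere up to area weighting
  tot <- state_total(out_u)
  per_area <- tot * as.vector(cell_areas(grid))  # emissions were uniform per cell
  expect_equal(max(per_area) / min(per_area), 1, tolerance = 1e-9)
  expect_error(run_scenario(inv_u, uniform_env(pah_grid(6, 6))), "mismatch")
})

test_that("a one-cell trajectory reproduces the iterated step_cell oracle", {
  grid <- toy_grid()
  reg <- default_species_registry()
  species <- c("PHEN", "PYR", "BAP")
  sub <- reg[c(species, "NAP"), ]
  inv <- toy_inventory(fire_kg = c(PHEN = 40, PYR = 10, BAP = 5),
                       other_kg = list(residential = 30), grid = grid)
  env <- uniform_env(grid)
  cfg <- fate_config(dt_seconds = pahfire:::MONTH_SECONDS / 50, spinup_months = 2)
  out <- run_scenario(inv, env, reg, cfg)

  # oracle: literal step_cell loop for one cell, averaging post-step values
  cell <- c(2L, 3L)
  areas <- cell_areas(grid)
  env_cell <- toy_env_cell()
  all_sp <- inv$species
  e_rate <- vapply(all_sp, function(sp) {
    sum(inv$values[, sp, 1, cell[1], cell[2]]) * 1e12 /
      (areas[cell[1], cell[2]] * env$mixing_height * pahfire:::MONTH_SECONDS)
  }, numeric(1))
  st <- toy_cell_state(all_sp)
  months <- c(11:12, 1:12)
  gas_acc <- part_acc <- setNames(rep(0, length(all_sp)), all_sp)
  for (k in seq_along(months)) {
    gas_m <- part_m <- 0
    for (s in 1:50) {
      st <- step_cell(st, env_cell, e_rate, cfg$dt_seconds, reg, cfg)
      gas_m <- gas_m + st$gas
      part_m <- part_m + st$particle_oc + st$particle_bc
    }
    if (k > 2) {
      gas_acc <- gas_acc + gas_m / 50
      part_acc <- part_acc + part_m / 50
    }
  }
  for (sp in species) {
    i <- match(sp, out$species)
    expect_equal(out$conc[i, "gas", cell[1], cell[2]],
                 unname(gas_acc[sp] / 12), tolerance = 1e-10)
    expect_equal(out$conc[i, "particle_oc", cell[1], cell[2]] +
                   out$conc[i, "particle_bc", cell[1], cell[2]],
                 unname(part_acc[sp] / 12), tolerance = 1e-10)
  }
})

test_that("the box model is linear in emissions (superposition)", {
  grid <- toy_grid()
  env <- uniform_env(grid)
  set.seed(21)
  inv_a <- random_inventory(grid)
  inv_b <- random_inventory(grid)
  inv_ab <- inv_a
  inv_ab$values <- inv_a$values + inv_b$values
  s_ab <- run_scenario(inv_ab, env)
  s_sum <- state_total(run_scenario(inv_a, env)) + state_total(run_scenario(inv_b, env))
  expect_equal(state_total(s_ab), s_sum, tolerance = 1e-9)
})

test_that("zero losses give the analytic emission accumulation", {
  grid <- toy_grid()
  env <- uniform_env(grid, oc = 0, bc = 0, oh = 0, o3 = 0, no3 = 0,
                     k_dep_gas = 0, k_dep_particle = 0)
  inv <- toy_inventory(fire_kg = c(PHEN = 24), other_kg = NULL, grid = grid)
  cfg <- fate_config()
  out <- run_scenario(inv, env, config = cfg)
  n <- round(pahfire:::MONTH_SECONDS / cfg$dt_seconds)
  areas <- cell_areas(grid)
  cell <- c(1L, 1L)
  e <- sum(inv$values[, "PHEN", 1, cell[1], cell[2]]) * 1e12 /
    (areas[cell[1], cell[2]] * env$mixing_height * pahfire:::MONTH_SECONDS)
  # linear growth: spin-up leaves 2n steps of stock; month k mean adds
  # (k-1)*n + (n+1)/2 steps of fresh emission
  expected <- e * cfg$dt_seconds * (2 * n + mean((0:11) * n + (n + 1) / 2))
  i <- match("PHEN", out$species)
  expect_equal(out$conc[i, "gas", cell[1], cell[2]], expected, tolerance = 1e-9)
})

test_that("oxidant and PM monotonicity hold", {
  grid <- toy_grid()
  inv <- toy_inventory(fire_kg = c(PHEN = 10, PYR = 10, BAP = 5), grid = grid)
  base <- run_scenario(inv, uniform_env(grid))
  hi_pm <- run_scenario(inv, uniform_env(grid, oc = 20, bc = 4))
  phi_base <- phase_fractions(base)$particle_fraction
  phi_hi <- phase_fractions(hi_pm)$particle_fraction
  expect_gt(phi_hi, phi_base)

  hi_oh <- run_scenario(inv, uniform_env(grid, oh = 5e6))
  expect_lt(sum(state_total(hi_oh, phase = "gas")),
            sum(state_total(base, phase = "gas")))

  # doubling NO3 strictly raises the product:parent ratios (kinetic oracle)
  r1 <- pyr_product_ratios(1e7, 0.1)
  r2 <- pyr_product_ratios(2e7, 0.1)
  expect_gt(r2$n, r1$n)
  expect_gt(r2$dn / r2$n, r1$dn / r1$n)
  hi_no3 <- run_scenario(inv, uniform_env(grid, no3 = 2e7))
  share <- function(s) sum(state_total(s, phase = "npah")) / sum(state_total(s))
  expect_gt(share(hi_no3), share(base))
})

test_that("degradation-product diagnosis is the broadcast ratio rule", {
  grid <- toy_grid()
  st <- pah_state(grid, c("PHEN", "PYR"), gas = array(10, c(2, 4, 4)))
  z <- diagnose_degradation_products(st, 0, 0)
  expect_true(all(z$npah == 0) && all(z$dnpah == 0))
  d <- diagnose_degradation_products(st, 0.04, 0.01)
  expect_equal(unique(as.vector(d$npah)), 0.4)
  expect_equal(unique(as.vector(d$dnpah)), 0.1)
})

test_that("surface burden does the unit arithmetic and matches brute force", {
  grid <- toy_grid()
  reg <- default_species_registry()
  zero <- pah_state(grid, "BAP")
  expect_true(all(surface_burden(zero, cell_areas(grid), 1000, reg) == 0))

  # 1 ng m^-3 x 1e6 m^2 x 1000 m = 1e-3 kg (per cell)
  one <- pah_state(grid, "BAP", gas = array(1, c(1, 4, 4)))
  areas <- matrix(1e6, 4, 4)
  b <- surface_burden(one, areas, 1000, reg)
  expect_equal(b[["BAP"]], 16 * 1e-3)

  set.seed(13)
  st <- pah_state(grid, c("PHEN", "PYR"),
                  gas = array(runif(32), c(2, 4, 4)),
                  particle_oc = array(runif(32), c(2, 4, 4)))
  st <- diagnose_degradation_products(st, 0.02, 0.01)
  areas <- cell_areas(grid)
  b <- surface_burden(st, areas, 800, reg)
  brute <- 0
  for (i in 1:4) for (j in 1:4) {
    brute <- brute + sum(st$conc[1, , i, j]) * areas[i, j] * 800 * 1e-12
  }
  expect_equal(b[["PHEN"]], brute)
  # PYR's two NPAH products split the diagnosed field evenly
  expect_equal(b[["NPYR1"]], b[["NPYR4"]])
})
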