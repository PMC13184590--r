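#' Toxicity table
#'
#' Unit risk for the reference compound benzo[a]pyrene (BAP) together with
#' the toxic equivalency quotients (TEQ) of all species.  The default unit
#' risk, 1.0e-6 per (ng m^-3), is the intermediate animal-study-derived
#' value conventionally used for BAP; the EPA acceptable-risk benchmark for
#' comparison is 1.0e-6.
#'
#' @param registry a `pah_registry` supplying TEQs.
#' @param ur_a_bap unit risk for BAP, per (ng m^-3).
#' @return list of class `pah_toxicity` with `ur_a_bap` and named `teq`.
#' @export
toxicity_table <- function(registry = default_species_registry(),
                           ur_a_bap = 1.0e-6) {
  stopifnot(ur_a_bap > 0)
  teq <- setNames(registry$teq, registry$abbreviation)
  if (is.na(teq["BAP"]) || teq[["BAP"]] != 1) stop("teq[BAP] must be 1")
  if (any(teq < 0, na.rm = TRUE)) stop("teq must be >= 0")
  structure(list(ur_a_bap = ur_a_bap, teq = teq), class = "pah_toxicity")
}

#' Incremental lifetime cancer risk field
#'
#' Per cell, `ILCR = sum over species of UR_A x concentration x TEQ`, with
#' the same TEQ applied to every phase of a species.  Parents contribute
#' through their gas and combined particle phases; the known-TEQ NPAH/DNPAH
#' product species contribute through their diagnosed all-phase
#' concentrations.  Species without a tabulated TEQ contribute zero risk and
#' are reported via a warning.
#'
#' @param state a `pah_state`.
#' @param tox a [toxicity_table()].
#' @param registry a `pah_registry` (defines product species).
#' @return object of class `pah_risk`: `ilcr` matrix plus per-addend arrays
#'   `parent_gas`, `parent_particle` (species x lat x lon), `product`
#'   (product x lat x lon) and `product_class`.
#' @export
compute_ilcr <- function(state, tox = toxicity_table(),
                         registry = default_species_registry()) {
  if (any(state$conc < 0, state$npah < 0, state$dnpah < 0)) {
    stop("negative concentration in state")
  }
  teq_parent <- tox$teq[state$species]
  missing <- state$species[is.na(teq_parent)]
  if (length(missing) > 0L) {
    warning("species without TEQ excluded from ILCR: ", paste(missing, collapse = ", "))
    teq_parent[is.na(teq_parent)] <- 0
  }
  ur <- tox$ur_a_bap
  nlat <- length(state$grid$lat); nlon <- length(state$grid$lon)
  scale_sp <- ur * teq_parent
  gas <- state$conc[, "gas", , , drop = FALSE][, 1, , , drop = FALSE]
  gas <- array(gas, c(length(state$species), nlat, nlon), dimnames = list(state$species, NULL, NULL))
  part <- state$conc[, "particle_oc", , ] + state$conc[, "particle_bc", , ]
  part <- array(part, c(length(state$species), nlat, nlon), dimnames = list(state$species, NULL, NULL))
  parent_gas <- gas * scale_sp
  parent_particle <- part * scale_sp
  prod_conc <- product_concentrations(state, registry)
  prods <- dimnames(prod_conc)[[1]]
  teq_prod <- tox$teq[prods]
  miss_p <- prods[is.na(teq_prod)]
  if (length(miss_p) > 0L) {
    warning("product species without TEQ excluded from ILCR: ", paste(miss_p, collapse = ", "))
    teq_prod[is.na(teq_prod)] <- 0
  }
  product <- prod_conc * (ur * teq_prod)
  ilcr <- apply(parent_gas, c(2, 3), sum) + apply(parent_particle, c(2, 3), sum) +
    apply(product, c(2, 3), sum)
  structure(list(ilcr = ilcr, parent_gas = parent_gas,
                 parent_particle = parent_particle, product = product,
                 product_class = setNames(registry[prods, "species_class"], prods),
                 grid = state$grid),
            class = "pah_risk")
}

#' Toxicity per unit mass of a PAH mixture
#'
#' Burden-weighted mean TEQ: `TPUM = sum(M_i * TEQ_i) / sum(M_i)`.
#' Dimensionless; invariant under uniform rescaling of the burdens and
#' bounded by the minimum and maximum TEQ among species present.
#'
#' @param burdens named vector of surface burdens (kg), e.g. from
#'   [surface_burden()].
#' @param tox a [toxicity_table()].
#' @return scalar TPUM.
#' @export
compute_tpum <- function(burdens, tox = toxicity_table()) {
  m_total <- sum(burdens)
  if (m_total <= 0) stop("zero total burden")
  teq <- tox$teq[names(burdens)]
  if (anyNA(teq)) {
    warning("species without TEQ carry zero toxicity in TPUM: ",
            paste(names(burdens)[is.na(teq)], collapse = ", "))
    teq[is.na(teq)] <- 0
  }
  sum(burdens * teq) / m_total
}

#' Exceedance of an acceptable-risk threshold
#'
#' Strict inequality: a cell exactly at the threshold does not exceed.
#'
#' @param risk a `pah_risk`.
#' @param threshold acceptable-risk limit (default the EPA 1.0e-6 benchmark).
#' @return list with logical `mask` and integer `count`.
#' @export
exceedance <- function(risk, threshold = 1.0e-6) {
  mask <- risk$ilcr > threshold
  list(mask = mask, count = sum(mask))
}

#' Composition shares of a single risk field
#'
#' Area-weighted global shares of one ILCR field: gas versus particle over
#' the parent addends, and parent/NPAH/DNPAH over the total.
#'
#' @param risk a `pah_risk` from [compute_ilcr()].
#' @return list of percentages.
#' @export
risk_shares <- function(risk) {
  grid <- risk$grid
  aws <- function(arr) area_weighted_sum(apply(arr, c(2, 3), sum), grid)
  g <- aws(risk$parent_gas); p <- aws(risk$parent_particle)
  is_np <- risk$product_class == "NPAH"
  np <- aws(risk$product[is_np, , , drop = FALSE])
  dn <- aws(risk$product[!is_np, , , drop = FALSE])
  tot <- g + p + np + dn
  if (tot <= 0) stop("zero total risk")
  list(gas_share = 100 * g / (g + p), particle_share = 100 * p / (g + p),
       parent_share = 100 * (g + p) / tot,
       npah_share = 100 * np / tot, dnpah_share = 100 * dn / tot)
}

#' Decompose fire-attributed cancer risk
#'
#' Fire risk is the per-addend difference baseline minus NoWF; shares are
#' computed over area-weighted global sums.  Two partitions are reported:
#' gas versus particle shares of the parent-species fire ILCR (summing to
#' 100), and parent versus NPAH versus DNPAH shares of the total fire ILCR
#' (summing to 100).
#'
#' @param baseline_risk,nowf_risk matching `pah_risk` objects.
#' @return list with `fire_percent_of_total`, `gas_share_of_fire`,
#'   `particle_share_of_fire`, `parent_share`, `npah_share`, `dnpah_share`.
#' @export
risk_decomposition <- function(baseline_risk, nowf_risk) {
  grid <- baseline_risk$grid
  if (!grids_identical(grid, nowf_risk$grid)) stop("grid mismatch")
  aws <- function(arr) {
    if (length(dim(arr)) == 3L) area_weighted_sum(apply(arr, c(2, 3), sum), grid)
    else area_weighted_sum(arr, grid)
  }
  fire_gas <- aws(baseline_risk$parent_gas) - aws(nowf_risk$parent_gas)
  fire_part <- aws(baseline_risk$parent_particle) - aws(nowf_risk$parent_particle)
  is_np <- baseline_risk$product_class == "NPAH"
  fire_np <- aws(baseline_risk$product[is_np, , , drop = FALSE]) -
    aws(nowf_risk$product[is_np, , , drop = FALSE])
  fire_dn <- aws(baseline_risk$product[!is_np, , , drop = FALSE]) -
    aws(nowf_risk$product[!is_np, , , drop = FALSE])
  fire_total <- fire_gas + fire_part + fire_np + fire_dn
  base_total <- aws(baseline_risk$ilcr)
  if (fire_total <= 0) stop("zero fire-attributed risk: shares undefined")
  list(
    fire_percent_of_total = 100 * fire_total / base_total,
    gas_share_of_fire = 100 * fire_gas / (fire_gas + fire_part),
    particle_share_of_fire = 100 * fire_part / (fire_gas + fire_part),
    parent_share = 100 * (fire_gas + fire_part) / fire_total,
    npah_share = 100 * fire_np / fire_total,
    dnpah_share = 100 * fire_dn / fire_total
  )
}
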