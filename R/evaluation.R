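#' Pair site observations with model grid cells
#'
#' Each observation is matched to the grid cell containing it (equivalently,
#' the nearest cell center on a regular grid); records falling outside the
#' domain are dropped with a message and counted.
#'
#' @param obs data.frame with columns `site_id`, `lat`, `lon`,
#'   `conc_ng_m3`, and optionally `species` and `urban`.
#' @param field matrix (nlat x nlon) of modeled annual-mean concentrations.
#' @param grid the [pah_grid()].
#' @return data.frame of pairs (site_id, species, model, observed, urban)
#'   with attribute `n_dropped`.
#' @export
pair_to_grid <- function(obs, field, grid) {
  if (nrow(obs) == 0L) stop("empty observation list")
  stopifnot(all(obs$conc_ng_m3 >= 0),
            all(obs$lat >= -90 & obs$lat <= 90),
            all(obs$lon >= -180 & obs$lon <= 180))
  i <- match_coord(obs$lat, grid$lat)
  j <- match_coord(obs$lon, grid$lon)
  keep <- !is.na(i) & !is.na(j)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) message(n_dropped, " observation(s) outside the model domain dropped")
  out <- data.frame(
    site_id = obs$site_id[keep],
    species = if (is.null(obs$species)) NA_character_ else obs$species[keep],
    model = field[cbind(i[keep], j[keep])],
    observed = obs$conc_ng_m3[keep],
    urban = if (is.null(obs$urban)) NA else obs$urban[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Normalized mean bias
#'
#' `NMB = 100 * sum(model - observed) / sum(observed)` (percent).  The
#' conventional sum-ratio definition: invariant to pair ordering and never
#' below -100 for non-negative model values.
#'
#' @param pairs data.frame with `model` and `observed` columns (e.g. from
#'   [pair_to_grid()]), or a numeric vector of model values.
#' @param observed observed values when `pairs` is a numeric vector.
#' @return NMB in percent.
#' @export
normalized_mean_bias <- function(pairs, observed = NULL) {
  if (is.data.frame(pairs)) {
    model <- pairs$model
    observed <- pairs$observed
  } else {
    model <- pairs
  }
  stopifnot(length(model) == length(observed))
  s_obs <- sum(observed)
  if (s_obs <= 0) stop("sum of observations must be > 0")
  100 * sum(model - observed) / s_obs
}

#' NMB by group
#'
#' Per-species (or per-weight-class) normalized mean bias from a paired
#' table.
#'
#' @param pairs output of [pair_to_grid()] with a `species` column.
#' @param registry a `pah_registry`, used when `by = "weight_class"`.
#' @param by "species" or "weight_class".
#' @return data.frame (group, n, nmb_percent).
#' @export
nmb_by_group <- function(pairs, registry = default_species_registry(),
                         by = c("species", "weight_class")) {
  by <- match.arg(by)
  grp <- if (by == "species") pairs$species else {
    classify_weight_class(registry[pairs$species, , drop = FALSE])
  }
  rows <- lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel),
               nmb_percent = normalized_mean_bias(pairs[sel, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
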