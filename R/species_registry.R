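#' Load a species table
#'
#' Reads the per-species chemistry/toxicity table: the 16 EPA priority parent
#' PAHs plus nitro- (NPAH) and dinitro- (DNPAH) degradation products.  Lines
#' starting with `#` are treated as a provenance header and skipped.
#'
#' Required columns: `abbreviation`, `full_name`, `ring_count`,
#' `species_class` (one of parent/NPAH/DNPAH), `parent` (linkage for
#' products), `molecular_weight`, `teq`, `k_oh`, `k_no3`, `gamma_o3`,
#' `pplfer_l`, `pplfer_s`.  Missing kinetic columns are filled with zero for
#' product species.
#'
#' @param path CSV file path.
#' @return a `pah_registry` data.frame keyed by abbreviation.
#' @export
load_species_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  reg <- data.table::fread(text = paste(lines, collapse = "\n"),
                           na.strings = c("", "NA"), data.table = FALSE)
  required <- c("abbreviation", "full_name", "ring_count", "species_class",
                "molecular_weight", "teq")
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0L) {
    stop("species table missing required columns: ", paste(missing, collapse = ", "))
  }
  for (col in c("k_oh", "k_no3", "gamma_o3", "pplfer_l", "pplfer_s")) {
    if (is.null(reg[[col]])) reg[[col]] <- 0
    reg[[col]][is.na(reg[[col]]) & reg$species_class != "parent"] <- 0
  }
  if (is.null(reg$parent)) reg$parent <- NA_character_
  reg$parent[reg$parent == ""] <- NA_character_
  validate_registry(reg)
  rownames(reg) <- reg$abbreviation
  class(reg) <- c("pah_registry", "data.frame")
  reg
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$abbreviation)) {
    stop("duplicate abbreviation in species table: ",
         paste(unique(reg$abbreviation[duplicated(reg$abbreviation)]), collapse = ", "))
  }
  bad_class <- setdiff(unique(reg$species_class), c("parent", "NPAH", "DNPAH"))
  if (length(bad_class) > 0L) {
    stop("unknown species_class: ", paste(bad_class, collapse = ", "))
  }
  if (!"BAP" %in% reg$abbreviation) stop("reference species absent (BAP)")
  if (any(is.na(reg$teq)) || any(reg$teq < 0)) stop("teq must be >= 0 for all species")
  if (abs(reg$teq[reg$abbreviation == "BAP"] - 1) > 0) {
    stop("reference species BAP must have teq = 1")
  }
  if (sum(reg$teq == 1) != 1L) {
    stop("exactly one species (BAP) may have teq = 1")
  }
  parents <- reg$species_class == "parent"
  if (any(!reg$ring_count[parents] %in% 2:6)) {
    stop("parent ring_count must be in 2..6")
  }
  kin <- c("k_oh", "k_no3", "gamma_o3")
  if (any(vapply(kin, function(col) any(reg[[col]][parents] < 0), logical(1)))) {
    stop("rate constants must be >= 0")
  }
  prod <- !parents
  if (any(prod) && any(is.na(reg$parent[prod]))) {
    stop("NPAH/DNPAH species must carry a parent linkage")
  }
  if (any(prod) && !all(reg$parent[prod] %in% reg$abbreviation[parents])) {
    stop("product parent linkage refers to an unknown parent")
  }
  invisible(reg)
}

#' Default species registry
#'
#' The packaged 22-species table (16 parents + 6 known-TEQ degradation
#' products). All values are documented assumptions, overridable by passing a
#' user table to [load_species_table()].
#'
#' @return a `pah_registry`.
#' @export
default_species_registry <- function() {
  load_species_table(system.file("extdata", "species_default.csv",
                                 package = "pahfire", mustWork = TRUE))
}

#' Write a species table
#'
#' Round-trips bit-identically through [load_species_table()].
#'
#' @param registry a `pah_registry`.
#' @param path output CSV path.
#' @export
write_species_table <- function(registry, path) {
  data.table::fwrite(as.data.frame(registry), path)
  invisible(path)
}

#' Molecular-weight class of a parent PAH
#'
#' LMW (low molecular weight) PAHs carry two to four aromatic rings, HMW
#' (high molecular weight) PAHs five or six.
#'
#' @param species one or more rows of a `pah_registry`, or a `pah_registry`
#'   subset; all rows must be parents.
#' @return character vector of "LMW"/"HMW".
#' @export
classify_weight_class <- function(species) {
  if (!all(species$species_class == "parent")) {
    stop("weight class is defined for parent PAHs only")
  }
  rc <- species$ring_count
  if (any(!rc %in% 2:6)) stop("ring_count must be in 2..6")
  ifelse(rc <= 4, "LMW", "HMW")
}

parent_rows <- function(registry) {
  registry[registry$species_class == "parent", , drop = FALSE]
}

product_rows <- function(registry) {
  registry[registry$species_class != "parent", , drop = FALSE]
}
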