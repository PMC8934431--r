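#' Z-score standardization
#'
#' Centers and scales by the population (divide-by-n) standard deviation;
#' the convention is recorded in run manifests. A zero-variance column is
#' an error: it cannot be standardized and would poison every composite
#' index built from it.
#'
#' @param column Numeric vector, length >= 2.
#' @param name Optional indicator name used in error messages.
#' @return Vector with mean 0 and population SD 1.
#' @export
zscore <- function(column, name = NULL) {
  if (length(column) < 2) abort_validation("need at least 2 values to z-score")
  if (anyNA(column)) {
    abort_validation(paste0("missing values in ", name %||% "column",
                            " cannot be z-scored"))
  }
  s <- sd_pop(column)
  if (s == 0) {
    abort_validation(paste0(
      "zero standard deviation in function '", name %||% "column",
      "': cannot z-score"
    ))
  }
  (column - mean(column)) / s
}

#' Composite function index
#'
#' Row mean of the z-score matrix over a named subset of functions; used
#' for the plant growth (PGI), soil carbon (SCI), soil nutrient (SNI)
#' sub-indices and, over all 12 functions, the ecosystem
#' multifunctionality index (EMF).
#'
#' @param z Quadrat x function z-score matrix.
#' @param subset Character vector of function names (non-empty, all
#'   present in `colnames(z)`).
#' @return Per-quadrat numeric vector.
#' @export
composite_index <- function(z, subset) {
  if (length(subset) == 0) abort_validation("index subset must be non-empty")
  unknown <- setdiff(subset, colnames(z))
  if (length(unknown) > 0) {
    abort_validation(paste0(
      "unknown function name(s) in index subset: ",
      paste(unknown, collapse = ", ")
    ))
  }
  rowMeans(z[, subset, drop = FALSE])
}

#' Ecosystem multifunctionality and sub-indices
#'
#' Z-scores each of the configured function indicators over the analyzed
#' quadrats (species richness is derived from the species columns) and
#' averages them into the plant growth index (PGI), soil carbon
#' accumulation index (SCI), soil nutrient cycling index (SNI) and, over
#' all functions (12 by default), the ecosystem multifunctionality index
#' (EMF). Z-scores are plain (no polarity reversal): unlike the coupling
#' module, high soil bulk density raises EMF's `sbd` component.
#'
#' @param table A `survey_table`.
#' @param config An [analysis_config()] (its `emf_functions` and
#'   `index_groups` are used).
#' @return Tibble with `quadrat_id`, `pgi`, `sci`, `sni`, `emf`; the
#'   z-score matrix is attached as attribute `"zscores"`.
#' @export
multifunctionality <- function(table, config = analysis_config()) {
  funs <- config$emf_functions
  available <- c(names(table), "sr")
  missing <- setdiff(funs, available)
  if (length(missing) > 0) {
    abort_schema(paste0(
      "survey table lacks configured EMF function(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  raw <- sapply(funs, function(f) {
    if (f == "sr") {
      apply(species_biomass_matrix(table), 1, species_richness)
    } else {
      table[[f]]
    }
  })
  raw <- matrix(as.numeric(raw), nrow = nrow(table),
                dimnames = list(table$quadrat_id, funs))
  z <- raw
  for (f in funs) z[, f] <- zscore(raw[, f], name = f)
  out <- tibble::tibble(
    quadrat_id = table$quadrat_id,
    pgi = composite_index(z, config$index_groups$pgi),
    sci = composite_index(z, config$index_groups$sci),
    sni = composite_index(z, config$index_groups$sni),
    emf = composite_index(z, funs)
  )
  attr(out, "zscores") <- z
  attr(out, "sd_convention") <- "population"
  out
}
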