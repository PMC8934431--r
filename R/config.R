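#' Plant and soil subsystem specification
#'
#' Defines which indicators form the soil and plant subsystems of the
#' coupling model, the polarity of each indicator under min-max
#' standardization, and the contribution weights `alpha` (soil) and
#' `beta` (plant) entering the coordination term.
#'
#' Defaults: soil = SBD (negative polarity: compaction increases with
#' degradation), SM, ST, STC, STN, STP, STS (positive); plant = AGB, BGB,
#' plant density, plant height, species richness (all positive). ST's
#' polarity is a judgement call (warmer topsoil accompanies degraded,
#' sparse swards) and is deliberately configurable.
#'
#' @param soil,plant Named character vectors mapping indicator name to
#'   `"positive"` or `"negative"`.
#' @param alpha,beta Subsystem contribution weights; must sum to 1.
#' @return An object of class `subsystem_spec`.
#' @export
subsystem_spec <- function(soil = c(sbd = "negative", sm = "positive",
                                    st = "positive", stc = "positive",
                                    stn = "positive", stp = "positive",
                                    sts = "positive"),
                           plant = c(agb = "positive", bgb = "positive",
                                     plant_density = "positive",
                                     plant_height = "positive",
                                     sr = "positive"),
                           alpha = 0.5, beta = 0.5) {
  for (side in list(soil = soil, plant = plant)) {
    if (length(side) == 0) abort_schema("subsystem indicator sets must be non-empty")
    if (is.null(names(side)) || any(names(side) == "")) {
      abort_schema("subsystem indicators must be a named polarity vector")
    }
    if (!all(side %in% c("positive", "negative"))) {
      abort_schema("polarity must be 'positive' or 'negative'")
    }
  }
  if (length(intersect(names(soil), names(plant))) > 0) {
    abort_schema("soil and plant indicator sets must be disjoint")
  }
  if (abs(alpha + beta - 1) > 1e-12 || alpha < 0 || beta < 0) {
    abort_schema("alpha and beta must be non-negative and sum to 1")
  }
  structure(
    list(soil = soil, plant = plant, alpha = alpha, beta = beta),
    class = "subsystem_spec"
  )
}

#' Analysis configuration
#'
#' Bundles everything a full run needs: the coupling subsystem spec, the
#' 12 ecosystem-function indicators entering the multifunctionality index,
#' the sub-index groupings (plant growth PGI, soil carbon SCI, soil
#' nutrient SNI), the number of succession stages to cut the Ward tree at,
#' the Mantel permutation count, the RNG seed, and which coupling
#' coordination variant to use (`"product"`: D = C x T; `"sqrt"`:
#' D = sqrt(C x T)).
#'
#' @param subsystem A [subsystem_spec()].
#' @param emf_functions Character vector of the function indicators
#'   averaged into EMF (default: the 12 plant and soil variables).
#' @param index_groups Named list with elements `pgi`, `sci`, `sni`, each
#'   a subset of `emf_functions`.
#' @param n_clusters Number of succession stages (default 4).
#' @param n_permutations Mantel permutation count (default 9999).
#' @param rng_seed Integer seed for all stochastic steps.
#' @param coupling_variant `"product"` or `"sqrt"`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(subsystem = subsystem_spec(),
                            emf_functions = c("agb", "bgb", "sr",
                                              "plant_density", "plant_height",
                                              "st", "sm", "sbd",
                                              "stc", "stn", "stp", "sts"),
                            index_groups = list(
                              pgi = c("agb", "bgb", "plant_density", "plant_height"),
                              sci = "stc",
                              sni = c("stn", "stp", "sts")
                            ),
                            n_clusters = 4L,
                            n_permutations = 9999L,
                            rng_seed = 1L,
                            coupling_variant = c("product", "sqrt")) {
  coupling_variant <- match.arg(coupling_variant)
  if (!inherits(subsystem, "subsystem_spec")) {
    abort_schema("'subsystem' must be a subsystem_spec object")
  }
  if (anyDuplicated(emf_functions)) {
    abort_schema("emf_functions must not contain duplicates")
  }
  if (!all(c("pgi", "sci", "sni") %in% names(index_groups))) {
    abort_schema("index_groups must define pgi, sci and sni")
  }
  extra <- setdiff(unlist(index_groups), emf_functions)
  if (length(extra) > 0) {
    abort_schema(paste0(
      "index_groups contain indicator(s) outside emf_functions: ",
      paste(extra, collapse = ", ")
    ))
  }
  if (n_clusters < 1) abort_schema("n_clusters must be >= 1")
  structure(
    list(
      subsystem = subsystem,
      emf_functions = emf_functions,
      index_groups = index_groups,
      n_clusters = as.integer(n_clusters),
      n_permutations = as.integer(n_permutations),
      rng_seed = as.integer(rng_seed),
      coupling_variant = coupling_variant
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of [analysis_config()]; subsystem polarities
#' are given as nested maps, e.g. `subsystem: {soil: {sbd: negative, ...},
#' plant: {...}, alpha: 0.5, beta: 0.5}`. Absent keys fall back to the
#' defaults.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort_schema(paste0("file not found: ", path))
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$subsystem)) {
    s <- y$subsystem
    sargs <- list()
    if (!is.null(s$soil)) sargs$soil <- unlist(s$soil)
    if (!is.null(s$plant)) sargs$plant <- unlist(s$plant)
    if (!is.null(s$alpha)) sargs$alpha <- s$alpha
    if (!is.null(s$beta)) sargs$beta <- s$beta
    args$subsystem <- do.call(subsystem_spec, sargs)
  }
  for (key in c("emf_functions", "n_clusters", "n_permutations",
                "rng_seed", "coupling_variant")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$index_groups)) args$index_groups <- lapply(y$index_groups, unlist)
  do.call(analysis_config, args)
}
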