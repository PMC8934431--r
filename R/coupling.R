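#' Polarity-aware min-max standardization
#'
#' Rescales an indicator to `[0, 1]` over the analyzed sample. Positive
#' polarity: `(x - min) / (max - min)`; negative polarity (indicators
#' that worsen as they increase, e.g. soil bulk density):
#' `(max - x) / (max - min)`. A constant vector carries no ordering
#' information; it is mapped to 0.5 everywhere with a warning rather than
#' producing 0/0.
#'
#' @param values Numeric vector, length >= 2.
#' @param polarity `"positive"` or `"negative"`.
#' @return Vector in `[0, 1]` attaining 0 and 1 at the sample extremes
#'   (unless constant).
#' @export
minmax_standardize <- function(values, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (length(values) < 2) abort_validation("need at least 2 values to standardize")
  if (anyNA(values)) abort_validation("missing values cannot be standardized")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warn("constant indicator standardized to 0.5 everywhere")
    return(rep(0.5, length(values)))
  }
  if (polarity == "positive") {
    (values - rng[1]) / (rng[2] - rng[1])
  } else {
    (rng[2] - values) / (rng[2] - rng[1])
  }
}

# Assemble the quadrat x indicator matrix for one subsystem, deriving SR
# from the species columns when requested. Min-max bounds are taken over
# the full table (all stages pooled) for cross-stage comparability.
standardize_indicators <- function(table, indicators) {
  raw <- sapply(names(indicators), function(ind) {
    if (ind == "sr") {
      m <- species_biomass_matrix(table)
      apply(m, 1, species_richness)
    } else {
      if (!ind %in% names(table)) {
        abort_schema(paste0("indicator column not found in survey table: ", ind))
      }
      table[[ind]]
    }
  })
  raw <- matrix(as.numeric(raw), nrow = nrow(table),
                dimnames = list(table$quadrat_id, names(indicators)))
  std <- raw
  for (j in seq_along(indicators)) {
    std[, j] <- minmax_standardize(raw[, j], indicators[[j]])
  }
  attr(std, "ranges") <- apply(raw, 2, range)
  attr(std, "polarity") <- indicators
  std
}

#' PCA-derived indicator weights for a subsystem
#'
#' Principal component analysis of the standardized indicator matrix on
#' the correlation scale: components with eigenvalue >= 1 are retained
#' (at least one), each retained component receives its variance share
#' among the retained set, and the raw weight of indicator *i* is the
#' variance-share-weighted sum of its absolute loadings
#' (eigenvector x sqrt(eigenvalue)). Weights are normalized to sum to 1.
#'
#' @param standardized Quadrat x indicator matrix for one subsystem
#'   (>= 3 quadrats). A single-indicator subsystem gets weight 1 without
#'   PCA.
#' @return Named non-negative weights summing to 1.
#' @export
pca_weights <- function(standardized) {
  standardized <- as.matrix(standardized)
  p <- ncol(standardized)
  if (p == 1) {
    return(setNames(1, colnames(standardized)))
  }
  if (nrow(standardized) < 3) {
    abort_validation("pca_weights needs at least 3 quadrats")
  }
  sds <- apply(standardized, 2, sd)
  if (any(sds == 0)) {
    abort_validation(paste0(
      "zero-variance indicator column(s): ",
      paste(colnames(standardized)[sds == 0], collapse = ", ")
    ))
  }
  ee <- eigen(cor(standardized), symmetric = TRUE)
  keep <- which(ee$values >= 1)
  if (length(keep) == 0) keep <- 1L
  shares <- ee$values[keep] / sum(ee$values[keep])
  loadings <- ee$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ee$values[keep]), nrow = length(keep))
  raw <- as.vector(abs(loadings) %*% shares)
  setNames(raw / sum(raw), colnames(standardized))
}

#' Subsystem integral
#'
#' Weighted sum of a quadrat's standardized indicator values; with
#' weights summing to 1 and values in `[0, 1]` the integral lies in
#' `[0, 1]`.
#'
#' @param values Standardized indicator vector (one quadrat) or a
#'   quadrat x indicator matrix.
#' @param weights Non-negative weights summing to 1, in column order.
#' @return Scalar (or per-quadrat vector) in `[0, 1]`.
#' @export
subsystem_integral <- function(values, weights) {
  if (abs(sum(weights) - 1) > 1e-8) {
    abort_validation("weights must sum to 1")
  }
  if (is.matrix(values)) {
    if (ncol(values) != length(weights)) abort_validation("length mismatch between values and weights")
    return(as.vector(values %*% weights))
  }
  if (length(values) != length(weights)) {
    abort_validation("length mismatch between values and weights")
  }
  sum(values * weights)
}

#' Coupling coordination degree
#'
#' From subsystem integrals `S` (soil) and `P` (plant), both in `[0, 1]`:
#' the coupling degree `C = 2 * sqrt(S * P) / (S + P)` (defined as 0 when
#' `S + P = 0`) measures balance and equals 1 iff `S = P`; the
#' coordination `T = alpha * S + beta * P` measures joint level; and the
#' coupling coordination degree is `D = C * T` (`variant = "product"`)
#' or the classical `D = sqrt(C * T)` (`variant = "sqrt"`). All outputs
#' lie in `[0, 1]`.
#'
#' @param s,p Subsystem integrals in `[0, 1]` (vectorized).
#' @param alpha,beta Contribution weights summing to 1 (default 0.5/0.5).
#' @param variant `"product"` or `"sqrt"`.
#' @return Tibble with columns `C`, `T`, `D`.
#' @export
coupling_coordination <- function(s, p, alpha = 0.5, beta = 0.5,
                                  variant = c("product", "sqrt")) {
  variant <- match.arg(variant)
  if (any(s < 0 | s > 1) || any(p < 0 | p > 1)) {
    abort_validation("subsystem integrals must lie in [0, 1]")
  }
  if (abs(alpha + beta - 1) > 1e-12) {
    abort_validation("alpha + beta must equal 1")
  }
  denom <- s + p
  c_deg <- ifelse(denom == 0, 0, 2 * sqrt(s * p) / denom)
  t_coord <- alpha * s + beta * p
  d <- switch(variant,
    product = c_deg * t_coord,
    sqrt = sqrt(c_deg * t_coord)
  )
  tibble::tibble(C = c_deg, T = t_coord, D = d)
}

#' Per-quadrat plant-soil coupling
#'
#' Full coupling pipeline over a survey: min-max standardization of the
#' subsystem indicators with their configured polarities (bounds pooled
#' over all quadrats), PCA weights per subsystem, subsystem integrals
#' `S(X)` and `P(Y)`, and the coupling coordination degree.
#'
#' @param table A `survey_table`.
#' @param config An [analysis_config()] (its `subsystem` and
#'   `coupling_variant` are used).
#' @return Tibble with columns `quadrat_id`, `S`, `P`, `C`, `T`, `D`, and
#'   attributes `weights` (per-subsystem PCA weights) and `polarity`.
#' @export
coupling_indices <- function(table, config = analysis_config()) {
  spec <- config$subsystem
  soil_std <- standardize_indicators(table, spec$soil)
  plant_std <- standardize_indicators(table, spec$plant)
  w_soil <- pca_weights(soil_std)
  w_plant <- pca_weights(plant_std)
  s <- subsystem_integral(soil_std, w_soil)
  p <- subsystem_integral(plant_std, w_plant)
  ctd <- coupling_coordination(s, p, spec$alpha, spec$beta,
                               config$coupling_variant)
  out <- tibble::tibble(
    quadrat_id = table$quadrat_id,
    S = s, P = p, C = ctd$C, T = ctd$T, D = ctd$D
  )
  attr(out, "weights") <- list(soil = w_soil, plant = w_plant)
  attr(out, "polarity") <- list(soil = spec$soil, plant = spec$plant)
  out
}
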