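#' Species richness of a quadrat
#'
#' Counts the species recorded with biomass strictly greater than zero; a
#' biomass of 0 means "recorded absent" and a missing cell means "not
#' assessed", neither of which contributes to richness.
#'
#' @param biomass Named numeric vector of per-species biomass, or one row
#'   of [species_biomass_matrix()].
#' @return Integer species count (0 for an empty record).
#' @export
species_richness <- function(biomass) {
  if (length(biomass) == 0) return(0L)
  sum(biomass > 0, na.rm = TRUE)
}

#' Gamma diversity of a succession stage
#'
#' Size of the union of species recorded with positive biomass over all
#' quadrats belonging to `stage`.
#'
#' @param table A `survey_table` with a `stage` column.
#' @param stage Stage label to pool over.
#' @return Integer species count.
#' @export
gamma_diversity <- function(table, stage) {
  if (!"stage" %in% names(table)) {
    abort_schema("survey table has no 'stage' column")
  }
  idx <- which(table$stage == stage)
  if (length(idx) == 0) {
    abort_validation(paste0("no quadrats with stage label: ", stage))
  }
  m <- species_biomass_matrix(table)[idx, , drop = FALSE]
  sum(colSums(m > 0, na.rm = TRUE) > 0)
}

#' Camargo evenness
#'
#' Pairwise-difference evenness over the species present in the quadrat:
#' \deqn{E = 1 - \sum_{i<j} |P_i - P_j| / S}
#' where \eqn{P_i} is the biomass proportion of species \eqn{i} and
#' \eqn{S} the number of species with positive biomass. Absent species are
#' excluded so that the index is independent of the species universe.
#' `E = 1` exactly when all included proportions are equal, and
#' `0 < E <= 1` always.
#'
#' @param biomass Numeric vector of per-species biomass; zeros and `NA`s
#'   are dropped before computing proportions.
#' @return Scalar evenness in (0, 1].
#' @export
camargo_evenness <- function(biomass) {
  b <- biomass[!is.na(biomass) & biomass > 0]
  if (length(b) == 0) {
    abort_validation("camargo_evenness is undefined for an all-zero biomass vector")
  }
  p <- sort(b / sum(b))
  s <- length(p)
  # sum over unordered pairs of |Pi - Pj|, via the sorted-coefficient identity
  pair_sum <- sum((2 * seq_len(s) - s - 1) * p)
  1 - pair_sum / s
}

#' Functional-group biomass shares of a quadrat
#'
#' @param biomass Named numeric vector of per-species biomass.
#' @param fg_map Named character vector mapping species to one of
#'   `sedge, grass, desirable_forb, toxic_forb, shrub`. Every species with
#'   positive biomass must be mapped.
#' @return Named numeric over all five groups, summing to 1.
#' @export
functional_group_shares <- function(biomass, fg_map) {
  b <- biomass[!is.na(biomass) & biomass > 0]
  if (length(b) == 0) {
    abort_validation("functional_group_shares needs at least one positive biomass")
  }
  unmapped <- setdiff(names(b), names(fg_map))
  if (length(unmapped) > 0) {
    abort_validation(paste0(
      "species not covered by the functional-group map: ",
      paste(unmapped, collapse = ", ")
    ))
  }
  groups <- fg_map[names(b)]
  shares <- setNames(numeric(length(.functional_groups)), .functional_groups)
  agg <- tapply(b, groups, sum)
  shares[names(agg)] <- agg
  shares / sum(shares)
}

#' Per-quadrat community summary
#'
#' Species richness, Camargo evenness, functional-group biomass shares and
#' the toxic-plant share for every quadrat of a survey.
#'
#' @param table A `survey_table`.
#' @param fg_map Species-to-group map, e.g. [templates_fg_map()].
#' @return Tibble with columns `quadrat_id`, `sr`, `ev`, one `share_*`
#'   column per functional group, and `toxic_share`.
#' @export
community_summary <- function(table, fg_map) {
  m <- species_biomass_matrix(table)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    b <- m[i, ]
    shares <- functional_group_shares(b, fg_map)
    tibble::tibble(
      quadrat_id = table$quadrat_id[i],
      sr = species_richness(b),
      ev = camargo_evenness(b),
      !!!setNames(as.list(shares), paste0("share_", names(shares))),
      toxic_share = shares[["toxic_forb"]]
    )
  })
  dplyr::bind_rows(rows)
}
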