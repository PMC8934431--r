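#' Feature matrix for succession-stage clustering
#'
#' Default features are the five functional-group biomass shares plus
#' canopy height: composition carries the succession signal (the series
#' is quantified by functional-group biomass ratios), and mean plant
#' height tracks the tall-erect to short-prostrate growth-form axis of
#' the same series. Height is z-scored and then rescaled to the mean
#' standard deviation of the share columns, so the compositional block
#' keeps the dominant say in the Euclidean geometry — structural
#' covariates left at unit variance would drown shares that live on a
#' 0-1 scale. Constant columns are dropped with a warning (they carry no
#' clustering information and would break z-scoring).
#'
#' @param table A `survey_table`.
#' @param fg_map Species-to-group map.
#' @return Numeric matrix, rows named by `quadrat_id`; column names
#'   document the features used (`share_*` plus `z_plant_height`).
#' @export
feature_matrix <- function(table, fg_map) {
  comm <- community_summary(table, fg_map)
  out <- cbind(
    as.matrix(comm[, c(paste0("share_", .functional_groups))]),
    z_plant_height = table$plant_height
  )
  rownames(out) <- comm$quadrat_id
  keep <- apply(out, 2, function(v) sd(v) > 0)
  if (any(!keep)) {
    warn(paste0(
      "dropping constant feature column(s): ",
      paste(colnames(out)[!keep], collapse = ", ")
    ))
    out <- out[, keep, drop = FALSE]
  }
  share_cols <- grep("^share_", colnames(out), value = TRUE)
  share_scale <- if (length(share_cols) > 0) {
    mean(apply(out[, share_cols, drop = FALSE], 2, sd))
  } else {
    1
  }
  if ("z_plant_height" %in% colnames(out)) {
    ph <- out[, "z_plant_height"]
    out[, "z_plant_height"] <- share_scale * (ph - mean(ph)) / sd(ph)
  }
  out
}

#' Ward agglomerative clustering of quadrats
#'
#' Agglomerative clustering under the Ward minimum-increase-in-within-
#' cluster-variance criterion on Euclidean distances (the `ward.D2`
#' Lance-Williams update), cut at `k` clusters. Cluster labels are
#' arbitrary until ordered by [order_stages()].
#'
#' @param features Matrix from [feature_matrix()] (rows named by quadrat).
#' @param k Number of clusters, `1 <= k <= nrow(features)`.
#' @return A `stage_assignment`: list with `labels` (named integer
#'   vector), `k`, and the `hclust` merge tree (`merge`, `height`).
#' @export
ward_cluster <- function(features, k) {
  n <- nrow(features)
  if (k < 1) abort_validation("k must be >= 1")
  if (k > n) abort_validation(paste0("k (", k, ") exceeds the number of quadrats (", n, ")"))
  hc <- hclust(dist(features), method = "ward.D2")
  labels <- cutree(hc, k = k)
  names(labels) <- rownames(features)
  structure(
    list(labels = labels, k = as.integer(k),
         merge = hc$merge, height = hc$height, hclust = hc),
    class = "stage_assignment"
  )
}

#' Order clusters into the succession sequence
#'
#' Ranks clusters by descending mean sedge biomass share (the sedge
#' community is the least-disturbed end of the series), breaking ties by
#' ascending mean toxic-forb share, then by cluster label. Rank r becomes
#' stage r.
#'
#' @param assignment A `stage_assignment` from [ward_cluster()].
#' @param table The `survey_table` the features came from.
#' @param fg_map Species-to-group map.
#' @return The assignment with `stage_of_cluster` (named integer map) and
#'   `stage` (per-quadrat stage, named by quadrat_id) added.
#' @export
order_stages <- function(assignment, table, fg_map) {
  if (!inherits(assignment, "stage_assignment")) {
    abort_schema("'assignment' must come from ward_cluster()")
  }
  comm <- community_summary(table, fg_map)
  labels <- assignment$labels[comm$quadrat_id]
  sedge <- tapply(comm$share_sedge, labels, mean)
  toxic <- tapply(comm$share_toxic_forb, labels, mean)
  cl <- as.integer(names(sedge))
  ord <- order(-sedge, toxic, cl)
  stage_of_cluster <- setNames(seq_along(ord), names(sedge)[ord])
  if (anyDuplicated(round(sedge, 12)) && anyDuplicated(round(toxic, 12))) {
    inform("stage ordering tie broken by cluster label order")
  }
  assignment$stage_of_cluster <- stage_of_cluster
  assignment$stage <- setNames(
    as.integer(stage_of_cluster[as.character(assignment$labels)]),
    names(assignment$labels)
  )
  assignment
}

#' Assign succession stages to every quadrat
#'
#' Convenience wrapper: [feature_matrix()] then [ward_cluster()] then
#' [order_stages()].
#'
#' @param table A `survey_table`.
#' @param fg_map Species-to-group map.
#' @param k Number of stages (default 4).
#' @return Tibble with `quadrat_id`, `cluster`, `stage`.
#' @export
assign_stages <- function(table, fg_map, k = 4) {
  feats <- feature_matrix(table, fg_map)
  asg <- order_stages(ward_cluster(feats, k), table, fg_map)
  tibble::tibble(
    quadrat_id = names(asg$labels),
    cluster = as.integer(asg$labels),
    stage = asg$stage[names(asg$labels)]
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, about 0 for independent ones. Used to score
#' recovery of generator ground-truth stages.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort_schema("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
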