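# Shared fixtures and independent oracles for the test suite.

# A tiny two-quadrat survey with three species, built in code.
tiny_survey <- function() {
  as_survey_table(tibble::tibble(
    quadrat_id = c("q1", "q2"),
    transect_id = c("t1", "t1"),
    stage = c(1L, 2L),
    agb = c(4.5, 2.0),
    bgb = c(10, 8),
    plant_density = c(50, 40),
    plant_height = c(12, 9),
    sbd = c(0.9, 1.0),
    sm = c(30, 28),
    st = c(12, 13),
    stc = c(50, 45),
    stn = c(4.2, 3.8),
    stp = c(0.9, 0.8),
    sts = c(0.8, 0.7),
    `sp:Kobresia graminifolia` = c(3.0, 0.0),
    `sp:Elymus nutans` = c(1.0, 1.5),
    `sp:Gentiana macrophylla` = c(0.5, 0.5)
  ))
}

tiny_fg_map <- function() {
  c("Kobresia graminifolia" = "sedge",
    "Elymus nutans" = "grass",
    "Gentiana macrophylla" = "toxic_forb")
}

# Random covariate block for hand-built surveys.
random_survey <- function(n, n_species = 6, seed = 1) {
  withr::with_seed(seed, {
    sp <- matrix(rexp(n * n_species), n, n_species)
    colnames(sp) <- paste0("sp:species_", seq_len(n_species))
    as_survey_table(dplyr::bind_cols(
      tibble::tibble(
        quadrat_id = sprintf("q%03d", seq_len(n)),
        transect_id = "t1",
        stage = rep_len(1:2, n),
        agb = rowSums(sp),
        bgb = runif(n, 5, 20), plant_density = runif(n, 20, 80),
        plant_height = runif(n, 5, 20), sbd = runif(n, 0.7, 1.3),
        sm = runif(n, 20, 40), st = runif(n, 10, 16),
        stc = runif(n, 30, 70), stn = runif(n, 2, 6),
        stp = runif(n, 0.5, 1.2), sts = runif(n, 0.4, 1.0)
      ),
      tibble::as_tibble(sp)
    ))
  })
}

# --- independent oracles -------------------------------------------------

# Greedy brute-force Ward: at every step, merge the pair of clusters whose
# union minimizes the increase in total within-cluster sum of squares.
# Returns the list of partitions (membership vectors) after each merge.
brute_force_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  ess <- function(rows) {
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_delta <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        delta <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (delta < best_delta) {
          best_delta <- delta
          best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    membership <- integer(n)
    for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- membership
  }
  partitions
}

# All permutations of 1..n (n small), for exhaustive Mantel enumeration.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (perm in all_permutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(perm, n, after = pos - 1)
    }
  }
  out
}

# Exhaustive one-sided Mantel p-value over all n! simultaneous
# row/column permutations; the identity is part of the enumeration, so
# the count includes the observed statistic itself.
mantel_exact_p <- function(a, b) {
  ut <- upper.tri(a)
  va <- a[ut]
  r_obs <- cor(va, b[ut])
  perms <- all_permutations(nrow(a))
  rs <- vapply(perms, function(idx) {
    bp <- b[idx, idx]
    cor(va, bp[ut])
  }, numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# Naive LMG: average the R^2 increase of each predictor over every
# ordering, fitting each nested model with lm().
lmg_naive <- function(x, y) {
  x <- as.matrix(x)
  p <- ncol(x)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(lm(y ~ x[, cols, drop = FALSE]))$r.squared
  }
  orders <- all_permutations(p)
  shares <- numeric(p)
  for (ord in orders) {
    before <- integer(0)
    for (j in ord) {
      shares[j] <- shares[j] + r2(c(before, j)) - r2(before)
      before <- c(before, j)
    }
  }
  setNames(shares / length(orders), colnames(x))
}

random_distance_matrix <- function(n) {
  pts <- matrix(rnorm(n * 2), n, 2)
  as.matrix(dist(pts))
}
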