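#' One-way ANOVA with Tukey HSD letters
#'
#' Fixed-effects one-way ANOVA of `values` on `groups`, pairwise Tukey
#' honestly-significant-difference p-values from the studentized-range
#' distribution on the pooled within-group variance, and a compact letter
#' display (insert-and-absorb) at level `alpha`: groups sharing a letter
#' are not significantly different.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @param alpha Family-wise significance level for the letters.
#' @return List with `summary` (per-group n/mean/sd/letters tibble),
#'   `f_value`, `p_value`, `df`, `pairwise` (tibble of group pairs with
#'   differences and adjusted p), and `alpha`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  counts <- table(groups)
  if (length(counts) < 2) abort_validation("need at least 2 groups")
  if (any(counts < 2)) {
    abort_validation(paste0(
      "group(s) with fewer than 2 observations: ",
      paste(names(counts)[counts < 2], collapse = ", ")
    ))
  }
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, "groups")$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- tibble::tibble(
    group_a = vapply(pairs, `[`, character(1), 2),
    group_b = vapply(pairs, `[`, character(1), 1),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"])
  )
  lev <- levels(groups)
  pmat <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$group_a[i]; b <- pairwise$group_b[i]
    pmat[a, b] <- pmat[b, a] <- pairwise$p_adj[i]
  }
  letters_ <- compact_letters(pmat, alpha)
  summary_tbl <- tibble::tibble(
    group = lev,
    n = as.integer(counts[lev]),
    mean = as.numeric(tapply(values, groups, mean)[lev]),
    sd = as.numeric(tapply(values, groups, sd)[lev]),
    letters = unname(letters_[lev])
  )
  list(
    summary = summary_tbl,
    f_value = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]),
    pairwise = pairwise,
    alpha = alpha
  )
}

# Insert-and-absorb compact letter display. Starts from one letter
# containing every group; each significant pair splits the letters that
# contain both; letters that become subsets of another are absorbed.
# Groups keep the level order, so ties resolve by ascending stage number.
compact_letters <- function(pmat, alpha) {
  lev <- rownames(pmat)
  cols <- list(lev)
  sig <- which(pmat < alpha & upper.tri(pmat), arr.ind = TRUE)
  if (nrow(sig) > 0) {
    for (s in seq_len(nrow(sig))) {
      a <- lev[sig[s, 1]]; b <- lev[sig[s, 2]]
      new_cols <- list()
      for (col in cols) {
        if (all(c(a, b) %in% col)) {
          new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[j] &&
              all(new_cols[[i]] %in% new_cols[[j]]) &&
              !(length(new_cols[[i]]) == length(new_cols[[j]]) && i < j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # order letters by the first (in level order) group they contain
  first <- vapply(cols, function(col) min(match(col, lev)), numeric(1))
  cols <- cols[order(first)]
  out <- setNames(rep("", length(lev)), lev)
  for (i in seq_along(cols)) {
    for (g in cols[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with the two-sided slope test;
#' R-squared equals the squared Pearson correlation.
#'
#' @param x,y Numeric vectors (>= 3 points, `var(x) > 0`).
#' @return Tibble with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
simple_regression <- function(x, y) {
  if (length(x) != length(y)) abort_validation("x and y differ in length")
  if (length(x) < 3) abort_validation("need at least 3 points")
  if (var(x) == 0) abort_validation("x has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  tibble::tibble(
    slope = co["x", "Estimate"],
    intercept = co["(Intercept)", "Estimate"],
    r_squared = sm$r.squared,
    p_value = if (nrow(co) > 1) co["x", "Pr(>|t|)"] else NA_real_,
    n = length(x)
  )
}

#' Mantel permutation test
#'
#' Pearson correlation `r` between the upper-triangle entries of two
#' distance matrices, with a one-sided permutation p-value under
#' simultaneous row/column permutation of the second matrix:
#' `p = (1 + #{permuted r >= observed r}) / (1 + n_perm)`.
#'
#' @param d_a,d_b Symmetric zero-diagonal distance matrices (or `dist`
#'   objects) of equal dimension >= 4.
#' @param n_perm Number of permutations (default 9999); ignored when
#'   `exact = TRUE`.
#' @param seed Optional integer seed for the permutation stream.
#' @param exact Enumerate all `n!` permutations instead of sampling
#'   (feasible for n <= 8); `p` is then the exact fraction of
#'   permutations with `r >= observed` (the identity counts itself, so
#'   the smallest attainable p is `1/n!`).
#' @return List of class `mantel_result` with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(d_a, d_b, n_perm = 9999, seed = NULL, exact = FALSE) {
  a <- as_distance_matrix(d_a, "d_a")
  b <- as_distance_matrix(d_b, "d_b")
  n <- nrow(a)
  if (nrow(b) != n) abort_validation("distance matrices differ in dimension")
  if (n < 4) abort_validation("need at least 4 observations")
  ut <- upper.tri(a)
  va <- a[ut]
  r_obs <- cor(va, b[ut])
  if (exact) {
    if (n > 8) abort_validation("exact enumeration supported only for n <= 8")
    perms <- permutations_of(n)
    rs <- vapply(perms, function(idx) {
      bp <- b[idx, idx]
      cor(va, bp[ut])
    }, numeric(1))
    return(structure(
      list(r = r_obs, p = mean(rs >= r_obs - 1e-12),
           n_perm = length(perms), seed = NULL),
      class = "mantel_result"
    ))
  }
  count <- 0L
  local_seed(seed, {
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n)
      bp <- b[idx, idx]
      if (cor(va, bp[ut]) >= r_obs) count <- count + 1L
    }
  })
  structure(
    list(r = r_obs, p = (1 + count) / (1 + n_perm),
         n_perm = as.integer(n_perm), seed = seed),
    class = "mantel_result"
  )
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 0
  for (sub in permutations_of(n - 1)) {
    for (pos in 0:(n - 1)) {
      k <- k + 1
      out[[k]] <- append(sub, n, after = pos)
    }
  }
  out
}

as_distance_matrix <- function(d, arg) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort_validation(paste0(arg, " must be a square distance matrix"))
  }
  if (max(abs(d - t(d))) > 1e-10) {
    abort_validation(paste0(arg, " is not symmetric"))
  }
  if (any(abs(diag(d)) > 1e-10)) {
    abort_validation(paste0(arg, " has a non-zero diagonal"))
  }
  d
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' @param columns Data frame or named list of equal-length numeric
#'   vectors (>= 3 observations). Zero-variance columns are flagged and
#'   their correlations set to `NA` rather than returned as silent NaN.
#' @return List with `r` (unit-diagonal correlation matrix), `p`
#'   (two-sided p-values, `NA` diagonal), and `flagged` (names of
#'   zero-variance columns).
#' @export
correlation_matrix <- function(columns) {
  df <- as.data.frame(columns)
  if (nrow(df) < 3) abort_validation("need at least 3 observations")
  vars <- names(df)
  k <- length(vars)
  flagged <- vars[vapply(df, function(v) var(v) == 0, logical(1))]
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (vars[i] %in% flagged || vars[j] %in% flagged) next
      ct <- cor.test(df[[i]], df[[j]], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  if (length(flagged) > 0) {
    warn(paste0("zero-variance column(s) flagged: ",
                paste(flagged, collapse = ", ")))
  }
  list(r = r, p = p, flagged = flagged)
}

#' Relative importance by averaging over orderings (LMG)
#'
#' Decomposes the R-squared of the linear model of `y` on all columns of
#' `x` into non-negative per-predictor shares: the share of predictor *j*
#' is the average, over all orderings of the predictors, of the
#' R-squared increase when *j* enters the model. Computed by subset
#' enumeration with ordering-count weights, so it is exact.
#'
#' @param x Numeric predictor matrix or data frame (<= 12 columns;
#'   `n > p + 2`; full column rank with the intercept).
#' @param y Numeric response.
#' @return List with `shares` (named, summing to the full-model
#'   R-squared) and `r_squared`.
#' @export
lmg_importance <- function(x, y) {
  x <- as.matrix(x)
  p <- ncol(x)
  n <- nrow(x)
  if (p < 1) abort_validation("need at least one predictor")
  if (p > 12) abort_validation("subset enumeration supports at most 12 predictors")
  if (n != length(y)) abort_validation("x and y differ in length")
  if (n <= p + 2) abort_validation("need n > p + 2 observations")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (qr(cbind(1, x))$rank < p + 1) {
    abort_validation(paste0(
      "predictor matrix is collinear to singularity; ",
      "remove redundant predictors"
    ))
  }
  tss <- sum((y - mean(y))^2)
  n_subsets <- bitwShiftL(1L, p)
  r2 <- numeric(n_subsets)  # r2[mask + 1] = R^2 of that predictor subset
  for (mask in seq_len(n_subsets - 1)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0)
    fit <- lm.fit(cbind(1, x[, cols, drop = FALSE]), y)
    r2[mask + 1] <- 1 - sum(fit$residuals^2) / tss
  }
  # weight of a subset of size s among orderings: s! (p-s-1)! / p!
  size_weight <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - 0:(p - 1)) -
                       lfactorial(p))
  shares <- setNames(numeric(p), colnames(x))
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(n_subsets - 1)) {
      if (bitwAnd(mask, bit_j) != 0) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0)
      shares[j] <- shares[j] +
        size_weight[s + 1] * (r2[bitwOr(mask, bit_j) + 1] - r2[mask + 1])
    }
  }
  list(shares = shares, r_squared = r2[n_subsets])
}
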