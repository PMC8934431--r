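test_that("Tukey letters separate overwhelming group differences", {
  withr::with_seed(3, {
    y <- c(rnorm(30, 0, 0.01), rnorm(30, 10, 0.01),
           rnorm(30, 20, 0.01), rnorm(30, 30, 0.01))
    g <- rep(1:4, each = 30)
  })
  res <- anova_tukey(y, g)
  expect_true(all(res$pairwise$p_adj < 1e-6))
  expect_equal(sort(res$summary$letters), c("a", "b", "c", "d"))
  expect_lt(res$p_value, 1e-10)
})

test_that("identical groups share one letter", {
  y <- rep(c(1, 2, 3), times = 4)
  g <- rep(1:4, each = 3)
  res <- anova_tukey(y, g)
  expect_true(all(res$pairwise$p_adj > 0.99))
  expect_true(all(res$summary$letters == "a"))
  expect_error(anova_tukey(c(1, 2, 3), c(1, 1, 2)),
               class = "meadowsucc_validation_error")
})

test_that("Tukey at two groups equals the pooled two-sample t-test", {
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- rnorm(sample(5:15, 1), mean = runif(1, 0, 2))
      b <- rnorm(sample(5:15, 1))
      res <- anova_tukey(c(a, b), rep(1:2, c(length(a), length(b))))
      tt <- t.test(a, b, var.equal = TRUE)
      # ptukey's quadrature is accurate to ~1e-7, hence the tolerance
      expect_equal(res$pairwise$p_adj, tt$p.value, tolerance = 1e-5)
    }
  })
})

test_that("letters are invariant to group relabeling", {
  withr::with_seed(7, {
    y <- c(rnorm(20, 0), rnorm(20, 0.2), rnorm(20, 5))
    g <- rep(c("x", "y", "z"), each = 20)
  })
  res1 <- anova_tukey(y, g)
  relab <- c(x = "z", y = "x", z = "y")[g]
  res2 <- anova_tukey(y, relab)
  m1 <- setNames(res1$summary$letters, res1$summary$group)
  m2 <- setNames(res2$summary$letters, res2$summary$group)
  # groups sharing letters before must share letters after
  share1 <- outer(m1[c("x", "y", "z")], m1[c("x", "y", "z")],
                  Vectorize(function(a, b) any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])))
  share2 <- outer(m2[c("z", "x", "y")], m2[c("z", "x", "y")],
                  Vectorize(function(a, b) any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])))
  expect_equal(unname(share1), unname(share2))
})

test_that("simple regression reproduces hand OLS", {
  x <- c(0, 1, 2)
  # suppressed: lm warns about the (intentional) perfect fits
  exact <- suppressWarnings(simple_regression(c(1, 3, 5), 2 * c(1, 3, 5) + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)

  flat <- suppressWarnings(simple_regression(x, c(4, 4, 4)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  hand <- simple_regression(x, c(0, 1, 1))
  expect_equal(hand$slope, 0.5, tolerance = 1e-12)
  expect_equal(hand$r_squared, 0.75, tolerance = 1e-12)

  expect_error(simple_regression(c(1, 1, 1), c(1, 2, 3)),
               class = "meadowsucc_validation_error")
})

test_that("Mantel r and p behave at the identity and match enumeration", {
  withr::with_seed(11, d <- random_distance_matrix(6))
  res <- mantel_test(d, d, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_lte(res$p, 0.05)
  # exact enumeration: only the identity reaches r = 1 for generic points
  expect_equal(mantel_test(d, d, exact = TRUE)$p, 1 / factorial(6))

  # exact enumeration at n = 4 matches the independent oracle
  withr::with_seed(13, {
    for (i in 1:10) {
      a <- random_distance_matrix(4)
      b <- random_distance_matrix(4)
      res <- mantel_test(a, b, exact = TRUE)
      expect_equal(res$p, mantel_exact_p(a, b), tolerance = 1e-12)
      expect_equal(res$n_perm, 24)
    }
  })

  # r agrees with the vegan reference implementation
  skip_if_not_installed("vegan")
  withr::with_seed(17, {
    a <- random_distance_matrix(10)
    b <- random_distance_matrix(10)
  })
  expect_equal(mantel_test(a, b, n_perm = 9, seed = 1)$r,
               vegan::mantel(a, b, permutations = 9)$statistic,
               tolerance = 1e-12)
})

test_that("Mantel test validates its inputs and is seed-reproducible", {
  d <- random_distance_matrix(5)
  asym <- d; asym[1, 2] <- asym[1, 2] + 1
  expect_error(mantel_test(asym, d), class = "meadowsucc_validation_error")
  diagbad <- d; diag(diagbad) <- 1
  expect_error(mantel_test(diagbad, d), class = "meadowsucc_validation_error")
  expect_error(mantel_test(d, random_distance_matrix(6)),
               class = "meadowsucc_validation_error")
  expect_error(mantel_test(random_distance_matrix(3), random_distance_matrix(3)),
               class = "meadowsucc_validation_error")

  withr::with_seed(19, {
    a <- random_distance_matrix(8)
    b <- random_distance_matrix(8)
  })
  p1 <- mantel_test(a, b, n_perm = 99, seed = 42)$p
  p2 <- mantel_test(a, b, n_perm = 99, seed = 42)$p
  expect_identical(p1, p2)
  # invariance under simultaneous relabeling of both matrices
  idx <- c(3, 1, 4, 2, 8, 6, 5, 7)
  expect_equal(mantel_test(a[idx, idx], b[idx, idx], n_perm = 5, seed = 1)$r,
               mantel_test(a, b, n_perm = 5, seed = 1)$r, tolerance = 1e-12)
})

test_that("correlation matrix matches hand-computed Pearson values", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 4, 5, 4)
  z <- -x
  cm <- correlation_matrix(list(x = x, y = y, z = z))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$r["x", "z"], -1)
  expect_equal(cm$r["x", "y"], cor(x, y), tolerance = 1e-12)
  expect_equal(cm$p["x", "y"], cor.test(x, y)$p.value, tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))

  expect_warning(
    flagged <- correlation_matrix(list(a = x, const = rep(2, 4))),
    "const"
  )
  expect_equal(flagged$flagged, "const")
  expect_true(is.na(flagged$r["a", "const"]))
})

test_that("LMG shares match the factorial brute-force oracle", {
  withr::with_seed(23, {
    for (p in 2:5) {
      n <- 30
      x <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("v", 1:p)))
      y <- x %*% runif(p, -1, 1) + rnorm(n)
      fast <- lmg_importance(x, y)
      naive <- lmg_naive(x, as.vector(y))
      expect_equal(fast$shares, naive, tolerance = 1e-10)
      expect_equal(sum(fast$shares), fast$r_squared, tolerance = 1e-10)
      expect_true(all(fast$shares >= -1e-12))
    }
  })
})

test_that("LMG limiting cases and failure modes", {
  withr::with_seed(29, {
    x1 <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "a"))
    y <- 2 * x1[, 1] + rnorm(40)
    res <- lmg_importance(x1, y)
    expect_equal(unname(res$shares["a"]), res$r_squared)

    # exactly orthogonal predictors: shares equal the marginal R^2 values
    a <- scale(rnorm(40), scale = FALSE)
    b <- residuals(lm(rnorm(40) ~ a))  # centered and orthogonal to a
    x2 <- cbind(a = as.vector(a), b = as.vector(b))
    y2 <- x2 %*% c(1, -2) + rnorm(40, sd = 0.5)
    res2 <- lmg_importance(x2, y2)
    marg <- vapply(1:2, function(j) summary(lm(y2 ~ x2[, j]))$r.squared,
                   numeric(1))
    expect_equal(unname(res2$shares), marg, tolerance = 1e-8)

    collinear <- cbind(a = rnorm(30), b = 0)
    collinear <- cbind(collinear, c = collinear[, "a"] * 2)[, c(1, 3)]
    expect_error(lmg_importance(collinear, rnorm(30)),
                 class = "meadowsucc_validation_error")
  })
})
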