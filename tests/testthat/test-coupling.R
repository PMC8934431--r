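test_that("min-max standardization maps extremes to 0 and 1", {
  expect_equal(minmax_standardize(c(2, 4, 6), "positive"), c(0, 0.5, 1))
  expect_equal(minmax_standardize(c(2, 4, 6), "negative"), c(1, 0.5, 0))
  expect_warning(
    out <- minmax_standardize(c(5, 5, 5), "positive"),
    "constant"
  )
  expect_equal(out, c(0.5, 0.5, 0.5))
  expect_error(minmax_standardize(3, "positive"),
               class = "meadowsucc_validation_error")
})

test_that("PCA weights handle degenerate and symmetric cases", {
  one <- matrix(runif(10), ncol = 1, dimnames = list(NULL, "stc"))
  expect_equal(pca_weights(one), c(stc = 1))

  # two identical columns: 2x2 correlation matrix has eigenvalues (2, 0),
  # the retained loading is symmetric, so weights are exactly (1/2, 1/2)
  v <- runif(20)
  two <- cbind(a = v, b = v)
  expect_equal(pca_weights(two), c(a = 0.5, b = 0.5), tolerance = 1e-12)

  withr::with_seed(21, {
    for (i in 1:20) {
      m <- matrix(runif(8 * sample(2:6, 1)), nrow = 8)
      colnames(m) <- paste0("v", seq_len(ncol(m)))
      w <- pca_weights(m)
      expect_true(all(w >= 0))
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  })

  const <- cbind(a = rep(1, 5), b = runif(5))
  expect_error(pca_weights(const), "zero-variance",
               class = "meadowsucc_validation_error")
})

test_that("subsystem integral is the weighted mean of standardized values", {
  expect_equal(subsystem_integral(c(0.4, 0.8), c(0.5, 0.5)), 0.6)
  expect_equal(subsystem_integral(c(0, 0, 0), c(0.2, 0.3, 0.5)), 0)
  expect_equal(subsystem_integral(c(1, 1, 1), c(0.2, 0.3, 0.5)), 1)
  expect_error(subsystem_integral(c(1, 0), c(1)),
               class = "meadowsucc_validation_error")
  expect_error(subsystem_integral(c(1, 0), c(0.7, 0.7)),
               class = "meadowsucc_validation_error")
})

test_that("coupling coordination reproduces hand-derived values", {
  r <- coupling_coordination(0.6, 0.6, 0.5, 0.5, "product")
  expect_equal(r$C, 1)
  expect_equal(r$T, 0.6)
  expect_equal(r$D, 0.6)

  r <- coupling_coordination(0.8, 0.2, 0.5, 0.5, "product")
  expect_equal(r$C, 0.8, tolerance = 1e-12)
  expect_equal(r$T, 0.5)
  expect_equal(r$D, 0.4, tolerance = 1e-12)

  expect_equal(coupling_coordination(0, 0.7)$D, 0)
  expect_equal(coupling_coordination(0, 0)$D, 0)
  expect_error(coupling_coordination(1.2, 0.5),
               class = "meadowsucc_validation_error")
})

test_that("coupling degree properties hold on a grid", {
  g <- expand.grid(s = seq(0, 1, 0.1), p = seq(0, 1, 0.1))
  r <- coupling_coordination(g$s, g$p)
  expect_true(all(r$C >= 0 & r$C <= 1 + 1e-12))
  expect_true(all(r$D <= r$T + 1e-12))
  expect_true(all(r$D <= r$C + 1e-12))
  # C = 1 exactly when S = P (and S + P > 0)
  pos <- g$s + g$p > 0
  expect_equal(abs(r$C[pos] - 1) < 1e-12, g$s[pos] == g$p[pos])
  # swap symmetry at alpha = beta
  swapped <- coupling_coordination(g$p, g$s)
  expect_equal(r$D, swapped$D, tolerance = 1e-12)
  # sqrt variant dominates the product variant when C*T <= 1
  rs <- coupling_coordination(g$s, g$p, variant = "sqrt")
  expect_true(all(rs$D >= r$D - 1e-12))
  # monotonicity: with P fixed and S <= P, D non-decreasing in S
  for (p in c(0.4, 0.8)) {
    s_grid <- seq(0, p, 0.02)
    d <- coupling_coordination(s_grid, rep(p, length(s_grid)))$D
    expect_true(all(diff(d) >= -1e-12))
  }
})

test_that("per-quadrat coupling pipeline stays in bounds end to end", {
  survey <- generate_survey(generator_config(n_quadrats_per_stage = 12,
                                             rng_seed = 17))
  cp <- coupling_indices(survey)
  expect_equal(nrow(cp), nrow(survey))
  for (col in c("S", "P", "C", "T", "D")) {
    expect_true(all(cp[[col]] >= -1e-12 & cp[[col]] <= 1 + 1e-12))
  }
  w <- attr(cp, "weights")
  expect_equal(sum(w$soil), 1, tolerance = 1e-12)
  expect_equal(sum(w$plant), 1, tolerance = 1e-12)
  # each standardized column attains the [0, 1] extremes at the sample ends
  std <- meadowsucc:::standardize_indicators(survey, analysis_config()$subsystem$soil)
  expect_equal(unname(apply(std, 2, min)), rep(0, ncol(std)))
  expect_equal(unname(apply(std, 2, max)), rep(1, ncol(std)))
})
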