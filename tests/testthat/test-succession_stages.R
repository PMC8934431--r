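test_that("feature matrix exposes composition on the share columns", {
  tbl <- tiny_survey()
  fg <- tiny_fg_map()
  # make the two quadrats pure sedge vs pure grass
  tbl$`sp:Elymus nutans` <- c(0, 1.5)
  tbl$`sp:Gentiana macrophylla` <- c(0, 0)
  tbl$agb <- c(3, 1.5)
  f <- suppressWarnings(feature_matrix(as_survey_table(tbl), fg))
  expect_equal(unname(f["q1", "share_sedge"]), 1)
  expect_equal(unname(f["q2", "share_grass"]), 1)

  # identical quadrats give identical rows
  survey <- random_survey(6, seed = 2)
  m <- tibble::as_tibble(survey)
  m[2, -1] <- m[1, -1]  # same everything, different id
  f2 <- suppressWarnings(feature_matrix(
    as_survey_table(m),
    setNames(rep("grass", 6), paste0("species_", 1:6))
  ))
  expect_equal(unname(f2[1, ]), unname(f2[2, ]))
})

test_that("generated stages form separated groups in feature space", {
  survey <- generate_survey(generator_config(n_quadrats_per_stage = 20,
                                             rng_seed = 4))
  f <- feature_matrix(survey, templates_fg_map())
  sil <- cluster::silhouette(survey$stage, dist(f))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("constant feature columns are dropped with a warning", {
  survey <- random_survey(5, seed = 3)
  fg <- setNames(rep("sedge", 6), paste0("species_", 1:6))
  expect_warning(f <- feature_matrix(survey, fg), "constant")
  expect_false(any(c("share_grass", "share_shrub") %in% colnames(f)))
})

test_that("Ward clustering matches a brute-force oracle on small instances", {
  withr::with_seed(11, {
    for (i in 1:100) {
      n <- sample(4:8, 1)
      x <- matrix(rnorm(n * 3), n, 3)
      rownames(x) <- paste0("q", seq_len(n))
      oracle <- brute_force_ward(x)
      for (k in 2:(n - 1)) {
        got <- ward_cluster(x, k)$labels
        want <- oracle[[n - k]]
        expect_equal(adjusted_rand_index(got, want), 1)
      }
    }
  })
})

test_that("Ward merge heights are non-decreasing and k bounds enforced", {
  x <- matrix(rnorm(60), 20, 3)
  rownames(x) <- paste0("q", 1:20)
  asg <- ward_cluster(x, 4)
  expect_true(all(diff(asg$height) >= -1e-12))
  expect_error(ward_cluster(x, 0), class = "meadowsucc_validation_error")
  expect_error(ward_cluster(x, 21), class = "meadowsucc_validation_error")
  # n = k: every quadrat its own cluster
  all_own <- ward_cluster(x, 20)$labels
  expect_equal(length(unique(all_own)), 20)
})

test_that("two separated clouds are recovered exactly at k = 2", {
  withr::with_seed(5, {
    x <- rbind(matrix(rnorm(30, 0, 0.1), 15, 2),
               matrix(rnorm(30, 10, 0.1), 15, 2))
    rownames(x) <- paste0("q", 1:30)
    truth <- rep(1:2, each = 15)
    got <- ward_cluster(x, 2)$labels
    expect_equal(adjusted_rand_index(got, truth), 1)
  })
})

test_that("clustering is invariant to row order of the survey", {
  survey <- generate_survey(generator_config(n_quadrats_per_stage = 10,
                                             rng_seed = 8))
  fg <- templates_fg_map()
  a <- assign_stages(survey, fg)
  perm <- withr::with_seed(1, sample(nrow(survey)))
  shuffled <- as_survey_table(tibble::as_tibble(survey)[perm, ])
  b <- assign_stages(shuffled, fg)
  merged <- merge(a, b, by = "quadrat_id")
  expect_equal(adjusted_rand_index(merged$stage.x, merged$stage.y), 1)
  expect_equal(merged$stage.x, merged$stage.y)
})

test_that("stage ordering follows descending sedge then ascending toxic share", {
  survey <- generate_survey(generator_config(n_quadrats_per_stage = 15,
                                             rng_seed = 9))
  fg <- templates_fg_map()
  asg <- order_stages(ward_cluster(feature_matrix(survey, fg), 4), survey, fg)
  comm <- community_summary(survey, fg)
  sedge_by_stage <- tapply(comm$share_sedge,
                           asg$stage[comm$quadrat_id], mean)
  expect_equal(order(-sedge_by_stage), 1:4)

  # single cluster -> stage 1
  single <- order_stages(ward_cluster(feature_matrix(survey, fg), 1),
                         survey, fg)
  expect_true(all(single$stage == 1))
})

test_that("generator ground truth is recovered with high agreement", {
  aris <- vapply(1:5, function(seed) {
    survey <- generate_survey(generator_config(rng_seed = seed))
    asg <- assign_stages(survey, templates_fg_map())
    adjusted_rand_index(asg$stage, survey$stage)
  }, numeric(1))
  expect_gt(mean(aris), 0.8)
  # ordered stages track the truth directionally, not just as a partition
  survey <- generate_survey(generator_config(rng_seed = 1))
  asg <- assign_stages(survey, templates_fg_map())
  expect_gt(cor(asg$stage, survey$stage), 0.9)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  withr::with_seed(13, {
    for (i in 1:20) {
      a <- sample(1:4, 40, replace = TRUE)
      b <- sample(1:3, 40, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
})
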