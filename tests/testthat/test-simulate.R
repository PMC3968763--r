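test_that("image generation is fully determined by its spec", {
  a <- generate_image("spectral_noise", width = 40, height = 40, seed = 5, slope = 1.2)
  b <- generate_image("spectral_noise", width = 40, height = 40, seed = 5, slope = 1.2)
  c2 <- generate_image("spectral_noise", width = 40, height = 40, seed = 6, slope = 1.2)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c2$pixels))
  # generation does not disturb the global RNG stream
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_image("spectral_noise", width = 20, height = 20, seed = 9))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("generator kinds produce their advertised gradient structure", {
  expect_error(generate_image("constant", width = 8, height = 8), "16 x 16")
  const <- compute_features(generate_image("constant", width = 32, height = 32),
                            pixel_budget = 1024)
  expect_equal(const$complexity, 0)
  expect_true(is.na(const$self_similarity))

  ramp <- compute_features(
    generate_image("ramp", width = 64, height = 64, orientation = 0),
    pixel_budget = 64 * 64
  )
  expect_equal(ramp$self_similarity, 1)
  expect_lt(abs(ramp$anisotropy / (sqrt(15) / 16) - 1), 0.005)
})

test_that("a steeper spectral slope lowers measured complexity pairwise", {
  shallow <- purrr::map_dbl(1:8, function(s) {
    complexity(compute_gradient_field(
      generate_image("spectral_noise", width = 64, height = 64, seed = s, slope = 1)
    ))
  })
  steep <- purrr::map_dbl(1:8, function(s) {
    complexity(compute_gradient_field(
      generate_image("spectral_noise", width = 64, height = 64, seed = 100 + s, slope = 2.5)
    ))
  })
  ordered <- outer(steep, shallow, `<`)
  expect_gte(mean(ordered), 0.95)
})

test_that("a collection spans a wide self-similarity range with ground truth info", {
  coll <- generate_image_collection(40, seed = 12)
  expect_equal(length(coll$images), 40)
  expect_equal(coll$info$image_id, purrr::map_chr(coll$images, "id"))
  feats <- compute_all_features(coll$images, pixel_budget = 20000)
  expect_equal(nrow(feats), 40)
  ss <- feats$self_similarity[!is.na(feats$self_similarity)]
  expect_gte(diff(range(ss)), 0.4)
  # single-image collection is valid
  one <- generate_image_collection(1, seed = 2)
  expect_equal(nrow(one$info), 1)
})

test_that("population_spec validates the study-design constraints", {
  expect_error(population_spec(n_participants = 49), "sum")
  expect_error(population_spec(cluster_sizes = c(47, 3),
                               weights = matrix(0, 2, 5),
                               intercepts = c(2, 3), delta_sign = c(1, 1)),
               "at least 4")
  expect_error(population_spec(sigma = -1, cluster_sizes = c(25, 25),
                               weights = matrix(0, 2, 5),
                               intercepts = c(2, 3), delta_sign = c(1, 1)),
               "non-negative")
})

test_that("the rating model is deterministic and degenerates correctly", {
  feats <- simulate_feature_table(20, seed = 1)
  pop <- population_spec(seed = 9)
  r1 <- simulate_baseline_ratings(feats, pop)
  r2 <- simulate_baseline_ratings(feats, pop)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 50 * 20) # complete

  # sigma = 0 and zero weights: every rating equals the rounded intercept
  pop0 <- population_spec(
    n_participants = 8, cluster_sizes = c(4, 4),
    weights = matrix(0, 2, 5), intercepts = c(1.8, 3.4),
    sigma = 0, delta_sign = c(1, 1), seed = 2
  )
  r0 <- simulate_baseline_ratings(feats, pop0)
  m <- ratings_matrix(r0)
  expect_true(all(m[1:4, ] == 2))
  expect_true(all(m[5:8, ] == 3))
})

test_that("opposite-weight clusters produce anti-correlated mean ratings", {
  feats <- simulate_feature_table(80, seed = 4)
  pop <- population_spec(
    n_participants = 12, cluster_sizes = c(6, 6),
    weights = rbind(c(0.7, 0, 0, 0, 0), c(-0.7, 0, 0, 0, 0)),
    intercepts = c(2.5, 2.5), sigma = 0.3, delta_sign = c(1, 1), seed = 4
  )
  r <- simulate_baseline_ratings(feats, pop)
  assignment <- tibble::tibble(
    participant_id = sprintf("p%03d", 1:12), cluster = rep(1:2, each = 6)
  )
  means <- tidyr::pivot_wider(
    cluster_mean_ratings(r, assignment),
    names_from = "cluster", values_from = "mean_rating", names_prefix = "c"
  )
  expect_lt(cor(means$c1, means$c2), -0.5)
})

test_that("adaptation ratings cover only evaluation images, counterbalanced", {
  feats <- simulate_feature_table(150, seed = 6)
  pop <- population_spec(seed = 6)
  r <- simulate_baseline_ratings(feats, pop)
  sol <- cluster_raters(r, k = 7, seed = 6, k_range = 7)
  sets <- select_adaptor_sets(cluster_mean_ratings(r, sol))
  adapt <- simulate_adaptation_ratings(feats, pop, sets, assignment = sol$assignment)
  eval_ids <- unique(sets$image_id[sets$role == "evaluation"])
  expect_true(all(adapt$after_beautiful$image_id %in% eval_ids))
  expect_equal(nrow(adapt$after_beautiful), 50 * 60)
  expect_equal(sort(unique(adapt$after_beautiful$order)),
               c("beautiful_first", "least_first"))
  orders <- dplyr::distinct(adapt$after_beautiful, participant_id, order)
  expect_equal(as.numeric(table(orders$order)), c(25, 25))
})

test_that("a null shift yields nominal-rate rejections only", {
  feats <- simulate_feature_table(150, seed = 7)
  pop <- population_spec(seed = 7, delta0 = 0)
  r <- simulate_baseline_ratings(feats, pop)
  sol <- cluster_raters(r, k = 7, seed = 7, k_range = 7)
  sets <- select_adaptor_sets(cluster_mean_ratings(r, sol))
  adapt <- simulate_adaptation_ratings(feats, pop, sets, assignment = sol$assignment)
  tab <- compute_contrast(adapt$after_beautiful, adapt$after_least, sol)
  res <- paired_contrast_test(tab)
  expect_lt(abs(res$mean_difference), 0.08)
})

test_that("a self-similarity-linked shift is recovered by the contrast regression", {
  feats <- simulate_feature_table(150, seed = 8)
  pop <- population_spec(seed = 8, delta0 = 0, delta1 = 0.5)
  r <- simulate_baseline_ratings(feats, pop)
  sol <- cluster_raters(r, k = 7, seed = 8, k_range = 7)
  sets <- select_adaptor_sets(cluster_mean_ratings(r, sol))
  adapt <- simulate_adaptation_ratings(feats, pop, sets, assignment = sol$assignment)
  tab <- compute_contrast(adapt$after_beautiful, adapt$after_least, sol)
  pooled <- tab |>
    dplyr::group_by(image_id) |>
    dplyr::summarise(contrast = mean(contrast), .groups = "drop") |>
    dplyr::inner_join(feats, by = "image_id")
  fit <- regression_standardized(pooled, "contrast", "self_similarity")
  expect_gt(fit$coefficients$std_beta, 0.2)
  expect_lt(fit$coefficients$p, 0.01)
})
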