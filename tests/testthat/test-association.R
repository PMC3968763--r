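test_that("spearman rho: monotone perfection, oracle agreement, invariance", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.1)
  y <- x^3 # strictly monotone transform
  expect_equal(spearman_rho(x, y)$rho, 1)
  withr::with_seed(13, {
    for (i in 1:10) {
      a <- rnorm(15)
      b <- rnorm(15) + 0.5 * a
      expect_equal(spearman_rho(a, b)$rho, oracle_spearman(a, b), tolerance = 1e-12)
      # invariance under strictly monotone transforms of either variable
      expect_equal(spearman_rho(exp(a), b)$rho, spearman_rho(a, b)$rho)
      expect_equal(spearman_rho(a, rank(b))$rho, spearman_rho(a, b)$rho)
    }
    # ties handled by midranks
    a <- c(1, 1, 2, 3, 3, 4)
    b <- c(2, 1, 2, 2, 3, 3)
    expect_equal(spearman_rho(a, b)$rho, oracle_spearman(a, b), tolerance = 1e-12)
  })
  expect_true(spearman_rho(rep(1, 10), rnorm(10))$degenerate)
})

test_that("permutation and t-approximation p-values roughly agree at small n", {
  withr::with_seed(5, {
    a <- rnorm(20)
    b <- 0.6 * a + rnorm(20)
  })
  p_t <- spearman_rho(a, b)$p
  p_perm <- spearman_rho(a, b, p_method = "permutation", seed = 2)$p
  expect_lt(abs(p_t - p_perm), 0.05)
})

test_that("the spearman table reports one row per cluster x property", {
  feats <- simulate_feature_table(30, seed = 3)
  means <- tibble::tibble(
    cluster = rep(1:2, each = 30),
    image_id = rep(feats$image_id, 2),
    mean_rating = withr::with_seed(3, runif(60, 1, 4))
  )
  tab <- spearman_table(means, feats, properties = c("self_similarity", "hsv_value"))
  expect_equal(nrow(tab), 4)
  expect_true(all(abs(tab$rho) <= 1))
  # a feature monotone in the rating gives rho 1
  means2 <- dplyr::filter(means, cluster == 1)
  means2$mean_rating <- rank(feats$self_similarity)
  tab2 <- spearman_table(means2, feats, properties = "self_similarity")
  expect_equal(tab2$rho, 1)
})

test_that("opposite generating weights produce opposite rho signs per cluster", {
  feats <- simulate_feature_table(100, seed = 17)
  pop <- population_spec(
    n_participants = 16, cluster_sizes = c(8, 8),
    weights = rbind(c(0.6, 0, 0, 0, 0), c(-0.6, 0, 0, 0, 0)),
    intercepts = c(2.5, 2.5), sigma = 0.3, seed = 17
  )
  r <- simulate_baseline_ratings(feats, pop)
  assignment <- tibble::tibble(
    participant_id = sprintf("p%03d", 1:16), cluster = rep(1:2, each = 8)
  )
  means <- cluster_mean_ratings(r, assignment)
  tab <- spearman_table(means, feats, properties = "self_similarity")
  expect_gt(tab$rho[tab$cluster == 1], 0.3)
  expect_lt(tab$rho[tab$cluster == 2], -0.3)
})

test_that("standardized regression: identifiability and the single-predictor identity", {
  feats <- simulate_feature_table(150, seed = 23)
  # exact linear combination: R^2 = 1, betas proportional to the weights
  feats$resp <- 2 * scale(feats$self_similarity)[, 1] - scale(feats$hsv_value)[, 1]
  fit <- regression_standardized(feats, "resp", c("self_similarity", "hsv_value"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  b <- fit$coefficients$std_beta
  expect_equal(unname(b[1] / b[2]), -2, tolerance = 1e-6)

  fit1 <- regression_standardized(feats, "resp", "hsv_value")
  expect_equal(unname(fit1$coefficients$std_beta),
               cor(feats$resp, feats$hsv_value),
               tolerance = 1e-12)

  # independent response: R^2 stays near its null expectation p/(n-1)
  feats$null_resp <- withr::with_seed(1, rnorm(150))
  fit0 <- regression_standardized(
    feats, "null_resp", c("self_similarity", "hsv_value", "complexity")
  )
  expect_lt(fit0$r_squared, 0.1)
})

test_that("collinear predictors warn but still report coefficients", {
  feats <- simulate_feature_table(50, seed = 2)
  feats$dup <- feats$hsv_value * 3 + 1e-9 * seq_len(50)
  expect_warning(
    fit <- regression_standardized(feats, "lab_l", c("hsv_value", "dup")),
    "collinear"
  )
  expect_equal(nrow(fit$coefficients), 2)
})

test_that("the mixed-model interaction F matches the balanced-design ANOVA oracle", {
  withr::with_seed(31, {
    n_img <- 12
    feats <- tibble::tibble(image_id = sprintf("i%02d", 1:n_img), x = rnorm(n_img))
    img_eff <- rnorm(n_img, 0, 0.5)
    means <- purrr::map_dfr(1:2, function(g) {
      slope <- c(0.4, -0.4)[g]
      tibble::tibble(
        image_id = feats$image_id,
        cluster = g,
        mean_rating = 2.5 + img_eff + slope * feats$x + rnorm(n_img, 0, 0.2)
      )
    })
  })
  mm <- mixed_model_cluster_interaction(means, feats, properties = "x")
  oracle <- summary(stats::aov(
    mean_rating ~ x * factor(cluster) + Error(factor(image_id)),
    data = dplyr::inner_join(means, feats, by = "image_id")
  ))
  f_oracle <- oracle[["Error: Within"]][[1]]["x:factor(cluster)", "F value"]
  expect_equal(mm$anova$F, f_oracle, tolerance = 1e-4)
})

test_that("interaction F fires only for the feature with cluster-specific weights", {
  feats <- simulate_feature_table(120, seed = 41)
  withr::with_seed(41, {
    img_eff <- rnorm(120, 0, 0.2)
    z1 <- scale(feats$self_similarity)[, 1]
    z2 <- scale(feats$hsv_value)[, 1]
    means <- purrr::map_dfr(1:3, function(g) {
      slope <- c(0.5, 0, -0.5)[g]
      tibble::tibble(
        image_id = feats$image_id,
        cluster = g,
        mean_rating = 2.5 + img_eff + slope * z1 + 0.2 * z2 + rnorm(120, 0, 0.15)
      )
    })
  })
  mm <- mixed_model_cluster_interaction(
    means, feats, properties = c("self_similarity", "hsv_value", "complexity")
  )
  ps <- setNames(mm$anova$p, mm$anova$property)
  expect_lt(ps[["self_similarity"]], 1e-6)
  expect_gt(ps[["hsv_value"]], 0.01)
  expect_gt(ps[["complexity"]], 0.01)
  # per-cluster coefficients recover the generating slope pattern
  sl <- tidy(mm)
  sl <- sl[sl$property == "self_similarity", ]
  expect_equal(order(sl$rc), c(3, 2, 1)) # -0.5 < 0 < 0.5 on the rating scale
})

test_that("identical clusters give a null-scale interaction F", {
  feats <- simulate_feature_table(80, seed = 51)
  withr::with_seed(51, {
    base <- 2.5 + 0.3 * scale(feats$complexity)[, 1] + rnorm(80, 0, 0.2)
    means <- purrr::map_dfr(1:2, function(g) {
      tibble::tibble(
        image_id = feats$image_id, cluster = g,
        mean_rating = base + rnorm(80, 0, 0.2)
      )
    })
  })
  mm <- mixed_model_cluster_interaction(means, feats, properties = "complexity")
  expect_gt(mm$anova$p, 0.001)
  expect_lt(mm$anova$F, 12)
})

test_that("hue-group analysis finds a driven sector and flags grayscale degeneracy", {
  feats <- simulate_feature_table(100, seed = 61)
  means <- tibble::tibble(
    cluster = 1L,
    image_id = feats$image_id,
    mean_rating = withr::with_seed(61, {
      2.5 + 2 * (feats$hue_red - mean(feats$hue_red)) + rnorm(100, 0, 0.1)
    })
  )
  res <- hue_group_analysis(means, feats)
  expect_lt(res$p_holm[res$sector == "hue_red"], 0.01)

  # grayscale collection: constant sector fractions are degenerate
  gray_feats <- feats
  gray_feats$hue_red <- 1
  gray_feats$hue_yellow <- 0
  gray_feats$hue_green <- 0
  gray_feats$hue_cyan <- 0
  gray_feats$hue_blue <- 0
  gray_feats$hue_magenta <- 0
  res_gray <- hue_group_analysis(means, gray_feats)
  expect_true(all(res_gray$degenerate))
})

test_that("null hue preferences rarely reach corrected significance", {
  hits <- vapply(1:20, function(s) {
    feats <- simulate_feature_table(60, seed = 100 + s)
    means <- tibble::tibble(
      cluster = 1L,
      image_id = feats$image_id,
      mean_rating = withr::with_seed(200 + s, runif(60, 1, 4))
    )
    any(hue_group_analysis(means, feats)$p_holm < 0.05, na.rm = TRUE)
  }, logical(1))
  expect_lte(sum(hits), 2)
})

test_that("the quadratic probe detects an inverted-U relation", {
  feats <- simulate_feature_table(120, seed = 71)
  z <- scale(feats$complexity)[, 1]
  feats$resp <- withr::with_seed(71, -0.6 * z^2 + rnorm(120, 0, 0.2))
  probe <- quadratic_probe(feats, "resp", "complexity")
  expect_lt(probe$quadratic_beta, 0)
  expect_lt(probe$quadratic_p, 0.001)
})
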