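# tiny paired-condition ratings builder: one cluster, every participant
# rates every image under both conditions
paired_ratings <- function(ab_matrix, al_matrix) {
  to_long <- function(m, phase) {
    tibble::tibble(
      participant_id = rep(rownames(m), times = ncol(m)),
      image_id = rep(colnames(m), each = nrow(m)),
      phase = phase,
      rating = as.integer(m)
    )
  }
  list(
    ab = to_long(ab_matrix, "after_beautiful"),
    al = to_long(al_matrix, "after_least"),
    assignment = tibble::tibble(
      participant_id = rownames(ab_matrix), cluster = 1L
    )
  )
}

named_matrix <- function(data, n_p, n_i) {
  matrix(data, n_p, n_i, dimnames = list(
    sprintf("p%02d", seq_len(n_p)), sprintf("i%02d", seq_len(n_i))
  ))
}

test_that("contrast is the difference of pooled condition means", {
  ab <- named_matrix(c(3, 3, 3, 2, 3, 4, 2, 3, 4, 3, 3, 3), 3, 4)
  al <- named_matrix(c(3, 2, 3, 2, 3, 3, 2, 2, 4, 3, 2, 3), 3, 4)
  pr <- paired_ratings(ab, al)
  tab <- compute_contrast(pr$ab, pr$al, pr$assignment)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$mean_after_beautiful, unname(colMeans(ab)[sort(colnames(ab))]))
  expect_equal(tab$contrast, unname((colMeans(ab) - colMeans(al))[sort(colnames(ab))]))
})

test_that("identical condition matrices give zero contrast and a degenerate test", {
  m <- named_matrix(withr::with_seed(4, sample(1:4, 30, replace = TRUE)), 5, 6)
  pr <- paired_ratings(m, m)
  tab <- compute_contrast(pr$ab, pr$al, pr$assignment)
  expect_true(all(tab$contrast == 0))
  res <- paired_contrast_test(tab)
  expect_equal(res$t, 0)
  expect_true(res$degenerate)
})

test_that("all-equal nonzero differences flag an infinite t", {
  m <- named_matrix(rep(2L, 24), 4, 6)
  pr <- paired_ratings(m + 1L, m)
  tab <- compute_contrast(pr$ab, pr$al, pr$assignment)
  res <- paired_contrast_test(tab)
  expect_true(is.infinite(res$t) && res$t > 0)
  expect_true(res$degenerate)
})

test_that("swapping the conditions negates contrasts and the t statistic", {
  tab <- simulate_contrast_means(40, delta0 = 0.2, seed = 5)
  swapped <- dplyr::mutate(
    tab,
    tmp = mean_after_beautiful,
    mean_after_beautiful = mean_after_least,
    mean_after_least = tmp,
    contrast = mean_after_beautiful - mean_after_least
  )[, names(tab)]
  r1 <- paired_contrast_test(tab)
  r2 <- paired_contrast_test(swapped)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$mean_difference, -r2$mean_difference)
  expect_equal(r1$paired_correlation, r2$paired_correlation)
})

test_that("the paired test matches the textbook formula on a hand-sized table", {
  tab <- simulate_contrast_means(5, delta0 = 0.3, seed = 11)
  res <- paired_contrast_test(tab)
  manual <- oracle_paired_t(tab$mean_after_beautiful, tab$mean_after_least)
  expect_equal(res$t, manual$t, tolerance = 1e-12)
  expect_equal(res$df, manual$df)
})

test_that("an injected shift is recovered within its confidence interval", {
  tab <- simulate_contrast_means(132, delta0 = 0.2, seed = 3)
  res <- paired_contrast_test(tab)
  se <- sd(tab$contrast) / sqrt(nrow(tab))
  expect_lt(abs(res$mean_difference - 0.2), 2.5 * se)
  expect_lt(res$p, 0.001)
})

test_that("contrast is invariant to participant and image row order", {
  withr::with_seed(8, {
    ab <- named_matrix(sample(1:4, 40, replace = TRUE), 5, 8)
    al <- named_matrix(sample(1:4, 40, replace = TRUE), 5, 8)
  })
  pr <- paired_ratings(ab, al)
  t1 <- compute_contrast(pr$ab, pr$al, pr$assignment)
  shuffle <- function(df) withr::with_seed(2, df[sample(nrow(df)), ])
  t2 <- compute_contrast(shuffle(pr$ab), shuffle(pr$al), pr$assignment)
  expect_equal(t1, t2)
})

test_that("per-cluster summary flags a cluster with an inverted aftereffect", {
  normal <- simulate_contrast_means(30, delta0 = 0.2, seed = 21)
  inverted <- simulate_contrast_means(30, delta0 = -0.2, seed = 22)
  inverted$cluster <- 2L
  third <- simulate_contrast_means(30, delta0 = 0.2, seed = 23)
  third$cluster <- 3L
  tab <- dplyr::bind_rows(normal, inverted, third)
  class(tab) <- class(normal)
  summ <- per_cluster_contrast_summary(tab)
  expect_equal(summ$direction_flag, c(FALSE, TRUE, FALSE))
  # all same direction: no flags
  tab2 <- dplyr::bind_rows(normal, dplyr::mutate(third, cluster = 2L))
  class(tab2) <- class(normal)
  expect_false(any(per_cluster_contrast_summary(tab2)$direction_flag))
  # undersized cluster excluded with warning
  tab3 <- dplyr::bind_rows(normal, tab[31, ])
  class(tab3) <- class(normal)
  expect_warning(s3 <- per_cluster_contrast_summary(tab3), "excluded")
  expect_equal(s3$cluster, 1L)
})

test_that("the full generator recovers the configured condition shift", {
  feats <- simulate_feature_table(150, seed = 31)
  pop <- population_spec(seed = 31, delta0 = 0.16)
  baseline <- simulate_baseline_ratings(feats, pop)
  sol <- cluster_raters(baseline, k = 7, seed = 31, k_range = 7)
  sets <- select_adaptor_sets(cluster_mean_ratings(baseline, sol))
  adapt <- simulate_adaptation_ratings(feats, pop, sets, assignment = sol$assignment)
  tab <- compute_contrast(adapt$after_beautiful, adapt$after_least, sol)
  res <- paired_contrast_test(tab)
  expect_lt(abs(res$mean_difference - 0.16), 0.05)
  expect_gt(res$t, 3)
})
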