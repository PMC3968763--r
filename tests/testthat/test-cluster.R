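# two well-separated preference groups for recovery checks
two_group_ratings <- function(n_per = 10, n_i = 30, seed = 1) {
  withr::with_seed(seed, {
    profile_a <- sample(1:2, n_i, replace = TRUE)
    profile_b <- 5 - profile_a
    rows <- purrr::map_dfr(seq_len(2 * n_per), function(p) {
      base <- if (p <= n_per) profile_a else profile_b
      noisy <- pmin(pmax(base + sample(c(-1, 0, 0, 1), n_i, replace = TRUE), 1), 4)
      tibble::tibble(
        participant_id = sprintf("p%02d", p),
        image_id = sprintf("i%02d", seq_len(n_i)),
        phase = "baseline",
        rating = as.integer(noisy)
      )
    })
    load_ratings(rows)
  })
}

test_that("k-means recovers two opposite preference groups exactly", {
  r <- two_group_ratings()
  sol <- cluster_raters(r, k = 2, seed = 3)
  truth <- rep(1:2, each = 10)
  expect_equal(ari(truth, tidy(sol)$cluster), 1)
  expect_equal(sort(sol$sizes), c(10L, 10L))
})

test_that("infeasible and degenerate cluster requests are handled", {
  r <- tiny_ratings(n_p = 6, n_i = 10)
  expect_error(cluster_raters(r, k = 6), "infeasible")
  expect_error(cluster_raters(r, k = 1), "k must lie")
  # identical raters: degenerate separation warned
  same <- tiny_ratings(n_p = 1, n_i = 10)
  clones <- purrr::map_dfr(1:8, function(p) {
    dplyr::mutate(same, participant_id = sprintf("c%02d", p))
  })
  expect_warning(sol <- cluster_raters(load_ratings(clones), k = 3, seed = 1),
                 "degenerate")
  expect_true(sol$degenerate)
  # too-small clusters warn (25 raters, k close to P with min size 4)
  r2 <- two_group_ratings(n_per = 5, n_i = 12, seed = 9)
  expect_warning(cluster_raters(r2, k = 9, seed = 2, k_range = 9), "below the feasible minimum")
})

test_that("clustering is equivariant under participant relabeling", {
  r <- two_group_ratings(seed = 4)
  sol1 <- cluster_raters(r, k = 2, seed = 5)
  relabeled <- dplyr::mutate(
    r, participant_id = sprintf("z%s", participant_id)
  )
  sol2 <- cluster_raters(relabeled, k = 2, seed = 5)
  a1 <- tidy(sol1)$cluster
  a2 <- tidy(sol2)$cluster # same sorted order as z-prefix preserves order
  expect_equal(ari(a1, a2), 1)
})

test_that("within-cluster sum of squares is non-increasing in k", {
  r <- simulate_baseline_ratings(
    simulate_feature_table(40, seed = 6),
    population_spec(seed = 6)
  )
  sol <- cluster_raters(r, k = 4, seed = 7, k_range = 2:8)
  wss <- sol$diagnostics$tot_withinss[order(sol$diagnostics$k)]
  expect_true(all(diff(wss) <= 1e-8))
  expect_true(all(is.finite(sol$diagnostics$bic)))
  expect_true(all(sol$diagnostics$dunn >= 0))
})

test_that("cluster mean ratings equal the brute-force average", {
  r <- tiny_ratings(n_p = 6, n_i = 8, seed = 2)
  assignment <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:6),
    cluster = c(1L, 1L, 2L, 2L, 2L, 3L)
  )
  means <- cluster_mean_ratings(r, assignment)
  m <- ratings_matrix(r)
  for (g in 1:3) {
    members <- assignment$participant_id[assignment$cluster == g]
    manual <- colMeans(m[members, , drop = FALSE])
    got <- means$mean_rating[means$cluster == g][order(means$image_id[means$cluster == g])]
    expect_equal(got, unname(manual[sort(names(manual))]))
  }
  # one-member cluster equals that member's own ratings
  solo <- means[means$cluster == 3, ]
  expect_equal(solo$mean_rating, as.numeric(m["p06", sort(colnames(m))]))
})

test_that("adaptor selection takes the poles and a centered evaluation band", {
  means <- tibble::tibble(
    cluster = 1L,
    image_id = sprintf("i%03d", 1:150),
    mean_rating = seq(1, 4, length.out = 150) # strictly monotone
  )
  sets <- select_adaptor_sets(means)
  most <- sets$image_id[sets$role == "most_beautiful"]
  least <- sets$image_id[sets$role == "least_beautiful"]
  eval_set <- sets$image_id[sets$role == "evaluation"]
  expect_equal(most, sprintf("i%03d", 1:15))
  expect_equal(least, sprintf("i%03d", 136:150))
  expect_equal(eval_set, sprintf("i%03d", 46:105))
  expect_equal(length(intersect(most, eval_set)), 0)
  expect_equal(length(intersect(least, eval_set)), 0)
})

test_that("adaptor selection is deterministic under ties and row order", {
  means <- tibble::tibble(
    cluster = 1L,
    image_id = sprintf("i%03d", 1:120),
    mean_rating = 2.5 # all tied
  )
  s1 <- select_adaptor_sets(means, n_adapt = 10, n_eval = 40)
  shuffled <- withr::with_seed(1, means[sample(nrow(means)), ])
  s2 <- select_adaptor_sets(shuffled, n_adapt = 10, n_eval = 40)
  expect_equal(s1, s2)
  expect_equal(s1$image_id[s1$role == "most_beautiful"], sprintf("i%03d", 1:10))
  expect_error(select_adaptor_sets(means[1:50, ]), "at least")
})
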