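#' Cluster raters by their beauty-rating profiles
#'
#' k-means on the participant points in image-rating space (Euclidean
#' distance, 100 random restarts, deterministic given `seed`).  Individual
#' taste is heterogeneous, so participants are partitioned into preference
#' clusters before adaptor images are chosen; a feasible experimental
#' cluster needs at least `min_size` members (default 4), and solutions that
#' violate this are returned with a warning so the analyst can pick a
#' smaller `k`.
#'
#' Diagnostics are computed for every feasible `k` in `k_range`:
#' total within-cluster sum of squares, a spherical-Gaussian BIC
#' (shared variance `sigma^2 = WSS / (n d)`, `k d + 1` free parameters, so
#' `BIC = (k d + 1) log(n) + n d (log(2 pi sigma^2) + 1)`), and Dunn's index
#' (minimum inter-centroid distance over maximum within-cluster diameter).
#'
#' @param ratings validated ratings tibble (see [load_ratings()]), or a
#'   participant-by-image matrix.
#' @param k number of clusters, `2 <= k <= min(10, P - 1)`.
#' @param seed integer seed controlling the restarts.
#' @param nstart number of random restarts (default 100); best
#'   within-cluster sum of squares kept.
#' @param k_range integer vector of cluster counts to compute diagnostics
#'   for (default `2:10`, truncated to feasible values).
#' @param min_size minimum feasible cluster size for the adaptation
#'   experiment (default 4); smaller clusters trigger a warning, not an
#'   error.
#' @return An object of class `rater_clusters`: list with `k`, `assignment`
#'   (tibble `participant_id`, `cluster`), `centers`, `sizes`, `tot_withinss`,
#'   `diagnostics` (tibble over `k_range`), `degenerate`, `seed`.
#' @export
#' @examples
#' pop <- population_spec(seed = 1)
#' feats <- simulate_feature_table(60, seed = 1)
#' ratings <- simulate_baseline_ratings(feats, pop)
#' sol <- cluster_raters(ratings, k = 7, seed = 1)
#' glance(sol)
cluster_raters <- function(ratings, k, seed = 1L, nstart = 100L,
                           k_range = 2:10, min_size = 4L) {
  m <- if (is.matrix(ratings)) ratings else ratings_matrix(ratings, "baseline")
  p <- nrow(m)
  if (k >= p) {
    abort(sprintf(
      "k = %d infeasible for %d participants (clusters would be singletons)", k, p
    ))
  }
  if (k < 2 || k > min(10L, p - 1L)) {
    abort(sprintf("k must lie in [2, %d]", min(10L, p - 1L)))
  }
  n_distinct_rows <- nrow(unique(m))
  if (n_distinct_rows < k) {
    warn(sprintf(
      "only %d distinct rating profiles for k = %d clusters; degenerate separation",
      n_distinct_rows, k
    ))
    assignment <- tibble::tibble(
      participant_id = rownames(m),
      cluster = rep(1L, p)
    )
    return(structure(
      list(
        k = k, assignment = assignment,
        centers = matrix(rep(colMeans(m), k), nrow = k, byrow = TRUE,
                         dimnames = list(NULL, colnames(m))),
        sizes = c(p, rep(0L, k - 1L)), tot_withinss = 0,
        diagnostics = tibble::tibble(
          k = k, tot_withinss = 0, bic = NA_real_, dunn = 0, min_cluster_size = 0L
        ),
        degenerate = TRUE, seed = seed
      ),
      class = "rater_clusters"
    ))
  }
  fit_k <- function(kk) {
    set.seed(seed + kk)
    kmeans(m, centers = kk, nstart = nstart, iter.max = 100L)
  }
  km <- fit_k(k)
  if (any(km$size < min_size)) {
    warn(sprintf(
      "smallest cluster has %d member(s), below the feasible minimum of %d",
      min(km$size), min_size
    ))
  }
  k_range <- k_range[k_range >= 2 & k_range <= min(10L, p - 1L, n_distinct_rows)]
  diagnostics <- purrr::map_dfr(sort(unique(c(k_range, k))), function(kk) {
    fit <- if (kk == k) km else fit_k(kk)
    tibble::tibble(
      k = kk,
      tot_withinss = fit$tot.withinss,
      bic = kmeans_bic(m, fit),
      dunn = dunn_index(m, fit),
      min_cluster_size = min(fit$size)
    )
  })
  structure(
    list(
      k = k,
      assignment = tibble::tibble(
        participant_id = rownames(m),
        cluster = as.integer(km$cluster)
      ),
      centers = km$centers,
      sizes = as.integer(km$size),
      tot_withinss = km$tot.withinss,
      diagnostics = diagnostics,
      degenerate = FALSE,
      seed = seed
    ),
    class = "rater_clusters"
  )
}

# Spherical-Gaussian BIC with one shared variance across clusters.
kmeans_bic <- function(m, fit) {
  n <- nrow(m)
  d <- ncol(m)
  sigma2 <- fit$tot.withinss / (n * d)
  if (sigma2 <= 0) {
    return(-Inf)
  }
  n_par <- length(fit$size) * d + 1
  n_par * log(n) + n * d * (log(2 * pi * sigma2) + 1)
}

# Dunn's index, centroid-linkage variant: min inter-centroid distance over
# max within-cluster diameter (max pairwise member distance).
dunn_index <- function(m, fit) {
  centers <- fit$centers
  inter <- min(dist(centers))
  diam <- max(vapply(seq_len(nrow(centers)), function(g) {
    members <- m[fit$cluster == g, , drop = FALSE]
    if (nrow(members) < 2) 0 else max(dist(members))
  }, numeric(1)))
  if (diam == 0) {
    return(Inf)
  }
  inter / diam
}

#' @export
print.rater_clusters <- function(x, ...) {
  cat(sprintf(
    "<rater_clusters: k = %d, sizes = {%s}, WSS = %.1f%s>\n",
    x$k, paste(sort(x$sizes, decreasing = TRUE), collapse = ","),
    x$tot_withinss, if (x$degenerate) ", DEGENERATE" else ""
  ))
  invisible(x)
}

#' @describeIn cluster_raters tidy() returns the participant-to-cluster
#'   assignment tibble.
#' @param x a `rater_clusters` object.
#' @param ... unused.
#' @export
tidy.rater_clusters <- function(x, ...) x$assignment

#' @describeIn cluster_raters glance() returns a one-row tibble of the
#'   chosen solution's diagnostics.
#' @export
glance.rater_clusters <- function(x, ...) {
  row <- x$diagnostics[x$diagnostics$k == x$k, , drop = FALSE]
  dplyr::mutate(row, degenerate = x$degenerate)
}

#' Per-cluster mean ratings
#'
#' Arithmetic mean of member ratings per image within each cluster — the
#' cluster-level preference profile that drives adaptor selection and all
#' feature-association analyses.
#'
#' @param ratings validated ratings tibble (baseline phase used).
#' @param clusters a `rater_clusters` object, or an assignment tibble with
#'   columns `participant_id`, `cluster`.
#' @return Tibble with columns `cluster`, `image_id`, `mean_rating`.
#' @export
cluster_mean_ratings <- function(ratings, clusters) {
  assignment <- if (inherits(clusters, "rater_clusters")) clusters$assignment else clusters
  df <- ratings[ratings$phase == "baseline", , drop = FALSE]
  df |>
    dplyr::inner_join(assignment, by = "participant_id") |>
    dplyr::group_by(.data$cluster, .data$image_id) |>
    dplyr::summarise(mean_rating = mean(.data$rating), .groups = "drop") |>
    dplyr::arrange(.data$cluster, .data$image_id)
}

#' Overall mean ratings across all participants
#'
#' @param ratings validated ratings tibble (baseline phase used).
#' @return Tibble with columns `image_id`, `mean_rating`.
#' @export
overall_mean_ratings <- function(ratings) {
  df <- ratings[ratings$phase == "baseline", , drop = FALSE]
  df |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(mean_rating = mean(.data$rating), .groups = "drop") |>
    dplyr::arrange(.data$image_id)
}

#' Select adaptor and evaluation image sets per cluster
#'
#' For each cluster, images are ranked by the cluster's mean rating
#' (ascending; 1 = most beautiful), with ties broken by image id for
#' determinism.  The first `n_adapt` images form the most-beautiful adaptor
#' set and the last `n_adapt` the least-beautiful adaptor set; the
#' evaluation set is the `n_eval` images centered on the median of the
#' remaining (average-rated) ranking.  The three sets are pairwise disjoint
#' by construction.
#'
#' @param means tibble from [cluster_mean_ratings()] (`cluster`, `image_id`,
#'   `mean_rating`).
#' @param n_adapt adaptor set size per pole (default 15).
#' @param n_eval evaluation set size (default 60).
#' @return Tibble with columns `cluster`, `image_id`, `role`
#'   (`"most_beautiful"`, `"least_beautiful"`, `"evaluation"`), `rank`.
#' @export
select_adaptor_sets <- function(means, n_adapt = 15L, n_eval = 60L) {
  stopifnot(all(c("cluster", "image_id", "mean_rating") %in% names(means)))
  purrr::map_dfr(split(means, means$cluster), function(df) {
    n_img <- nrow(df)
    if (n_img < 2 * n_adapt + n_eval) {
      abort(sprintf(
        "cluster %s has %d images; need at least %d for 2 x %d adaptors + %d evaluation",
        df$cluster[1], n_img, 2 * n_adapt + n_eval, n_adapt, n_eval
      ))
    }
    ord <- order(df$mean_rating, df$image_id)
    ranked <- df$image_id[ord]
    most <- ranked[seq_len(n_adapt)]
    least <- ranked[seq(n_img - n_adapt + 1L, n_img)]
    remaining <- ranked[seq(n_adapt + 1L, n_img - n_adapt)]
    start <- (length(remaining) - n_eval) %/% 2L
    eval_set <- remaining[seq(start + 1L, start + n_eval)]
    sel <- c(most, eval_set, least)
    tibble::tibble(
      cluster = df$cluster[1],
      image_id = sel,
      role = rep(c("most_beautiful", "evaluation", "least_beautiful"),
                 times = c(n_adapt, n_eval, n_adapt)),
      rank = match(sel, ranked)
    )
  })
}
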