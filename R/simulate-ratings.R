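DEFAULT_CLUSTER_SIZES <- c(10L, 9L, 7L, 7L, 7L, 6L, 4L)

DEFAULT_FEATURE_SET <- c(
  "self_similarity", "complexity", "hsv_saturation", "hsv_value", "lab_b"
)

# Default latent preference weights (clusters x features, on standardized
# features).  Positive weight: more of the feature -> higher rating number
# -> judged LESS beautiful.  Rows are chosen to give well-separated,
# qualitatively distinct profiles: some clusters penalize self-similarity,
# others reward it; most reward brightness/saturation to different degrees.
DEFAULT_WEIGHTS <- rbind(
  c( 0.45, 0.00,  0.10, -0.50,  0.00),
  c(-0.40, 0.10, -0.45,  0.05, -0.35),
  c( 0.05, 0.45, -0.40, -0.05, -0.45),
  c( 0.50, -0.10, 0.45, -0.45,  0.10),
  c(-0.50, -0.05, -0.35, 0.45,  0.40),
  c( 0.35, -0.45, 0.05, -0.40, -0.45),
  c( 0.00, 0.05, -0.50, -0.45,  0.45)
)

# Cluster intercepts on the 1-4 rating scale.  Their participant-weighted
# mean (~2.91) puts the clip-and-round grand mean near 2.88; cluster 5 is
# the deliberately more generous (lower-rating) group.
DEFAULT_INTERCEPTS <- c(3.00, 3.10, 2.80, 3.20, 2.30, 2.90, 3.00)

#' Specify a synthetic rater population
#'
#' A latent-cluster preference model: participant `p` in cluster `g` rates
#' image `i` as
#' `round(clip(a_g + w_g . z_i + eps, 1, 4))`, with `z_i` the standardized
#' image features, `w_g` the cluster's weight vector, `a_g` its intercept,
#' and `eps ~ N(0, sigma^2)`.  Adaptation shifts the latent rating by
#' `+delta_i/2` after beautiful adaptors and `-delta_i/2` after least
#' beautiful ones (`delta_i = delta0 + delta1 * z_ss(i)`, optionally
#' sign-flipped per cluster via `delta_sign` to emulate a cluster with an
#' inverted aftereffect).  The linear-Gaussian rating model is the
#' package's modelling assumption for the generator, not an empirical claim
#' about raters.
#'
#' Defaults mirror the reference study design: 50 participants in 7
#' clusters of sizes 10/9/7/7/7/6/4 (all at least 4), a condition shift of
#' 0.16 rating points, and half of the participants adapting to the
#' beautiful pole first (counterbalanced order, recorded but not modelled).
#'
#' @param n_participants total number of raters.
#' @param cluster_sizes integer vector of cluster sizes (sums to
#'   `n_participants`; all at least 4).
#' @param weights numeric matrix, one row per cluster, one column per
#'   feature in `feature_set`.
#' @param intercepts numeric vector of per-cluster intercepts on the 1-4
#'   scale.
#' @param sigma rating noise SD (default 0.5).
#' @param delta0 baseline condition shift (default 0.16).
#' @param delta1 self-similarity modulation of the shift (default 0).
#' @param delta_sign per-cluster sign of the shift (default all +1).
#' @param feature_set feature columns entering the preference model.
#' @param counterbalance logical; alternate which condition comes first.
#' @param seed integer seed.
#' @return An object of class `population_spec` (a validated list).
#' @export
population_spec <- function(n_participants = 50L,
                            cluster_sizes = DEFAULT_CLUSTER_SIZES,
                            weights = DEFAULT_WEIGHTS,
                            intercepts = DEFAULT_INTERCEPTS,
                            sigma = 0.5,
                            delta0 = 0.16,
                            delta1 = 0,
                            delta_sign = rep(1, length(cluster_sizes)),
                            feature_set = DEFAULT_FEATURE_SET,
                            counterbalance = TRUE,
                            seed = 1L) {
  g <- length(cluster_sizes)
  if (sum(cluster_sizes) != n_participants) {
    abort("`cluster_sizes` must sum to `n_participants`")
  }
  if (any(cluster_sizes < 4)) {
    abort("all cluster sizes must be at least 4 (feasible experimental clusters)")
  }
  if (sigma < 0) abort("`sigma` must be non-negative")
  if (is.list(weights)) weights <- do.call(rbind, weights) # YAML row lists
  weights <- as.matrix(weights)
  if (nrow(weights) != g || ncol(weights) != length(feature_set)) {
    abort("`weights` must be n_clusters x length(feature_set)")
  }
  stopifnot(length(intercepts) == g, length(delta_sign) == g)
  structure(
    list(
      n_participants = as.integer(n_participants),
      cluster_sizes = as.integer(cluster_sizes),
      n_clusters = g,
      weights = weights,
      intercepts = as.numeric(intercepts),
      sigma = sigma,
      delta0 = delta0,
      delta1 = delta1,
      delta_sign = as.numeric(delta_sign),
      feature_set = feature_set,
      counterbalance = isTRUE(counterbalance),
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    "<population_spec: %d raters in %d clusters {%s}, sigma = %.2f, delta0 = %.2f>\n",
    x$n_participants, x$n_clusters, paste(x$cluster_sizes, collapse = ","),
    x$sigma, x$delta0
  ))
  invisible(x)
}

# participant roster: id, latent cluster
population_roster <- function(pop) {
  tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(pop$n_participants)),
    latent_cluster = rep(seq_len(pop$n_clusters), times = pop$cluster_sizes)
  )
}

#' Draw a feature table directly (fast path for rating-model studies)
#'
#' Samples plausible image-feature records from parametric distributions
#' matched to the ranges the image generators produce (self-similarity
#' concentrated around 0.65, complexity log-normal, colors spanning their
#' gamuts), without rendering any pixels.  Use it when a test or simulation
#' only exercises the rating/clustering/association layers; rendered images
#' via [generate_image_collection()] + [compute_all_features()] remain the
#' ground truth for the image-analysis layer.
#'
#' @param n number of images.
#' @param seed integer seed.
#' @return Tibble shaped like [compute_all_features()] output (without
#'   degenerate flags).
#' @export
simulate_feature_table <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    hue <- runif(n)
    sat <- stats::rbeta(n, 2, 2)
    val <- stats::rbeta(n, 3, 2)
    ss <- pmin(pmax(rnorm(n, 0.65, 0.15), 0.02), 1)
    comp <- exp(rnorm(n, 0.7, 0.6))
    sector <- t(vapply(seq_len(n), function(i) {
      x <- stats::rgamma(6, shape = 0.8)
      x / sum(x)
    }, numeric(6)))
    tibble::tibble(
      image_id = sprintf("sim%04d", seq_len(n)),
      self_similarity = ss,
      complexity = comp,
      anisotropy = pmin(pmax(rnorm(n, 0.1, 0.04), 0), sqrt(15) / 16),
      birkhoff = ss / comp,
      aspect_ratio = exp(rnorm(n, 0, 0.2)),
      hsv_hue = hue,
      hsv_saturation = sat,
      hsv_value = val,
      rgb_r = pmin(pmax(255 * (val + rnorm(n, 0, 0.1)), 0), 255),
      rgb_g = pmin(pmax(255 * (val + rnorm(n, 0, 0.1)), 0), 255),
      rgb_b = pmin(pmax(255 * (val + rnorm(n, 0, 0.1)), 0), 255),
      lab_l = pmin(pmax(100 * (val + rnorm(n, 0, 0.05)), 0), 100),
      lab_a = rnorm(n, 0, 15),
      lab_b = rnorm(n, 0, 20),
      hue_red = sector[, 1], hue_yellow = sector[, 2], hue_green = sector[, 3],
      hue_cyan = sector[, 4], hue_blue = sector[, 5], hue_magenta = sector[, 6],
      achromatic_fraction = stats::rbeta(n, 1, 6)
    )
  })
}

# standardized feature matrix (images x feature_set), NA-safe
standardized_features <- function(features, feature_set) {
  missing_cols <- setdiff(feature_set, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("features lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  z <- scale(as.matrix(features[, feature_set]))
  z[is.nan(z)] <- 0
  rownames(z) <- features$image_id
  z
}

#' Simulate complete baseline ratings
#'
#' Every participant rates every image once under the latent-cluster
#' preference model of [population_spec()].
#'
#' @param features feature tibble (from [compute_all_features()] or
#'   [simulate_feature_table()]); features are standardized over the
#'   collection before entering the model.
#' @param pop a [population_spec()].
#' @return Validated ratings tibble (phase `"baseline"`), complete.
#' @export
simulate_baseline_ratings <- function(features, pop) {
  stopifnot(inherits(pop, "population_spec"))
  z <- standardized_features(features, pop$feature_set)
  roster <- population_roster(pop)
  n_img <- nrow(z)
  withr::with_seed(pop$seed, {
    rows <- purrr::map_dfr(seq_len(nrow(roster)), function(p) {
      g <- roster$latent_cluster[p]
      latent <- pop$intercepts[g] + as.numeric(z %*% pop$weights[g, ]) +
        rnorm(n_img, 0, pop$sigma)
      tibble::tibble(
        participant_id = roster$participant_id[p],
        image_id = rownames(z),
        phase = "baseline",
        rating = as.integer(round(pmin(pmax(latent, 1), 4)))
      )
    })
    load_ratings(rows)
  })
}

#' Simulate post-adaptation ratings under both conditions
#'
#' Each participant rates the evaluation images of their (analysis)
#' cluster twice: once after adaptation to that cluster's most beautiful
#' images and once after its least beautiful images.  The latent rating
#' model is the baseline model plus the condition shift `+/- delta_i / 2`
#' (see [population_spec()]); the shift is symmetric so the condition-free
#' expectation equals the baseline model.  Condition order is
#' counterbalanced across participants and recorded in the `order` column.
#'
#' @param features feature tibble.
#' @param pop a [population_spec()].
#' @param adaptor_sets tibble from [select_adaptor_sets()].
#' @param assignment participant-to-cluster tibble (`participant_id`,
#'   `cluster`) from the clustering used to build `adaptor_sets`; defaults
#'   to the latent generator clusters.
#' @return List with `after_beautiful` and `after_least` ratings tibbles
#'   (each with an `order` column: `"beautiful_first"` or `"least_first"`).
#' @export
simulate_adaptation_ratings <- function(features, pop, adaptor_sets,
                                        assignment = NULL) {
  stopifnot(inherits(pop, "population_spec"))
  z <- standardized_features(features, pop$feature_set)
  z_ss <- if ("self_similarity" %in% colnames(z)) {
    setNames(z[, "self_similarity"], rownames(z))
  } else {
    setNames(rep(0, nrow(z)), rownames(z))
  }
  roster <- population_roster(pop)
  if (is.null(assignment)) {
    assignment <- tibble::tibble(
      participant_id = roster$participant_id,
      cluster = roster$latent_cluster
    )
  }
  roster <- dplyr::inner_join(roster, assignment, by = "participant_id")
  eval_sets <- adaptor_sets[adaptor_sets$role == "evaluation", , drop = FALSE]
  withr::with_seed(pop$seed + 1L, {
    per_participant <- purrr::map(seq_len(nrow(roster)), function(p) {
      g_lat <- roster$latent_cluster[p]
      imgs <- eval_sets$image_id[eval_sets$cluster == roster$cluster[p]]
      if (length(imgs) == 0) {
        abort(sprintf("no evaluation images for cluster %s", roster$cluster[p]))
      }
      zi <- z[imgs, , drop = FALSE]
      base <- pop$intercepts[g_lat] + as.numeric(zi %*% pop$weights[g_lat, ])
      delta <- (pop$delta0 + pop$delta1 * z_ss[imgs]) * pop$delta_sign[g_lat]
      order_lab <- if (pop$counterbalance && p %% 2 == 0) "least_first" else "beautiful_first"
      make <- function(phase, shift) {
        tibble::tibble(
          participant_id = roster$participant_id[p],
          image_id = imgs,
          phase = phase,
          rating = as.integer(round(pmin(pmax(
            base + shift + rnorm(length(imgs), 0, pop$sigma), 1
          ), 4))),
          order = order_lab
        )
      }
      list(
        ab = make("after_beautiful", +delta / 2),
        al = make("after_least", -delta / 2)
      )
    })
    list(
      after_beautiful = dplyr::bind_rows(purrr::map(per_participant, "ab")),
      after_least = dplyr::bind_rows(purrr::map(per_participant, "al"))
    )
  })
}
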