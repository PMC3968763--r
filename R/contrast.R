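#' Per-image perceptual contrast table
#'
#' The adaptation aftereffect is measured as a contrast: the same evaluation
#' image is rated once after adaptation to the cluster's most beautiful
#' images and once after its least beautiful images.  For every
#' (cluster, image) cell this function pools the ratings of the
#' participants who rated it under each condition and reports
#' `contrast = mean_after_beautiful - mean_after_least`.  A positive
#' contrast means the image was rated *less* beautiful (higher number on
#' the 1-4 scale) after beautiful adaptors — the headline direction of the
#' aftereffect.
#'
#' @param after_beautiful,after_least ratings tibbles for the two
#'   adaptation conditions (phases `"after_beautiful"` / `"after_least"`).
#' @param clusters a `rater_clusters` object or an assignment tibble.
#' @return A tibble of class `contrast_table` with columns `cluster`,
#'   `image_id`, `mean_after_beautiful`, `mean_after_least`, `contrast`.
#'   Images present under only one condition are excluded with a warning.
#' @export
compute_contrast <- function(after_beautiful, after_least, clusters) {
  assignment <- if (inherits(clusters, "rater_clusters")) clusters$assignment else clusters
  cond_means <- function(df, phase) {
    df <- df[df$phase == phase, , drop = FALSE]
    df |>
      dplyr::inner_join(assignment, by = "participant_id") |>
      dplyr::group_by(.data$cluster, .data$image_id) |>
      dplyr::summarise(m = mean(.data$rating), .groups = "drop")
  }
  ab <- cond_means(after_beautiful, "after_beautiful")
  al <- cond_means(after_least, "after_least")
  joined <- dplyr::inner_join(
    dplyr::rename(ab, mean_after_beautiful = "m"),
    dplyr::rename(al, mean_after_least = "m"),
    by = c("cluster", "image_id")
  )
  n_dropped <- nrow(ab) + nrow(al) - 2L * nrow(joined)
  if (n_dropped > 0) {
    warn(sprintf(
      "%d (cluster, image) cell(s) present under only one condition were excluded",
      n_dropped
    ))
  }
  out <- joined |>
    dplyr::mutate(contrast = .data$mean_after_beautiful - .data$mean_after_least) |>
    dplyr::arrange(.data$cluster, .data$image_id)
  class(out) <- c("contrast_table", class(out))
  out
}

#' Paired test of the perceptual-contrast effect across images
#'
#' Pools the contrast table to unique evaluation images (averaging the two
#' condition means within image across the clusters that evaluated it) and
#' runs a paired t-test of after-beautiful vs after-least ratings across
#' those images, reporting also the correlation between the two condition
#' vectors.  The t statistic is computed on
#' `after_beautiful - after_least`, so a positive mean difference gives a
#' positive t (published analyses sometimes print the negated sign; the
#' reported `mean_difference` keeps the direction unambiguous).
#'
#' Degenerate inputs are flagged rather than tested: if the per-image
#' differences have zero variance the t statistic is `0` (all differences
#' zero) or signed infinity (all equal and nonzero).
#'
#' @param table a `contrast_table` from [compute_contrast()].
#' @return Object of class `contrast_test`: list with `t`, `df`, `p`,
#'   `paired_correlation`, `mean_difference`, `n_images`, `degenerate`.
#' @export
paired_contrast_test <- function(table) {
  pooled <- table |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      ab = mean(.data$mean_after_beautiful),
      al = mean(.data$mean_after_least),
      .groups = "drop"
    )
  n <- nrow(pooled)
  if (n < 3) abort("need at least 3 images with both conditions")
  d <- pooled$ab - pooled$al
  res <- if (sd(d) == 0) {
    list(
      t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
      p = NA_real_, degenerate = TRUE
    )
  } else {
    tt <- t.test(pooled$ab, pooled$al, paired = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  }
  structure(
    list(
      t = res$t,
      df = n - 1L,
      p = res$p,
      paired_correlation = if (sd(pooled$ab) > 0 && sd(pooled$al) > 0) {
        cor(pooled$ab, pooled$al)
      } else {
        NA_real_
      },
      mean_difference = mean(d),
      n_images = n,
      degenerate = res$degenerate
    ),
    class = "contrast_test"
  )
}

#' @export
print.contrast_test <- function(x, ...) {
  cat(sprintf(
    "Paired contrast test across %d images: mean diff = %+.3f, r = %.3f, t(%d) = %.3f, p = %.3g%s\n",
    x$n_images, x$mean_difference,
    x$paired_correlation, x$df, x$t, x$p,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' @describeIn paired_contrast_test tidy() returns the test as a one-row
#'   tibble.
#' @param x a `contrast_test` object.
#' @param ... unused.
#' @export
tidy.contrast_test <- function(x, ...) {
  tibble::tibble(
    mean_difference = x$mean_difference,
    paired_correlation = x$paired_correlation,
    t = x$t, df = x$df, p = x$p,
    n_images = x$n_images, degenerate = x$degenerate
  )
}

#' Per-cluster contrast summary
#'
#' Condition means and SDs, the mean contrast, and a within-cluster paired
#' test across that cluster's evaluation images.  Clusters whose contrast
#' sign opposes the majority sign are flagged (`direction_flag`), surfacing
#' the occasional cluster that shows an *inverted* aftereffect.
#'
#' @param table a `contrast_table`.
#' @return Tibble with one row per cluster: `cluster`, `n_images`,
#'   `mean_after_beautiful`, `sd_after_beautiful`, `mean_after_least`,
#'   `sd_after_least`, `mean_contrast`, `t`, `p`, `direction_flag`.
#'   Clusters with fewer than 2 evaluation images are excluded with a
#'   warning.
#' @export
per_cluster_contrast_summary <- function(table) {
  sizes <- table |>
    dplyr::count(.data$cluster)
  small <- sizes$cluster[sizes$n < 2]
  if (length(small) > 0) {
    warn(sprintf(
      "excluded cluster(s) with < 2 evaluation images: %s",
      paste(small, collapse = ", ")
    ))
    table <- table[!table$cluster %in% small, , drop = FALSE]
  }
  out <- table |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      sd_after_beautiful = sd(.data$mean_after_beautiful),
      sd_after_least = sd(.data$mean_after_least),
      mean_after_beautiful = mean(.data$mean_after_beautiful),
      mean_after_least = mean(.data$mean_after_least),
      mean_contrast = mean(.data$contrast),
      t = if (sd(.data$contrast) > 0) {
        unname(t.test(.data$contrast)$statistic)
      } else {
        NA_real_
      },
      p = if (sd(.data$contrast) > 0) t.test(.data$contrast)$p.value else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::select(
      "cluster", "n_images", "mean_after_beautiful", "sd_after_beautiful",
      "mean_after_least", "sd_after_least", "mean_contrast", "t", "p"
    )
  majority <- sign(sum(sign(out$mean_contrast)))
  if (majority == 0) majority <- sign(mean(out$mean_contrast))
  dplyr::mutate(
    out,
    direction_flag = sign(.data$mean_contrast) != majority & .data$mean_contrast != 0
  )
}

#' Simulate image-level condition means for contrast calibration studies
#'
#' A direct image-level generator for calibration and power work on the
#' paired contrast test, bypassing the participant layer: each image gets a
#' latent mean `base_mean + N(0, image_sd^2)` shared by both conditions,
#' independent condition noise `N(0, resid_sd^2)`, and a condition shift of
#' `+delta0/2` (after beautiful) / `-delta0/2` (after least).  The defaults
#' (`image_sd = 0.16`, `resid_sd = 0.085`) give per-condition SDs near 0.19
#' and a paired correlation near 0.8 at the image-mean level, matching the
#' scale on which the aftereffect is observed.
#'
#' @param n_images number of evaluation images (default 132).
#' @param delta0 condition shift on the rating scale (default 0.16).
#' @param base_mean grand mean rating (default 2.76).
#' @param image_sd SD of the latent per-image mean.
#' @param resid_sd SD of the per-condition residual.
#' @param seed integer seed (optional).
#' @return A `contrast_table` tibble (single pseudo-cluster 1).
#' @export
simulate_contrast_means <- function(n_images = 132L, delta0 = 0.16,
                                    base_mean = 2.76, image_sd = 0.16,
                                    resid_sd = 0.085, seed = NULL) {
  draw <- function() {
    latent <- base_mean + rnorm(n_images, 0, image_sd)
    ab <- latent + delta0 / 2 + rnorm(n_images, 0, resid_sd)
    al <- latent - delta0 / 2 + rnorm(n_images, 0, resid_sd)
    out <- tibble::tibble(
      cluster = 1L,
      image_id = sprintf("img%03d", seq_len(n_images)),
      mean_after_beautiful = ab,
      mean_after_least = al,
      contrast = ab - al
    )
    class(out) <- c("contrast_table", class(out))
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
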