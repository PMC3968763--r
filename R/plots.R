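#' Plot clustering diagnostics against the number of clusters
#'
#' Within-cluster sum of squares, spherical-Gaussian BIC, and Dunn's index
#' for every cluster count evaluated — the evidence used (or, as often, the
#' lack of it) when fixing the experimental `k`.
#'
#' @param object a `rater_clusters` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rater_clusters <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$diagnostics, c("tot_withinss", "bic", "dunn"),
    names_to = "diagnostic", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::facet_wrap(~diagnostic, scales = "free_y") +
    ggplot2::labs(
      x = "number of clusters k", y = NULL,
      title = sprintf("k-means diagnostics (chosen k = %d)", object$k)
    )
}

#' Per-cluster condition means after adaptation
#'
#' Bar chart of the mean evaluation rating after beautiful vs after least
#' beautiful adaptors, per cluster, with SD error bars — the standard view
#' of the perceptual-contrast effect and of any cluster showing the
#' inverted pattern.  Lower bars mean "rated more beautiful".
#'
#' @param table a `contrast_table` from [compute_contrast()].
#' @return A ggplot object.
#' @export
plot_cluster_contrast <- function(table) {
  summ <- per_cluster_contrast_summary(table)
  long <- tidyr::pivot_longer(
    summ,
    c("mean_after_beautiful", "mean_after_least"),
    names_to = "condition", values_to = "mean_rating"
  )
  long$sd <- ifelse(
    long$condition == "mean_after_beautiful", summ$sd_after_beautiful[
      match(long$cluster, summ$cluster)
    ],
    summ$sd_after_least[match(long$cluster, summ$cluster)]
  )
  long$condition <- ifelse(
    long$condition == "mean_after_beautiful", "after beautiful", "after least"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$cluster), y = .data$mean_rating, fill = .data$condition
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_rating - .data$sd,
        ymax = .data$mean_rating + .data$sd
      ),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(
      x = "cluster", y = "mean beauty rating (1 = most beautiful)",
      fill = NULL, title = "Ratings after adaptation, by cluster"
    )
}

#' Heatmap of a Spearman association table
#'
#' Clusters by properties, tile fill = rho, significance stars at raw
#' p < 0.05 / p < 0.01.
#'
#' @param table output of [spearman_table()].
#' @return A ggplot object.
#' @export
plot_spearman_table <- function(table) {
  table$stars <- dplyr::case_when(
    is.na(table$p) ~ "",
    table$p < 0.01 ~ "**",
    table$p < 0.05 ~ "*",
    TRUE ~ ""
  )
  ggplot2::ggplot(table, ggplot2::aes(
    x = .data$property, y = factor(.data$cluster), fill = .data$rho
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(
      x = NULL, y = "cluster", fill = "Spearman rho",
      title = "Beauty-rating vs image-property correlations"
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Distributions of extracted image features
#'
#' Histograms of each feature over a collection — the quick check that a
#' stimulus set (synthetic or scanned) spans a usable range of every
#' statistic.
#'
#' @param features tibble from [compute_all_features()].
#' @param columns feature columns to show (defaults to the PHOG and color
#'   channels).
#' @return A ggplot object.
#' @export
plot_feature_distributions <- function(features,
                                       columns = intersect(PROPERTY_COLUMNS, names(features))) {
  long <- tidyr::pivot_longer(
    features[, c("image_id", columns)], -"image_id",
    names_to = "feature", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "images")
}
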