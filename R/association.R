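PROPERTY_COLUMNS <- c(
  "self_similarity", "complexity", "anisotropy", "birkhoff",
  "hsv_hue", "hsv_saturation", "hsv_value",
  "rgb_r", "rgb_g", "rgb_b", "lab_l", "lab_a", "lab_b"
)

REGRESSION_PREDICTORS <- c(
  "self_similarity", "complexity", "anisotropy", "birkhoff",
  "hsv_hue", "hsv_saturation", "hsv_value", "aspect_ratio",
  "lab_l", "lab_a", "lab_b"
)

MIXED_MODEL_PROPERTIES <- c(
  "self_similarity", "complexity", "anisotropy", "birkhoff",
  "hsv_hue", "hsv_saturation", "hsv_value", "aspect_ratio"
)

#' Spearman rank correlation with tie correction
#'
#' rho is the Pearson correlation of midranks (the tie-corrected Spearman
#' estimate).  The p-value uses the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` df by default; for small
#' samples an exact Monte-Carlo permutation p is available.
#'
#' @param x,y numeric vectors.
#' @param p_method `"t_approx"` (default) or `"permutation"` (recommended
#'   only for `n <= 30`).
#' @param n_perm number of permutations for `p_method = "permutation"`.
#' @param seed seed for the permutation draw.
#' @return One-row tibble: `rho`, `p`, `n`, `degenerate` (TRUE when either
#'   input is constant, in which case rho is `NA`).
#' @export
spearman_rho <- function(x, y, p_method = c("t_approx", "permutation"),
                         n_perm = 10000L, seed = 1L) {
  p_method <- match.arg(p_method)
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 5 || sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  p <- if (p_method == "t_approx") {
    if (abs(rho) >= 1) {
      0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tt), df = n - 2)
    }
  } else {
    withr::with_seed(seed, {
      perm <- vapply(seq_len(n_perm), function(i) cor(rx, sample(ry)), numeric(1))
      (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    })
  }
  tibble::tibble(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Spearman association table between cluster ratings and image properties
#'
#' For every cluster and every image property, the tie-corrected Spearman
#' correlation between the cluster's mean beauty ratings (raw 1-4 scale) and
#' the property across images.  Because 1 = most beautiful, a *positive*
#' rho means images with more of that property were rated *less* beautiful.
#' Raw p-values are reported (as association tables in this literature
#' conventionally are), alongside a Holm-adjusted column per cluster.
#'
#' @param cluster_means tibble (`cluster`, `image_id`, `mean_rating`), e.g.
#'   from [cluster_mean_ratings()]; the cluster column may be any label,
#'   including `"average evaluation"` for the all-participants profile.
#' @param features feature tibble from [compute_all_features()] (or any
#'   tibble with `image_id` plus property columns).
#' @param properties character vector of property columns to correlate
#'   (default: the PHOG and color-channel columns).
#' @param ... passed to [spearman_rho()].
#' @return Tibble with columns `cluster`, `property`, `rho`, `p`, `p_holm`,
#'   `n`, `degenerate` (constant properties are flagged, not dropped).
#' @export
spearman_table <- function(cluster_means, features,
                           properties = intersect(PROPERTY_COLUMNS, names(features)),
                           ...) {
  stopifnot(length(properties) > 0, all(properties %in% names(features)))
  joined <- dplyr::inner_join(cluster_means, features, by = "image_id")
  if (dplyr::n_distinct(joined$image_id) < 5) abort("need at least 5 images")
  out <- purrr::map_dfr(split(joined, joined$cluster), function(df) {
    rows <- purrr::map_dfr(properties, function(prop) {
      dplyr::mutate(
        spearman_rho(df[[prop]], df$mean_rating, ...),
        property = prop, .before = 1
      )
    })
    dplyr::mutate(rows,
      cluster = df$cluster[1], .before = 1,
      p_holm = p.adjust(.data$p, method = "holm")
    )
  })
  dplyr::select(
    out, "cluster", "property", "rho", "p", "p_holm", "n", "degenerate"
  )
}

#' Standardized multivariate linear regression across images
#'
#' Ordinary least squares after z-scoring the response and every predictor,
#' so the coefficients are standardized betas directly comparable across
#' predictors; with a single predictor the standardized beta equals the
#' Pearson correlation.  Rows with missing predictor or response values are
#' dropped (count recorded).  A condition number of the predictor matrix
#' above `kappa_warn` triggers a collinearity warning, but coefficients are
#' still reported.
#'
#' @param data tibble with one row per image.
#' @param response name of the response column.
#' @param predictors character vector of predictor columns.
#' @param kappa_warn condition-number threshold for the collinearity
#'   warning (default 30).
#' @return Object of class `std_regression`: list with `coefficients`
#'   (tibble `term`, `std_beta`, `se`, `statistic`, `p`), `r_squared`,
#'   `n`, `n_dropped`, `condition_number`, `response`, and the underlying
#'   `lm` fit.
#' @export
regression_standardized <- function(data, response, predictors,
                                    kappa_warn = 30) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  df <- data[, c(response, predictors), drop = FALSE]
  keep <- complete.cases(df)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d row(s) with missing values", n_dropped))
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < length(predictors) + 2) abort("too few complete rows to fit")
  z <- as.data.frame(lapply(df, function(col) as.numeric(scale(col))))
  names(z) <- c(".y", predictors)
  x_mat <- as.matrix(z[, predictors, drop = FALSE])
  kappa_x <- kappa(x_mat, exact = TRUE)
  if (kappa_x > kappa_warn) {
    warn(sprintf(
      "predictor condition number %.1f exceeds %.0f; collinear predictors",
      kappa_x, kappa_warn
    ))
  }
  fit <- lm(
    stats::reformulate(predictors, response = ".y"),
    data = z
  )
  sm <- summary(fit)
  co <- matrix(NA_real_, length(predictors), 4,
               dimnames = list(predictors, colnames(sm$coefficients)))
  est <- sm$coefficients[intersect(predictors, rownames(sm$coefficients)), ,
                         drop = FALSE]
  if (nrow(est) < length(predictors)) {
    warn(sprintf(
      "%d aliased (perfectly collinear) predictor(s) dropped by the fit",
      length(predictors) - nrow(est)
    ))
  }
  co[rownames(est), ] <- est
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(co),
        std_beta = co[, 1],
        se = co[, 2],
        statistic = co[, 3],
        p = co[, 4]
      ),
      r_squared = sm$r.squared,
      n = nrow(df),
      n_dropped = n_dropped,
      condition_number = kappa_x,
      response = response,
      fit = fit
    ),
    class = "std_regression"
  )
}

#' @export
print.std_regression <- function(x, ...) {
  cat(sprintf(
    "<std_regression '%s': n = %d, R^2 = %.3f>\n", x$response, x$n, x$r_squared
  ))
  print(x$coefficients)
  invisible(x)
}

#' @describeIn regression_standardized tidy() returns the standardized
#'   coefficient table.
#' @param x a `std_regression` object.
#' @param ... unused.
#' @export
tidy.std_regression <- function(x, ...) x$coefficients

#' @describeIn regression_standardized glance() returns a one-row model
#'   summary.
#' @export
glance.std_regression <- function(x, ...) {
  tibble::tibble(
    response = x$response, r_squared = x$r_squared, n = x$n,
    n_dropped = x$n_dropped, condition_number = x$condition_number
  )
}

#' Linear mixed model with cluster-by-property interactions
#'
#' Observations are (image, cluster) pairs with the cluster mean beauty
#' rating as dependent variable; cluster is a fixed factor, the image
#' properties are covariates, and each image contributes one random
#' intercept (the only grouping factor left once cluster is fixed).  The
#' cluster-by-property interactions ask whether the effect of a property on
#' the rating differs between preference clusters; each is tested by a
#' Satterthwaite F (Type III).  Per-cluster regression coefficients for
#' each property, with their p-values, come from the cluster-conditional
#' slopes of the fitted model ([emmeans::emtrends()]).
#'
#' @param cluster_means tibble (`cluster`, `image_id`, `mean_rating`).
#' @param features feature tibble with `image_id` and property columns.
#' @param properties property columns used as covariates (default: PHOG
#'   statistics, HSV channels, aspect ratio).
#' @return Object of class `cluster_mixed_model`: list with `anova`
#'   (tibble `property`, `F`, `df1`, `df2`, `p` for each interaction),
#'   `slopes` (tibble `cluster`, `property`, `rc`, `se`, `df`, `p`),
#'   `singular` flag, and the `lmerMod` fit.  A singular fit is reported in
#'   the object and by a message — never silently refitted.
#' @export
mixed_model_cluster_interaction <- function(cluster_means, features,
                                            properties = intersect(MIXED_MODEL_PROPERTIES, names(features))) {
  stopifnot(length(properties) > 0, all(properties %in% names(features)))
  if (dplyr::n_distinct(cluster_means$cluster) < 2) abort("need at least 2 clusters")
  df <- dplyr::inner_join(cluster_means, features, by = "image_id")
  df$cluster <- factor(df$cluster)
  fml <- stats::as.formula(paste(
    "mean_rating ~ cluster *",
    paste0("(", paste(properties, collapse = " + "), ")"),
    "+ (1 | image_id)"
  ))
  fit <- lmerTest::lmer(fml, data = df, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    inform("mixed model fit is singular (a variance component is ~0); results reported as-is")
  }
  an <- anova(fit, type = 3)
  inter_terms <- paste0("cluster:", properties)
  an_tbl <- tibble::tibble(
    property = properties,
    F = an[inter_terms, "F value"],
    df1 = an[inter_terms, "NumDF"],
    df2 = an[inter_terms, "DenDF"],
    p = an[inter_terms, "Pr(>F)"]
  )
  slopes <- purrr::map_dfr(properties, function(prop) {
    tr <- summary(emmeans::emtrends(fit, ~cluster, var = prop,
                                    lmer.df = "satterthwaite"),
                  infer = c(FALSE, TRUE))
    tibble::tibble(
      cluster = as.character(tr$cluster),
      property = prop,
      rc = tr[[2]],
      se = tr$SE,
      df = tr$df,
      p = tr$p.value
    )
  })
  structure(
    list(anova = an_tbl, slopes = slopes, singular = singular, fit = fit),
    class = "cluster_mixed_model"
  )
}

#' @export
print.cluster_mixed_model <- function(x, ...) {
  cat(sprintf(
    "<cluster_mixed_model: %d properties%s>\n",
    nrow(x$anova), if (x$singular) ", SINGULAR fit" else ""
  ))
  print(x$anova)
  invisible(x)
}

#' @describeIn mixed_model_cluster_interaction tidy() returns the
#'   per-cluster regression coefficients.
#' @param x a `cluster_mixed_model` object.
#' @param ... unused.
#' @export
tidy.cluster_mixed_model <- function(x, ...) x$slopes

#' @describeIn mixed_model_cluster_interaction glance() returns the
#'   interaction F table with the singularity flag.
#' @export
glance.cluster_mixed_model <- function(x, ...) {
  dplyr::mutate(x$anova, singular = x$singular)
}

#' Hue-group (six-sector) preference analysis
#'
#' Hue is circular, so channel-mean correlations can hide sector-specific
#' preferences.  This analysis correlates (Spearman) the pixel fraction of
#' each of the six hue sectors with the cluster mean ratings, applying a
#' Holm correction across the six sectors within each cluster.  Sectors
#' with constant fractions (e.g. an all-grayscale collection) are flagged
#' degenerate.
#'
#' @param cluster_means tibble (`cluster`, `image_id`, `mean_rating`).
#' @param features feature tibble containing the `hue_*` sector columns.
#' @param ... passed to [spearman_rho()].
#' @return Tibble `cluster`, `sector`, `rho`, `p`, `p_holm`, `n`,
#'   `degenerate`.
#' @export
hue_group_analysis <- function(cluster_means, features, ...) {
  sectors <- paste0("hue_", HUE_SECTORS)
  stopifnot(all(sectors %in% names(features)))
  out <- spearman_table(cluster_means, features, properties = sectors, ...)
  dplyr::rename(out, sector = "property")
}

#' Quadratic (inverted-U) probe for a feature
#'
#' Fits `rating ~ feature + feature^2` on standardized variables and
#' reports the quadratic term — a concrete probe for an inverted-U
#' relationship between, e.g., complexity and beauty.
#'
#' @param data tibble with one row per image.
#' @param response response column name.
#' @param feature feature column name.
#' @return One-row tibble: `linear_beta`, `quadratic_beta`, `quadratic_p`,
#'   `r_squared`.
#' @export
quadratic_probe <- function(data, response, feature) {
  z <- tibble::tibble(
    y = as.numeric(scale(data[[response]])),
    x = as.numeric(scale(data[[feature]]))
  )
  fit <- lm(y ~ x + I(x^2), data = z)
  sm <- summary(fit)
  tibble::tibble(
    linear_beta = coef(fit)[["x"]],
    quadratic_beta = coef(fit)[["I(x^2)"]],
    quadratic_p = sm$coefficients["I(x^2)", 4],
    r_squared = sm$r.squared
  )
}
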