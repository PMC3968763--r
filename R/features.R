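FEATURE_COLUMNS <- c(
  "self_similarity", "complexity", "anisotropy", "birkhoff", "aspect_ratio",
  "hsv_hue", "hsv_saturation", "hsv_value",
  "rgb_r", "rgb_g", "rgb_b", "lab_l", "lab_a", "lab_b",
  paste0("hue_", HUE_SECTORS), "achromatic_fraction"
)

#' Compute the full feature record of one image
#'
#' Runs the whole image-analysis chain on a single image: fixed-budget
#' bicubic downsampling, Lab gradient field, PHOG pyramid, the four
#' PHOG-derived statistics (self-similarity, complexity, anisotropy,
#' Birkhoff-like measure), aspect ratio (from the original dimensions), the
#' nine per-channel color means, and the six hue-sector fractions.
#'
#' @param img a [raster_image()].
#' @param pixel_budget downsampling target passed to [preprocess_image()].
#' @param ss_aggregate aggregation of the 64 level-3 intersections,
#'   `"median"` or `"mean"` (see [self_similarity()]).
#' @param anisotropy_pooling `"pooled"` or `"per_block"` (see [anisotropy()]).
#' @param hue_mean `"arithmetic"` or `"circular"` (see
#'   [color_channel_means()]).
#' @return One-row tibble with `image_id`, the feature columns in fixed
#'   order, and `degenerate_flags` (semicolon-separated warnings, `""` when
#'   clean).
#' @export
#' @examples
#' img <- generate_image("grating", width = 120, height = 90, orientation = 30)
#' compute_features(img, pixel_budget = 120 * 90)
compute_features <- function(img, pixel_budget = 1e5,
                             ss_aggregate = c("median", "mean"),
                             anisotropy_pooling = c("pooled", "per_block"),
                             hue_mean = c("arithmetic", "circular")) {
  stopifnot(inherits(img, "raster_image"))
  ss_aggregate <- match.arg(ss_aggregate)
  anisotropy_pooling <- match.arg(anisotropy_pooling)
  hue_mean <- match.arg(hue_mean)

  ar <- aspect_ratio(img)
  pre <- preprocess_image(img, pixel_budget = pixel_budget)
  field <- compute_gradient_field(pre)
  pyr <- build_hog_pyramid(field)

  ss <- self_similarity(pyr, aggregate = ss_aggregate)
  comp <- complexity(field)
  ani <- anisotropy(pyr, pooling = anisotropy_pooling)
  bir <- birkhoff_measure(ss, comp)

  flags <- character(0)
  if (isTRUE(attr(ss, "degenerate"))) flags <- c(flags, "self_similarity_undefined")
  if (isTRUE(attr(ani, "degenerate"))) flags <- c(flags, "anisotropy_undefined")
  if (isTRUE(attr(bir, "degenerate"))) flags <- c(flags, "birkhoff_undefined")

  colors <- color_channel_means(pre, hue_mean = hue_mean)
  hues <- hue_sector_fractions(pre)
  if (hues$achromatic_fraction == 1) flags <- c(flags, "achromatic_image")

  dplyr::bind_cols(
    tibble::tibble(
      image_id = img$id,
      self_similarity = as.numeric(ss),
      complexity = comp,
      anisotropy = as.numeric(ani),
      birkhoff = as.numeric(bir),
      aspect_ratio = ar
    ),
    colors,
    hues,
    tibble::tibble(degenerate_flags = paste(flags, collapse = ";"))
  )
}

#' Compute features for a collection of images
#'
#' Vectorized front end over [compute_features()].  Accepts either a list of
#' [raster_image()] objects or a manifest data frame with columns `image_id`
#' and `path`; unreadable files are skipped with a warning and appear as a
#' flagged all-`NA` row, so one corrupt scan never aborts a batch.
#'
#' @param images list of `raster_image` objects, or a data frame manifest
#'   (`image_id`, `path`).
#' @param ... passed on to [compute_features()].
#' @return Tibble with one row per image, columns in fixed order, ready to
#'   serialize with [readr::write_csv()].  Deterministic given its inputs.
#' @export
compute_all_features <- function(images, ...) {
  if (is.data.frame(images)) {
    stopifnot(all(c("image_id", "path") %in% names(images)))
    images <- purrr::map2(images$path, images$image_id, function(p, id) {
      tryCatch(read_raster_image(p, id = id), error = function(e) {
        warn(sprintf("skipping unreadable image '%s' (%s): %s", id, p, conditionMessage(e)))
        structure(list(id = id), class = "unreadable_image")
      })
    })
  }
  if (length(images) == 0) abort("no images supplied")
  purrr::map_dfr(images, function(img) {
    if (inherits(img, "unreadable_image")) {
      row <- tibble::as_tibble(setNames(
        as.list(rep(NA_real_, length(FEATURE_COLUMNS))), FEATURE_COLUMNS
      ))
      return(dplyr::bind_cols(
        tibble::tibble(image_id = img$id), row,
        tibble::tibble(degenerate_flags = "read_error")
      ))
    }
    compute_features(img, ...)
  })
}
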