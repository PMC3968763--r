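#' Construct a raster image
#'
#' The basic unit of image analysis: an 8-bit RGB pixel grid stored as an
#' `H x W x 3` array of integers in `[0, 255]`, plus an identifier.  All
#' feature extraction in the package operates on this type.
#'
#' @param pixels numeric array of dimension `H x W x 3`, values in `[0, 255]`.
#'   A matrix (grayscale) is promoted to three identical channels.
#' @param id character scalar identifying the image.
#'
#' @return An object of class `raster_image`: a list with elements `pixels`
#'   (integer array), `height_px`, `width_px`, `id`.
#' @export
#' @examples
#' img <- raster_image(array(128, dim = c(32, 32, 3)), id = "gray")
#' img$height_px
raster_image <- function(pixels, id = "img") {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array (or an H x W matrix).")
  }
  if (anyNA(pixels)) abort("`pixels` must not contain missing values.")
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("`pixels` must lie in [0, 255].")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(
      pixels = pixels,
      height_px = dim(pixels)[1],
      width_px = dim(pixels)[2],
      id = as.character(id)
    ),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf(
    "<raster_image '%s': %d x %d px, 3 channels>\n",
    x$id, x$height_px, x$width_px
  ))
  invisible(x)
}

#' Read a raster image from a PNG or TIFF file
#'
#' Reads an 8-bit image file and returns a [raster_image()].  Grayscale
#' images are promoted to RGB; an alpha channel, if present, is dropped.
#'
#' @param path file path; format detected from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @param id image identifier; defaults to the file name without extension.
#' @return A [raster_image()].
#' @export
read_raster_image <- function(path, id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext))
  )
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  raster_image(round(arr * 255), id = id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a raster image to a PNG file
#'
#' @param img a [raster_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}

# Keys cubic-convolution kernel (a = -0.5); partition of unity, so rows of the
# resampling matrix sum to 1 for any sub-pixel phase.
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(
    x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
    ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0)
  )
}

# Dense n_dst x n_src bicubic resampling matrix with edge replication,
# center-aligned coordinate mapping.
resample_matrix <- function(n_src, n_dst) {
  pos <- (seq_len(n_dst) - 0.5) * n_src / n_dst + 0.5 # 1-based source coords
  i0 <- floor(pos)
  w <- matrix(0, n_dst, n_src)
  for (k in -1:2) {
    idx <- pmin(pmax(i0 + k, 1L), n_src)
    wk <- cubic_kernel(pos - (i0 + k))
    w[cbind(seq_len(n_dst), idx)] <- w[cbind(seq_len(n_dst), idx)] + wk
  }
  w
}

#' Downsample an image to a fixed pixel budget
#'
#' Resamples an image so that its total pixel count is as close as possible
#' to `pixel_budget` while preserving the aspect ratio, using bicubic
#' (Keys cubic-convolution) interpolation with edge replication.  Scanned
#' artwork reproductions often carry halftone dots at full resolution;
#' analysing all images at one fixed size removes that artifact and makes
#' gradient statistics comparable across images.
#'
#' @param img a [raster_image()].
#' @param pixel_budget target total pixel count (default 100000).
#' @return A [raster_image()] whose area is within ~2% of `pixel_budget`.
#'   If the target dimensions equal the input dimensions the input is
#'   returned unchanged.
#' @export
#' @examples
#' img <- generate_image("spectral_noise", width = 100, height = 100, seed = 1)
#' small <- preprocess_image(img, pixel_budget = 2500)
#' dim(small$pixels)
preprocess_image <- function(img, pixel_budget = 1e5) {
  stopifnot(inherits(img, "raster_image"))
  if (pixel_budget < 256) abort("`pixel_budget` must be at least 256.")
  h <- img$height_px
  w <- img$width_px
  if (h < 16 || w < 16) {
    abort(sprintf("image '%s' is %d x %d; at least 16 x 16 required", img$id, h, w))
  }
  ar <- h / w
  h2 <- max(16L, as.integer(round(sqrt(pixel_budget * ar))))
  w2 <- max(16L, as.integer(round(sqrt(pixel_budget / ar))))
  if (h2 == h && w2 == w) {
    return(img)
  }
  wr <- resample_matrix(h, h2)
  wc <- resample_matrix(w, w2)
  out <- array(0, dim = c(h2, w2, 3L))
  for (ch in 1:3) {
    out[, , ch] <- wr %*% img$pixels[, , ch] %*% t(wc)
  }
  out <- round(pmin(pmax(out, 0), 255))
  raster_image(out, id = img$id)
}

#' Aspect ratio of an image
#'
#' The quotient of image height over width, taken from the original
#' (pre-downsampling) dimensions.
#'
#' @param img a [raster_image()].
#' @return height / width as a positive real.
#' @export
aspect_ratio <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  img$height_px / img$width_px
}
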