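#' Convert an RGB image to CIE Lab channels
#'
#' sRGB (8-bit, D65) to CIE Lab via the standard CIE pipeline
#' ([grDevices::convertColor()]).  Returned as three `H x W` matrices with
#' `L` in `[0, 100]` and signed `a`, `b`.
#'
#' @param img a [raster_image()].
#' @return list with matrices `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  h <- img$height_px
  w <- img$width_px
  pix <- matrix(as.numeric(img$pixels), ncol = 3L) / 255
  lab <- grDevices::convertColor(pix, from = "sRGB", to = "Lab")
  list(
    L = matrix(lab[, 1], h, w),
    a = matrix(lab[, 2], h, w),
    b = matrix(lab[, 3], h, w)
  )
}

# Centered differences ([-1, 0, 1] per axis) with edge replication.
# Rows increase downward, so gy is the down-positive derivative.
channel_gradient <- function(x) {
  h <- nrow(x)
  w <- ncol(x)
  gx <- x[, c(2:w, w), drop = FALSE] - x[, c(1, 1:(w - 1)), drop = FALSE]
  gy <- x[c(2:h, h), , drop = FALSE] - x[c(1, 1:(h - 1)), , drop = FALSE]
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

#' Compute the oriented gradient field of an image
#'
#' The image is converted to Lab space and centered-difference gradients are
#' computed independently in the L, a, and b channels (with edge
#' replication at the borders).  For each pixel, the channel with the
#' largest gradient magnitude supplies both the magnitude and the
#' orientation of the field at that pixel, so chromatic edges register even
#' where luminance is flat.
#'
#' Orientation is `atan2(gy, gx)` in degrees, mapped to `[0, 360)`.  Pixels
#' with zero magnitude carry the sentinel orientation 0; they contribute no
#' mass to any histogram.
#'
#' @param img a [raster_image()], normally after [preprocess_image()].
#' @return An object of class `gradient_field`: list with `magnitude` and
#'   `orientation_deg` matrices (same shape as the image) and the source
#'   image `id`.
#' @export
#' @examples
#' img <- raster_image(array(200, dim = c(16, 16, 3)))
#' fld <- compute_gradient_field(img)
#' max(fld$magnitude) # constant image: no edges
compute_gradient_field <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  lab <- rgb_to_lab(img)
  gl <- channel_gradient(lab$L)
  ga <- channel_gradient(lab$a)
  gb <- channel_gradient(lab$b)
  mags <- cbind(c(gl$magnitude), c(ga$magnitude), c(gb$magnitude))
  pick <- max.col(mags, ties.method = "first")
  n <- length(pick)
  sel <- cbind(seq_len(n), pick)
  gx <- cbind(c(gl$gx), c(ga$gx), c(gb$gx))[sel]
  gy <- cbind(c(gl$gy), c(ga$gy), c(gb$gy))[sel]
  mag <- mags[sel]
  ori <- (atan2(gy, gx) * 180 / pi) %% 360
  ori[mag == 0] <- 0
  h <- img$height_px
  w <- img$width_px
  structure(
    list(
      magnitude = matrix(mag, h, w),
      orientation_deg = matrix(ori, h, w),
      id = img$id
    ),
    class = "gradient_field"
  )
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf(
    "<gradient_field '%s': %d x %d, mean |g| = %.3f>\n",
    x$id, nrow(x$magnitude), ncol(x$magnitude), mean(x$magnitude)
  ))
  invisible(x)
}
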