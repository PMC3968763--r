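#' Per-channel color statistics
#'
#' Mean pixel value of each channel after conversion to three color spaces:
#' HSV (all channels in `[0, 1]`), RGB (in `[0, 255]`), and CIE Lab (`L` in
#' `[0, 100]`, signed `a`, `b`; sRGB with D65 white point).
#'
#' Hue is a circular quantity, but the default here is the plain arithmetic
#' mean of the hue channel, which is the convention used for tabulated
#' channel means in this line of work; set `hue_mean = "circular"` for the
#' circular mean (resultant-vector angle) instead.
#'
#' @param img a [raster_image()].
#' @param hue_mean `"arithmetic"` (default) or `"circular"`.
#' @return One-row tibble with columns `hsv_hue`, `hsv_saturation`,
#'   `hsv_value`, `rgb_r`, `rgb_g`, `rgb_b`, `lab_l`, `lab_a`, `lab_b`.
#' @export
#' @examples
#' red <- raster_image(array(rep(c(255, 0, 0), each = 16 * 16), c(16, 16, 3)))
#' color_channel_means(red)
color_channel_means <- function(img, hue_mean = c("arithmetic", "circular")) {
  stopifnot(inherits(img, "raster_image"))
  hue_mean <- match.arg(hue_mean)
  pix <- matrix(as.numeric(img$pixels), ncol = 3L)
  hsv <- grDevices::rgb2hsv(t(pix), maxColorValue = 255)
  hue <- if (hue_mean == "arithmetic") {
    mean(hsv["h", ])
  } else {
    ang <- hsv["h", ] * 2 * pi
    (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1
  }
  lab <- grDevices::convertColor(pix / 255, from = "sRGB", to = "Lab")
  tibble::tibble(
    hsv_hue = hue,
    hsv_saturation = mean(hsv["s", ]),
    hsv_value = mean(hsv["v", ]),
    rgb_r = mean(pix[, 1]),
    rgb_g = mean(pix[, 2]),
    rgb_b = mean(pix[, 3]),
    lab_l = mean(lab[, 1]),
    lab_a = mean(lab[, 2]),
    lab_b = mean(lab[, 3])
  )
}

HUE_SECTORS <- c("red", "yellow", "green", "cyan", "blue", "magenta")

#' Fractions of pixels per hue sector
#'
#' Splits the hue circle into six 60-degree sectors centered on the primary
#' and secondary hues (red = `[330, 30)` degrees, then yellow, green, cyan,
#' blue, magenta) and reports the fraction of pixels falling in each.  Every
#' pixel is assigned by its raw hue, so the six fractions always sum to 1;
#' pixels whose saturation falls below `achromatic_threshold` additionally
#' contribute to a separate achromatic tally, because hue is numerically
#' unstable near zero saturation.
#'
#' @param img a [raster_image()].
#' @param achromatic_threshold saturation below which a pixel is counted as
#'   achromatic (default 0.05).
#' @return One-row tibble with columns `hue_red` ... `hue_magenta` (summing
#'   to 1) and `achromatic_fraction`.
#' @export
hue_sector_fractions <- function(img, achromatic_threshold = 0.05) {
  stopifnot(inherits(img, "raster_image"))
  pix <- matrix(as.numeric(img$pixels), ncol = 3L)
  hsv <- grDevices::rgb2hsv(t(pix), maxColorValue = 255)
  deg <- hsv["h", ] * 360
  sector <- (as.integer((deg + 30) %/% 60) %% 6L) + 1L
  frac <- tabulate(sector, nbins = 6L) / length(sector)
  out <- tibble::as_tibble(as.list(setNames(frac, paste0("hue_", HUE_SECTORS))))
  out$achromatic_fraction <- mean(hsv["s", ] < achromatic_threshold)
  out
}
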