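#' Generate a synthetic image with controlled statistical structure
#'
#' Deterministic (per seed) generators standing in for scanned artworks, so
#' every pipeline stage is testable without copyrighted stimuli.  Kinds:
#'
#' * `"constant"`: a single flat color — zero complexity, undefined
#'   self-similarity (degenerate gradient field).
#' * `"grating"`: sinusoidal luminance grating at a given orientation.
#' * `"ramp"`: a linear luminance ramp at a given orientation; the gradient
#'   direction is constant over the whole image, so every pyramid histogram
#'   is one-hot in the same bin (maximal anisotropy, self-similarity 1).
#' * `"ramp_mosaic"`: a separable piecewise-linear grid `F(x) + G(y)` with
#'   integer slopes alternating in sign per grid strip.  Each grid cell has
#'   an exactly constant gradient direction distinct from its neighbours, so
#'   the level-3 histograms are one-hot in scattered bins: low
#'   self-similarity and near-maximal pooled anisotropy.
#' * `"block_mosaic"`: grid of sinusoidal gratings with distinct
#'   orientations per block.
#' * `"periodic_tiling"`: one seamless (circularly periodic) texture tile
#'   repeated on an `n_tiles x n_tiles` grid aligned with the level-3
#'   partition, so all 64 subimages are pixel-identical to each other —
#'   self-similarity 1.
#' * `"spectral_noise"`: random-phase noise with amplitude spectrum
#'   `1/f^slope`; larger `slope` means smoother images and monotonically
#'   lower measured complexity.
#' * `"color_field"`: smooth bilinear blend of four corner colors — for
#'   exercising the color statistics.
#'
#' @param kind one of the kinds above.
#' @param width,height image dimensions in pixels.
#' @param seed integer seed; the output is fully determined by the spec
#'   (global RNG state is preserved).
#' @param id image identifier (default built from `kind` and `seed`).
#' @param color base color for `"constant"` (RGB in 0-255).
#' @param orientation grating/ramp orientation in degrees.
#' @param frequency cycles per image for `"grating"`.
#' @param n_blocks grid size for the mosaic kinds.
#' @param n_tiles grid size for `"periodic_tiling"` (default 8, matching the
#'   level-3 partition).
#' @param slope spectral slope for `"spectral_noise"` (typical range 0.5-3).
#' @param saturation chroma of the tint applied to the textured kinds, in
#'   `[0, 1]`.
#' @return A [raster_image()].
#' @export
#' @examples
#' img <- generate_image("spectral_noise", width = 64, height = 64,
#'                       slope = 1.5, seed = 7)
generate_image <- function(kind = c("constant", "grating", "ramp", "ramp_mosaic",
                                    "block_mosaic", "periodic_tiling",
                                    "spectral_noise", "color_field"),
                           width = 316L, height = 316L, seed = 1L, id = NULL,
                           color = c(128, 128, 128), orientation = 0,
                           frequency = 8, n_blocks = 8L, n_tiles = 8L,
                           slope = 1.5, saturation = 0) {
  kind <- match.arg(kind)
  if (width < 16 || height < 16) abort("images must be at least 16 x 16")
  id <- id %||% sprintf("%s_%d", kind, seed)
  gray <- withr::with_seed(seed, switch(kind,
    constant = NULL,
    grating = grating_pattern(height, width, orientation, frequency),
    ramp = ramp_pattern(height, width, orientation),
    ramp_mosaic = ramp_mosaic_pattern(height, width, n_blocks),
    block_mosaic = block_mosaic_pattern(height, width, n_blocks, frequency),
    periodic_tiling = tiling_pattern(height, width, n_tiles),
    spectral_noise = spectral_noise_pattern(height, width, slope),
    color_field = NULL
  ))
  px <- switch(kind,
    constant = {
      stopifnot(length(color) == 3, all(color >= 0), all(color <= 255))
      array(rep(round(color), each = height * width), c(height, width, 3L))
    },
    color_field = withr::with_seed(seed, color_field_pattern(height, width)),
    tint_gray(gray, seed = seed, saturation = saturation)
  )
  raster_image(px, id = id)
}

# rescale a real-valued pattern matrix to integers 0..255; patterns that
# are already exact 8-bit integers (the seam-exact mosaics) pass through
# untouched so their integer slopes survive
to_255 <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) {
    return(matrix(128L, nrow(m), ncol(m)))
  }
  if (rng[1] >= 0 && rng[2] <= 255 && all(m == round(m))) {
    return(m)
  }
  round((m - rng[1]) / diff(rng) * 255)
}

# apply an optional uniform color tint to a grayscale pattern
tint_gray <- function(gray, seed, saturation = 0) {
  h <- nrow(gray)
  w <- ncol(gray)
  g <- to_255(gray)
  if (saturation <= 0) {
    return(array(rep(g, 3L), c(h, w, 3L)))
  }
  hue <- withr::with_seed(seed + 1000L, runif(1))
  rgb_w <- as.numeric(grDevices::col2rgb(grDevices::hsv(hue, 1, 1))) / 255
  out <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    scale_ch <- (1 - saturation) + saturation * rgb_w[ch]
    out[, , ch] <- round(g * scale_ch)
  }
  out
}

grating_pattern <- function(h, w, orientation, frequency) {
  th <- orientation * pi / 180
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  u <- (x * cos(th) + y * sin(th)) / max(h, w)
  sin(2 * pi * frequency * u)
}

ramp_pattern <- function(h, w, orientation) {
  th <- orientation * pi / 180
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  x * cos(th) + y * sin(th)
}

# Separable F(x) + G(y) with exact integer slopes, sign-paired per strip so
# the value range stays inside 8 bits without rescaling.  Within each
# interior cell the centered-difference gradient is exactly (2 gx, 2 gy),
# hence a single exact orientation per cell and a one-hot histogram; only
# the pixel rows/columns straddling a seam mix slopes, and those carry low
# magnitude because adjacent slopes nearly cancel.  Must not be rescaled:
# non-integer slopes would quantize into mixed orientations.
ramp_mosaic_pattern <- function(h, w, n_blocks) {
  slopes_x <- rep_len(c(1L, -1L, 2L, -2L, 2L, -2L, 1L, -1L), n_blocks)
  slopes_y <- rep_len(c(2L, -2L, 1L, -1L, 1L, -1L, 2L, -2L), n_blocks)
  strip_profile <- function(n_pixels, slopes) {
    br <- level_breaks(n_pixels, length(slopes))
    steps <- unlist(lapply(seq_along(slopes), function(i) {
      rep(slopes[i], br$ends[i] - br$starts[i] + 1L)
    }))
    cumsum(c(0L, steps[-n_pixels]))
  }
  fx <- strip_profile(w, slopes_x)
  gy <- strip_profile(h, slopes_y)
  m <- outer(gy, fx, `+`)
  m <- m - min(m)
  if (max(m) > 255) m <- m %% 256L # only reachable for extreme block counts
  m
}

block_mosaic_pattern <- function(h, w, n_blocks, frequency) {
  rb <- level_breaks(h, n_blocks)
  cb <- level_breaks(w, n_blocks)
  orientations <- matrix(
    (seq_len(n_blocks^2) - 1L) * 180 / n_blocks^2,
    n_blocks, n_blocks
  )
  out <- matrix(0, h, w)
  for (r in seq_len(n_blocks)) {
    for (cc in seq_len(n_blocks)) {
      rows <- rb$starts[r]:rb$ends[r]
      cols <- cb$starts[cc]:cb$ends[cc]
      out[rows, cols] <- grating_pattern(
        length(rows), length(cols), orientations[r, cc], frequency
      )
    }
  }
  out
}

# seamless tile (sum of circularly periodic sinusoids), repeated
tiling_pattern <- function(h, w, n_tiles) {
  th <- ceiling(h / n_tiles)
  tw <- ceiling(w / n_tiles)
  x <- matrix(rep(seq_len(tw) - 1L, each = th), th, tw)
  y <- matrix(rep(seq_len(th) - 1L, times = tw), th, tw)
  tile <- matrix(0, th, tw)
  n_comp <- 4L
  fx <- sample.int(3L, n_comp, replace = TRUE)
  fy <- sample.int(3L, n_comp, replace = TRUE)
  ph <- runif(n_comp, 0, 2 * pi)
  amp <- runif(n_comp, 0.5, 1)
  for (i in seq_len(n_comp)) {
    tile <- tile + amp[i] * sin(2 * pi * (fx[i] * x / tw + fy[i] * y / th) + ph[i])
  }
  big <- tile[rep(seq_len(th), n_tiles), rep(seq_len(tw), n_tiles)]
  big[seq_len(h), seq_len(w)]
}

spectral_noise_pattern <- function(h, w, slope) {
  fy <- c(seq(0, floor(h / 2)), seq(-ceiling(h / 2) + 1, -1)) / h
  fx <- c(seq(0, floor(w / 2)), seq(-ceiling(w / 2) + 1, -1)) / w
  f <- sqrt(outer(fy^2, fx^2, `+`))
  f[1, 1] <- Inf # zero out DC
  amp <- f^(-slope)
  phase <- matrix(runif(h * w, 0, 2 * pi), h, w)
  spec <- amp * exp(1i * phase)
  Re(fft(spec, inverse = TRUE)) / (h * w)
}

color_field_pattern <- function(h, w) {
  corners <- matrix(runif(12, 0, 255), 4, 3) # rows: TL, TR, BL, BR
  u <- (seq_len(w) - 1) / (w - 1)
  v <- (seq_len(h) - 1) / (h - 1)
  out <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    top <- outer(rep(1, h), corners[1, ch] * (1 - u) + corners[2, ch] * u)
    bot <- outer(rep(1, h), corners[3, ch] * (1 - u) + corners[4, ch] * u)
    out[, , ch] <- round((1 - v) * top + v * bot)
  }
  out
}

#' Generate a collection of synthetic images
#'
#' Draws `n` image specs from a mixture over generator kinds, with
#' randomized parameters inside documented ranges, and renders them.  The
#' returned `info` tibble records each image's kind and generating
#' parameters — including the ordinal levels (e.g. spectral slope) needed
#' for feature-recovery tests.
#'
#' The default mixture spans a wide range of every feature: ramps and
#' tilings sit at the high end of self-similarity, ramp mosaics at the low
#' end, and spectral noise with varying slope covers the complexity range.
#'
#' @param n number of images.
#' @param seed integer seed; fully determines the collection.
#' @param mix named numeric vector of kind weights (need not sum to 1).
#' @return List with `images` (list of [raster_image()]) and `info`
#'   (tibble `image_id`, `kind`, `orientation`, `frequency`, `slope`,
#'   `saturation`, `width`, `height`).
#' @export
generate_image_collection <- function(n, seed = 1L,
                                      mix = c(grating = 0.15, ramp = 0.1,
                                              ramp_mosaic = 0.15,
                                              block_mosaic = 0.1,
                                              periodic_tiling = 0.15,
                                              spectral_noise = 0.25,
                                              color_field = 0.1)) {
  stopifnot(n >= 1, all(names(mix) != ""))
  info <- withr::with_seed(seed, {
    kinds <- sample(names(mix), n, replace = TRUE, prob = mix)
    tibble::tibble(
      image_id = sprintf("syn%04d", seq_len(n)),
      kind = kinds,
      orientation = round(runif(n, 0, 180), 1),
      frequency = sample(4:16, n, replace = TRUE),
      slope = round(runif(n, 0.5, 3), 2),
      saturation = round(runif(n, 0.2, 0.9), 2),
      width = sample(280:360, n, replace = TRUE),
      height = sample(280:360, n, replace = TRUE),
      seed = seed + seq_len(n)
    )
  })
  images <- purrr::pmap(info, function(image_id, kind, orientation, frequency,
                                       slope, saturation, width, height, seed) {
    generate_image(
      kind = kind, width = width, height = height, seed = seed, id = image_id,
      orientation = orientation, frequency = frequency, slope = slope,
      saturation = saturation
    )
  })
  list(images = images, info = info)
}
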