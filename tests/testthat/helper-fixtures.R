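# small in-code image fixtures

gray_image <- function(value, h = 24, w = 24, id = "gray") {
  raster_image(array(value, c(h, w, 3)), id = id)
}

# vertical luminance step: left half `lo`, right half `hi`
step_image <- function(h = 16, w = 16, lo = 40, hi = 210, id = "step") {
  m <- matrix(lo, h, w)
  m[, (w %/% 2 + 1):w] <- hi
  raster_image(array(rep(m, 3), c(h, w, 3)), id = id)
}

# solid color image
solid_image <- function(rgb, h = 16, w = 16, id = "solid") {
  raster_image(array(rep(rgb, each = h * w), c(h, w, 3)), id = id)
}

# synthetic gradient field with given orientation/magnitude matrices
fake_field <- function(magnitude, orientation_deg, id = "fake") {
  structure(
    list(magnitude = magnitude, orientation_deg = orientation_deg, id = id),
    class = "gradient_field"
  )
}

# pyramid whose level-3 histograms are all one-hot in bin `bin`
one_hot_pyramid <- function(bin = 1) {
  hist1 <- function(b) {
    bins <- numeric(16)
    bins[b] <- 1
    structure(list(bins = bins, normalized = TRUE, degenerate = FALSE),
              class = "orientation_histogram")
  }
  structure(
    list(levels = list(
      list(hist1(bin)),
      replicate(4, hist1(bin), simplify = FALSE),
      replicate(16, hist1(bin), simplify = FALSE),
      replicate(64, hist1(bin), simplify = FALSE)
    ), id = "onehot"),
    class = "hog_pyramid"
  )
}

uniform_hist <- function() {
  structure(list(bins = rep(1 / 16, 16), normalized = TRUE, degenerate = FALSE),
            class = "orientation_histogram")
}

# complete baseline ratings tibble for small synthetic setups
tiny_ratings <- function(n_p = 6, n_i = 8, seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(
      participant_id = sprintf("p%02d", seq_len(n_p)),
      image_id = sprintf("i%02d", seq_len(n_i)),
      stringsAsFactors = FALSE
    )
    grid$phase <- "baseline"
    grid$rating <- sample(1:4, nrow(grid), replace = TRUE)
    load_ratings(grid)
  })
}
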