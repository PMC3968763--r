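#' Orientation histograms, the PHOG pyramid, and its summary statistics
#'
#' @description
#' A HOG feature is the histogram of gradient magnitudes binned by gradient
#' orientation into 16 equal bins covering the full 360 degrees.  The PHOG
#' pyramid stacks HOG features over a recursive 4-way spatial subdivision of
#' the image (levels 0-3, i.e. 1, 4, 16, and 64 rectangles).  From the
#' pyramid the package derives self-similarity (histogram-intersection
#' agreement between the finest-level parts and the whole), complexity (mean
#' gradient magnitude), anisotropy (dispersion of binned gradient strength
#' across orientations), and the Birkhoff-like order/complexity ratio.
#'
#' @name phog
NULL

N_BINS <- 16L
BIN_WIDTH <- 360 / 16

orientation_histogram <- function(bins, normalized, degenerate = FALSE) {
  structure(
    list(bins = as.numeric(bins), normalized = normalized, degenerate = degenerate),
    class = "orientation_histogram"
  )
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf(
    "<orientation_histogram: %s%s>\n",
    if (x$normalized) "normalized" else "raw",
    if (x$degenerate) ", degenerate (zero gradient mass)" else ""
  ))
  print(round(x$bins, 4))
  invisible(x)
}

bin_index <- function(orientation_deg) {
  pmin(as.integer(orientation_deg %/% BIN_WIDTH), N_BINS - 1L) + 1L
}

#' Histogram of oriented gradients over a region
#'
#' Accumulates gradient magnitudes into 16 orientation bins
#' (bin *b* covers `[(b-1) * 22.5, b * 22.5)` degrees) over a rectangular
#' region, then L1-normalizes so the bins sum to 1.  Zero-magnitude pixels
#' contribute no mass.  A region with zero total gradient mass cannot be
#' normalized and is returned with `degenerate = TRUE` and all-zero bins.
#'
#' @param field a `gradient_field` from [compute_gradient_field()].
#' @param rows,cols integer index vectors delimiting the region; `NULL`
#'   (default) means the whole field.
#' @return An `orientation_histogram` (list with `bins`, `normalized`,
#'   `degenerate`).
#' @export
compute_hog <- function(field, rows = NULL, cols = NULL) {
  stopifnot(inherits(field, "gradient_field"))
  rows <- rows %||% seq_len(nrow(field$magnitude))
  cols <- cols %||% seq_len(ncol(field$magnitude))
  if (length(rows) == 0 || length(cols) == 0) abort("empty region")
  m <- field$magnitude[rows, cols]
  b <- bin_index(field$orientation_deg[rows, cols])
  h <- vapply(
    split(as.numeric(m), factor(b, levels = seq_len(N_BINS))),
    sum, numeric(1)
  )
  h[is.na(h)] <- 0
  total <- sum(h)
  if (total <= 0) {
    return(orientation_histogram(numeric(N_BINS), normalized = FALSE, degenerate = TRUE))
  }
  orientation_histogram(h / total, normalized = TRUE)
}

# level-l breakpoints: integer division, remainder absorbed by the last
# rectangle in each row/column
level_breaks <- function(n_pixels, n_rect) {
  base <- n_pixels %/% n_rect
  starts <- (seq_len(n_rect) - 1L) * base + 1L
  ends <- c(starts[-1L] - 1L, n_pixels)
  list(starts = starts, ends = ends)
}

#' Build the PHOG pyramid of a gradient field
#'
#' The gradient field is computed once globally and pooled per rectangle:
#' level `l` tiles the image into a row-major `2^l x 2^l` grid
#' (levels 0 through 3, so 1, 4, 16, 64 rectangles).  Rectangle bounds come
#' from integer division; remainder pixels are absorbed by the last
#' rectangle of each row/column.
#'
#' @param field a `gradient_field`.
#' @return An object of class `hog_pyramid`: list with `levels` (list of 4
#'   lists of `orientation_histogram`) and the source `id`.
#' @export
#' @examples
#' img <- generate_image("grating", width = 64, height = 64, orientation = 45)
#' pyr <- build_hog_pyramid(compute_gradient_field(img))
#' lengths(pyr$levels)
build_hog_pyramid <- function(field) {
  stopifnot(inherits(field, "gradient_field"))
  h <- nrow(field$magnitude)
  w <- ncol(field$magnitude)
  if (h < 8 || w < 8) {
    abort(sprintf("field is %d x %d; at least 8 x 8 needed for the level-3 partition", h, w))
  }
  m <- as.numeric(field$magnitude)
  b <- bin_index(field$orientation_deg)
  levels <- vector("list", 4L)
  for (lev in 0:3) {
    n <- 2L^lev
    rb <- level_breaks(h, n)
    cb <- level_breaks(w, n)
    # per-pixel rectangle id, row-major over the n x n grid
    row_block <- rep(seq_len(n), times = rb$ends - rb$starts + 1L)
    col_block <- rep(seq_len(n), times = cb$ends - cb$starts + 1L)
    rect <- outer(row_block - 1L, col_block, function(r, cc) r * n + cc)
    key <- (as.integer(rect) - 1L) * N_BINS + as.integer(b)
    sums <- numeric(n * n * N_BINS)
    agg <- rowsum(m, key)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    mat <- matrix(sums, nrow = N_BINS) # one column per rectangle
    levels[[lev + 1L]] <- lapply(seq_len(n * n), function(j) {
      total <- sum(mat[, j])
      if (total <= 0) {
        orientation_histogram(numeric(N_BINS), normalized = FALSE, degenerate = TRUE)
      } else {
        orientation_histogram(mat[, j] / total, normalized = TRUE)
      }
    })
  }
  structure(list(levels = levels, id = field$id), class = "hog_pyramid")
}

#' @export
print.hog_pyramid <- function(x, ...) {
  cat(sprintf(
    "<hog_pyramid '%s': levels 0-3 with %s histograms>\n",
    x$id, paste(lengths(x$levels), collapse = "/")
  ))
  invisible(x)
}

#' Histogram intersection kernel
#'
#' Similarity between two L1-normalized histograms: the sum of elementwise
#' minima.  Equals 1 for identical histograms, 0 for disjoint supports, and
#' is symmetric and bounded in `[0, 1]`.
#'
#' @param h1,h2 `orientation_histogram` objects (normalized) or bare numeric
#'   bin vectors of equal length.
#' @return A real in `[0, 1]`, or `NA` if either histogram is degenerate.
#' @export
#' @examples
#' histogram_intersection(c(.5, .5, 0, 0), c(.25, .25, .25, .25))
histogram_intersection <- function(h1, h2) {
  b1 <- if (inherits(h1, "orientation_histogram")) h1 else orientation_histogram(h1, TRUE)
  b2 <- if (inherits(h2, "orientation_histogram")) h2 else orientation_histogram(h2, TRUE)
  if (b1$degenerate || b2$degenerate) {
    warn("degenerate histogram in intersection; returning NA")
    return(NA_real_)
  }
  stopifnot(length(b1$bins) == length(b2$bins))
  sum(pmin(b1$bins, b2$bins))
}

#' PHOG self-similarity
#'
#' Compares each of the 64 level-3 subimage histograms with the whole-image
#' (level-0) histogram via the histogram intersection kernel and aggregates
#' the 64 intersections into one value in `[0, 1]`.  High values mean the
#' parts of the image are statistically similar to the whole.  Degenerate
#' (zero-gradient) subimages contribute intersection 0; a degenerate level-0
#' histogram (a fully constant image) makes self-similarity undefined and
#' returns `NA` with attribute `degenerate = TRUE`.
#'
#' @param pyr a `hog_pyramid`.
#' @param aggregate `"median"` (default, robust to degenerate blocks) or
#'   `"mean"`.
#' @return Self-similarity in `[0, 1]`, or flagged `NA`.
#' @export
self_similarity <- function(pyr, aggregate = c("median", "mean")) {
  stopifnot(inherits(pyr, "hog_pyramid"))
  aggregate <- match.arg(aggregate)
  h0 <- pyr$levels[[1]][[1]]
  if (h0$degenerate) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  vals <- vapply(pyr$levels[[4]], function(h) {
    if (h$degenerate) 0 else sum(pmin(h$bins, h0$bins))
  }, numeric(1))
  if (aggregate == "median") median(vals) else mean(vals)
}

#' Image complexity
#'
#' The mean gradient magnitude over all pixels of the field.  The underlying
#' quantity is the total strength of all oriented gradients; because every
#' image is analysed at one fixed pixel budget, the mean differs from the
#' total only by a constant factor, and the mean is explicitly
#' size-invariant.  Units are Lab pixel-value units per pixel step.
#'
#' @param field a `gradient_field`.
#' @return Non-negative real; 0 iff the field is identically zero.
#' @export
complexity <- function(field) {
  stopifnot(inherits(field, "gradient_field"))
  mean(field$magnitude)
}

#' Orientation anisotropy
#'
#' Dispersion of binned gradient strength across orientations at pyramid
#' level 3.  With `pooling = "pooled"` (default) the 16 normalized bin values
#' of every non-degenerate level-3 histogram are pooled into one vector
#' (up to 16 x 64 values) and their standard deviation is returned; with
#' `"per_block"` the per-histogram standard deviations are averaged.  A value
#' near 0 indicates orientations are uniformly represented; identical
#' one-hot histograms give the pooled maximum `sqrt(15)/16`.
#'
#' @param pyr a `hog_pyramid`.
#' @param pooling `"pooled"` or `"per_block"`.
#' @return Non-negative real, or flagged `NA` if every level-3 histogram is
#'   degenerate.
#' @export
anisotropy <- function(pyr, pooling = c("pooled", "per_block")) {
  stopifnot(inherits(pyr, "hog_pyramid"))
  pooling <- match.arg(pooling)
  hs <- Filter(function(h) !h$degenerate, pyr$levels[[4]])
  if (length(hs) == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (pooling == "pooled") {
    sd(unlist(lapply(hs, `[[`, "bins")))
  } else {
    mean(vapply(hs, function(h) sd(h$bins), numeric(1)))
  }
}

#' Birkhoff-like measure
#'
#' The quotient of self-similarity ("order") over complexity, after
#' Birkhoff's aesthetic-measure idea.
#'
#' @param ss self-similarity value.
#' @param comp complexity value.
#' @return `ss / comp`, or flagged `NA` when `comp` is 0 or `ss` undefined.
#' @export
birkhoff_measure <- function(ss, comp) {
  if (is.na(ss) || is.na(comp) || comp <= 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  as.numeric(ss) / as.numeric(comp)
}
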