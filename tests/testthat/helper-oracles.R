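# Brute-force, double-loop oracles: deliberately naive reimplementations of
# the gradient / histogram / pyramid chain (and small statistics), used to
# cross-check the vectorized implementation on tiny images.

oracle_lab <- function(img) {
  h <- img$height_px
  w <- img$width_px
  out <- list(
    L = matrix(0, h, w), a = matrix(0, h, w), b = matrix(0, h, w)
  )
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      lab <- grDevices::convertColor(
        matrix(as.numeric(img$pixels[i, j, ]) / 255, 1), "sRGB", "Lab"
      )
      out$L[i, j] <- lab[1]
      out$a[i, j] <- lab[2]
      out$b[i, j] <- lab[3]
    }
  }
  out
}

oracle_gradient_field <- function(img) {
  lab <- oracle_lab(img)
  h <- img$height_px
  w <- img$width_px
  mag <- matrix(0, h, w)
  ori <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      best <- -1
      bx <- 0
      by <- 0
      for (ch in c("L", "a", "b")) {
        x <- lab[[ch]]
        gx <- x[i, min(j + 1, w)] - x[i, max(j - 1, 1)]
        gy <- x[min(i + 1, h), j] - x[max(i - 1, 1), j]
        m <- sqrt(gx^2 + gy^2)
        if (m > best) {
          best <- m
          bx <- gx
          by <- gy
        }
      }
      mag[i, j] <- best
      ori[i, j] <- if (best == 0) 0 else (atan2(by, bx) * 180 / pi) %% 360
    }
  }
  structure(list(magnitude = mag, orientation_deg = ori, id = img$id),
            class = "gradient_field")
}

oracle_hog <- function(field, rows, cols) {
  bins <- numeric(16)
  for (i in rows) {
    for (j in cols) {
      m <- field$magnitude[i, j]
      if (m > 0) {
        b <- min(floor(field$orientation_deg[i, j] / 22.5), 15) + 1
        bins[b] <- bins[b] + m
      }
    }
  }
  if (sum(bins) > 0) bins / sum(bins) else bins
}

oracle_rect_bounds <- function(n_pixels, n_rect) {
  base <- n_pixels %/% n_rect
  lapply(seq_len(n_rect), function(r) {
    lo <- (r - 1) * base + 1
    hi <- if (r == n_rect) n_pixels else r * base
    lo:hi
  })
}

oracle_self_similarity <- function(field) {
  h <- nrow(field$magnitude)
  w <- ncol(field$magnitude)
  global <- oracle_hog(field, 1:h, 1:w)
  if (sum(global) == 0) return(NA_real_)
  rb <- oracle_rect_bounds(h, 8)
  cb <- oracle_rect_bounds(w, 8)
  vals <- c()
  for (r in 1:8) {
    for (cc in 1:8) {
      sub <- oracle_hog(field, rb[[r]], cb[[cc]])
      vals <- c(vals, if (sum(sub) == 0) 0 else sum(pmin(sub, global)))
    }
  }
  median(vals)
}

# Spearman via explicit midranks + textbook Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# paired t from the textbook formula
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  list(t = mean(d) / (sd(d) / sqrt(n)), df = n - 1)
}

# Adjusted Rand Index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
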