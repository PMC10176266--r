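# Independent brute-force oracles used across the suite.

# 8-connected component labeling by explicit flood fill, components numbered
# in raster-scan (row-major) order of their first pixel.
flood_fill_labels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      stack <- list(c(i, j)); lab[i, j] <- k
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          a <- p[1] + di; b <- p[2] + dj
          if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
              mask[a, b] && lab[a, b] == 0L) {
            lab[a, b] <- k
            stack[[length(stack) + 1]] <- c(a, b)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive per-pixel distance scan implementing the nearest-stain rule.
# Scans every image pixel in row-major order; keeps the strictly closest
# stain pixel (so ties resolve to the smallest (row, col)).
nearest_stain_scan_oracle <- function(nuclei, stain, fallback_value,
                                      rule = "other_nucleus") {
  tab <- nuclei$table
  lab <- nuclei$labels
  slab <- stain$labels
  nr <- nrow(lab); nc <- ncol(lab)
  out <- data.frame(cell_id = tab$label, raw = NA_real_, fallback = NA,
                    d_stain = NA_real_, d_other = NA_real_)
  for (k in seq_len(nrow(tab))) {
    r0 <- tab$centroid_row[k]; c0 <- tab$centroid_col[k]
    best_d2 <- Inf; best_comp <- NA_integer_
    other_d2 <- Inf
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      d2 <- (a - r0)^2 + (b - c0)^2
      if (slab[a, b] > 0 && d2 < best_d2) {
        best_d2 <- d2; best_comp <- slab[a, b]
      }
      own <- lab[a, b]
      if (own > 0 && (rule == "any_blue" || own != tab$label[k]) && d2 < other_d2)
        other_d2 <- d2
    }
    ds <- sqrt(best_d2); do <- sqrt(other_d2)
    fb <- !is.finite(ds) || ds > do
    out$raw[k] <- if (fb) fallback_value else stain$comp_mean[best_comp]
    out$fallback[k] <- fb
    out$d_stain[k] <- ds
    out$d_other[k] <- do
  }
  out
}

# O(n^2) pairwise neighbor classification.
brute_force_spatial <- function(rows, cols, radius_px) {
  n <- length(rows)
  cls <- character(n)
  for (i in seq_len(n)) {
    nb <- FALSE
    for (j in seq_len(n)) {
      if (i != j &&
          sqrt((rows[i] - rows[j])^2 + (cols[i] - cols[j])^2) <= radius_px) {
        nb <- TRUE; break
      }
    }
    cls[i] <- if (nb) "colony" else "single"
  }
  cls
}

# Pairwise-comparison Mann-Whitney U oracle: wins plus half-ties.
pairwise_u_oracle <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Match detected cells to ground-truth rows by nearest true centroid.
match_truth <- function(cells, truth) {
  vapply(seq_len(nrow(cells)), function(i) {
    which.min((truth$true_row - cells$centroid_row[i])^2 +
              (truth$true_col - cells$centroid_col[i])^2)
  }, integer(1))
}

# A small random field for oracle-equivalence runs: a few disk nuclei and a
# few constant-value stain blobs on a blank background.
random_oracle_field <- function(seed, size = 48) {
  set.seed(seed)
  blue <- matrix(0, size, size)
  green <- matrix(0, size, size)
  n_nuc <- sample(2:4, 1)
  for (i in seq_len(n_nuc)) {
    r0 <- runif(1, 5, size - 5); c0 <- runif(1, 5, size - 5)
    px <- trophoquant:::.disk_pixels(size, size, r0, c0, 3)
    blue[px] <- 200
  }
  n_blob <- sample(0:3, 1)
  for (i in seq_len(n_blob)) {
    r0 <- runif(1, 4, size - 4); c0 <- runif(1, 4, size - 4)
    px <- trophoquant:::.disk_pixels(size, size, r0, c0, 2)
    green[px] <- runif(1, 50, 250)
  }
  f <- field(list(blue = blue, green = green), um_per_px = 0.62,
             field_id = sprintf("oracle%d", seed))
  nuc <- label_nuclei(clean_mask(blue > 100, min_area_px = 5, fill_holes = FALSE))
  st <- build_stain_mask(f, "green",
                         segmentation_config(method = "global", threshold = 10,
                                             min_area_px = 1, fill_holes = FALSE))
  list(field = f, nuclei = nuc, stain = st)
}
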