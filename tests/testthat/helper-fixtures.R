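# Small, fast simulation geometries used across the suite. Per-area physics
# (spot rates per 100 um^2, 12-um tiles) match the full-size defaults; only
# the core extent is scaled down.

tiny_params <- function(...) {
  sim_params(core_diameter_um = 60, ...)
}

small_params <- function(...) {
  sim_params(core_diameter_um = 120, ...)
}

# well-separated homogeneous per-class rates (band-free mode)
separated_params <- function(diameter = 120, ...) {
  sim_params(core_diameter_um = diameter, spot_rate_band_per_class = NULL, ...)
}

# a random connected-ish blob mask: union of a few discs inside an n x n frame
random_blob_mask <- function(n, seed, core_id = "T1") {
  withr::with_seed(seed, {
    m <- matrix(FALSE, n, n)
    k <- sample(1:3, 1)
    cx <- runif(k, n * 0.3, n * 0.7)
    cy <- runif(k, n * 0.3, n * 0.7)
    r <- runif(k, n * 0.1, n * 0.3)
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    for (i in seq_len(k)) {
      m <- m | ((rows - cx[i])^2 + (cols - cy[i])^2 <= r[i]^2)
    }
    invasive_mask(m, core_id)
  })
}

# independent, naive tile-grid enumeration: loops over every candidate anchor
# and every pixel of every tile
tile_grid_oracle <- function(mask, t, incl) {
  m <- mask$mask
  rr <- range(which(apply(m, 1, any)))
  cc <- range(which(apply(m, 2, any)))
  out <- NULL
  for (r in seq(rr[1], rr[2], by = t)) {
    for (c in seq(cc[1], cc[2], by = t)) {
      cnt <- 0L
      for (i in r:(r + t - 1L)) {
        for (j in c:(c + t - 1L)) {
          if (i <= nrow(m) && j <= ncol(m) && m[i, j]) cnt <- cnt + 1L
        }
      }
      if (cnt / t^2 >= incl) out <- rbind(out, c(r, c))
    }
  }
  out
}

# closed-form two-sample test oracles (textbook formulas)
student_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

welch_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  va <- var(a) / n1; vb <- var(b) / n2
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n1 - 1) + vb^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

f_oracle <- function(a, b) {
  va <- var(a); vb <- var(b)
  if (va >= vb) {
    f <- va / vb; d1 <- length(a) - 1; d2 <- length(b) - 1
  } else {
    f <- vb / va; d1 <- length(b) - 1; d2 <- length(a) - 1
  }
  list(f = f, p = 2 * min(pf(f, d1, d2), 1 - pf(f, d1, d2)))
}
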