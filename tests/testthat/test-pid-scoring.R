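test_that("a full square mask tiles exactly", {
  m <- invasive_mask(matrix(TRUE, 24, 24), "A1")
  g <- build_tile_grid(m, pixel_size_um = 1, tile_size_um = 12)
  expect_equal(g$tile_size_px, 12L)
  expect_equal(nrow(g$origins), 4)
  g1 <- build_tile_grid(m, pixel_size_um = 1, tile_size_um = 24)
  expect_equal(nrow(g1$origins), 1)
})

test_that("tile grids match exhaustive enumeration on random blob masks", {
  for (s in 1:30) {
    m <- random_blob_mask(48, seed = 100 + s)
    g <- build_tile_grid(m, pixel_size_um = 1, tile_size_um = 7,
                         inclusion_fraction = 0.5)
    oracle <- tile_grid_oracle(m, 7L, 0.5)
    expect_equal(nrow(g$origins), NROW(oracle), info = paste("mask seed", s))
    if (NROW(oracle) > 0) {
      expect_equal(unname(g$origins[order(g$origins[, 1], g$origins[, 2]), ,
                                    drop = FALSE]),
                   unname(oracle[order(oracle[, 1], oracle[, 2]), ,
                                 drop = FALSE]))
    }
  }
})

test_that("an empty mask is an unanalyzable-core error", {
  m <- invasive_mask(matrix(FALSE, 10, 10), "H15")
  expect_error(build_tile_grid(m, 1), "no invasive region")
})

test_that("tile integrals are masked sums in grid order", {
  m <- invasive_mask(matrix(TRUE, 24, 24), "A1")
  img <- core_image(matrix(1, 24, 24), 1, "A1")
  g <- build_tile_grid(m, 1, 12)
  v <- integrate_tiles(img, m, g)
  expect_equal(v$values, rep(144, 4)) # area x intensity
  expect_equal(v$n_tiles, 4)

  z <- core_image(matrix(0, 24, 24), 1, "A1")
  expect_equal(integrate_tiles(z, m, g)$values, rep(0, 4))

  # conservation against a direct masked-sum oracle on a simulated core
  s <- simulate_core(tiny_params(), "2+", seed = 13)
  g2 <- build_tile_grid(s$mask, 0.46)
  v2 <- integrate_tiles(s$image, s$mask, g2)
  total_masked <- sum(s$image$intensities[s$mask$mask])
  expect_lte(sum(v2$values), total_masked + 1e-9)
  # each tile independently recomputed pixel by pixel
  t <- g2$tile_size_px
  for (i in seq_len(v2$n_tiles)) {
    r <- g2$origins[i, 1]; c <- g2$origins[i, 2]
    acc <- 0
    for (rr in r:min(r + t - 1, nrow(s$mask$mask))) {
      for (cc in c:min(c + t - 1, ncol(s$mask$mask))) {
        if (s$mask$mask[rr, cc]) acc <- acc + s$image$intensities[rr, cc]
      }
    }
    expect_equal(v2$values[i], acc)
  }
})

test_that("shape mismatch between image and mask is a pairing error", {
  m <- invasive_mask(matrix(TRUE, 10, 10), "A1")
  img <- core_image(matrix(1, 12, 12), 1, "A1")
  g <- build_tile_grid(m, 1, 5)
  expect_error(integrate_tiles(img, m, g), "shape mismatch")
})

test_that("top-fraction mean agrees with a full-sort oracle", {
  expect_equal(top_fraction_mean(5, 0.10), 5) # k floors at 1
  expect_equal(top_fraction_mean(1:10, 0.10), 10)

  v <- withr::with_seed(77, runif(25))
  expect_equal(top_fraction_mean(v, 0.10),
               mean(sort(v, decreasing = TRUE)[1:3])) # k = ceiling(2.5)

  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(1:100, 1)
      x <- rnorm(n) * 10
      frac <- runif(1, 0.01, 1)
      k <- max(1, ceiling(frac * n))
      expect_equal(top_fraction_mean(x, frac),
                   mean(sort(x, decreasing = TRUE)[1:k]))
    }
  })
})

test_that("top-fraction mean is the plain mean at fraction 1 and non-increasing in fraction", {
  x <- withr::with_seed(8, rnorm(50))
  expect_equal(top_fraction_mean(x, 1), mean(x))
  fr <- c(0.05, 0.1, 0.25, 0.5, 0.75, 1)
  vals <- vapply(fr, function(f) top_fraction_mean(x, f), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(top_fraction_mean(numeric(0)), "empty")
  expect_error(top_fraction_mean(1:3, 0), "fraction")
  expect_error(top_fraction_mean(1:3, 1.2), "fraction")
})

test_that("a uniform field scores area x intensity regardless of the top fraction", {
  m <- invasive_mask(matrix(TRUE, 36, 36), "A1")
  img <- core_image(matrix(2.5, 36, 36), 1, "A1")
  s <- score_core(img, m, pixel_size_um = 1)
  expect_equal(s$pid_value, 144 * 2.5)
  expect_equal(s$n_tiles, 9)
  z <- core_image(matrix(0, 36, 36), 1, "A1")
  expect_equal(score_core(z, m, pixel_size_um = 1)$pid_value, 0)
})

test_that("PID value is homogeneous of degree 1 in intensity", {
  s <- simulate_core(tiny_params(), "1+", seed = 31)
  base <- score_core(s$image, s$mask)$pid_value
  for (alpha in c(0.5, 3, 17.2)) {
    scaled <- core_image(s$image$intensities * alpha, 0.46, "A1")
    expect_equal(score_core(scaled, s$mask)$pid_value, alpha * base)
  }
})

test_that("PID value is invariant under whole-tile translations", {
  s <- simulate_core(tiny_params(), "2+", seed = 41)
  g <- build_tile_grid(s$mask, 0.46)
  t <- g$tile_size_px
  n <- nrow(s$image$intensities)
  pad <- 2L * t
  big_i <- matrix(0, n + pad, n + pad)
  big_m <- matrix(FALSE, n + pad, n + pad)
  big_i[(t + 1):(t + n), (t + 1):(t + n)] <- s$image$intensities
  big_m[(t + 1):(t + n), (t + 1):(t + n)] <- s$mask$mask
  shifted <- score_core(core_image(big_i, 0.46, "A1"),
                        invasive_mask(big_m, "A1"))
  expect_equal(shifted$pid_value, score_core(s$image, s$mask)$pid_value)
  expect_equal(shifted$n_tiles, score_core(s$image, s$mask)$n_tiles)
})

test_that("simulated high expressers outscore null cores", {
  p <- separated_params(diameter = 60)
  hi <- vapply(1:8, function(s) {
    sim <- simulate_core(p, "3+", seed = 600 + s)
    score_core(sim$image, sim$mask)$pid_value
  }, numeric(1))
  lo <- vapply(1:8, function(s) {
    sim <- simulate_core(p, "0", seed = 700 + s)
    score_core(sim$image, sim$mask)$pid_value
  }, numeric(1))
  expect_gt(mean(hi), mean(lo))
  expect_gt(min(hi), max(lo)) # well-separated rates: disjoint supports
})
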