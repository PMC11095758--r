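test_that("identical parameters and seed give bit-identical cores", {
  p <- tiny_params()
  a <- simulate_core(p, "2+", seed = 11, core_id = "A1")
  b <- simulate_core(p, "2+", seed = 11, core_id = "A1")
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$mask$mask, b$mask$mask)
  expect_identical(a$truth, b$truth)
  d <- simulate_core(p, "2+", seed = 12, core_id = "A1")
  expect_false(identical(a$image$intensities, d$image$intensities))
})

test_that("zero spot rate and zero background give an all-zero image and PID value 0", {
  p <- tiny_params(spot_rate_per_class = c("0" = 0, "1+" = 5, "2+" = 10, "3+" = 20),
                   spot_rate_band_per_class = NULL,
                   background_mean = 0, background_sd = 0)
  s <- simulate_core(p, "0", seed = 3)
  expect_true(all(s$image$intensities == 0))
  expect_identical(s$truth$n_spots_drawn, 0L)
  expect_equal(score_core(s$image, s$mask)$pid_value, 0)
})

test_that("invalid geometry parameters are rejected", {
  expect_error(sim_params(pixel_size_um = 0), "pixel_size_um")
  expect_error(sim_params(core_diameter_um = -5), "core_diameter_um")
  expect_error(sim_params(mask_coverage = 0), "mask_coverage")
  expect_error(sim_params(spot_rate_per_class = c("0" = 5, "1+" = 1, "2+" = 10, "3+" = 20),
                          spot_rate_band_per_class = NULL),
               "non-decreasing")
})

test_that("rendered spot mass matches the analytic Gaussian integral", {
  # sigma = 2 px, fixed amplitude, no background; per-spot rendered mass
  # should equal amp * 2 * pi * sigma^2 up to Monte-Carlo error and the
  # documented 5-sigma truncation (< 4e-6 relative)
  p <- sim_params(pixel_size_um = 1, core_diameter_um = 100,
                  mask_coverage = 0.5, psf_sigma_um = 2,
                  spot_amplitude_mean = 100, spot_amplitude_sd = 0,
                  background_mean = 0, background_sd = 0,
                  spot_rate_per_class = c("0" = 0, "1+" = 0.5, "2+" = 1.0,
                                          "3+" = 1.27),
                  spot_rate_band_per_class = NULL)
  per_spot <- vapply(1:120, function(s) {
    sim <- simulate_core(p, "3+", seed = 1000 + s)
    if (sim$truth$n_spots_drawn == 0) return(NA_real_)
    sum(sim$image$intensities) / sim$truth$n_spots_drawn
  }, numeric(1))
  per_spot <- per_spot[!is.na(per_spot)]
  analytic <- 100 * 2 * pi * 2^2
  se <- sd(per_spot) / sqrt(length(per_spot))
  expect_lt(abs(mean(per_spot) - analytic), 3 * se + 1e-4 * analytic)
})

test_that("background adds exactly on top of spots (conservation)", {
  p_bg <- tiny_params(background_mean = 5, background_sd = 0)
  p_no <- tiny_params(background_mean = 0, background_sd = 0)
  a <- simulate_core(p_bg, "1+", seed = 21)
  b <- simulate_core(p_no, "1+", seed = 21)
  diffs <- a$image$intensities - b$image$intensities
  expect_equal(max(abs(diffs - 5)), 0, tolerance = 1e-12)
})

test_that("mean PID value is non-decreasing across classes with noise-free background", {
  p <- separated_params(diameter = 60, background_mean = 0, background_sd = 0)
  mean_pid <- vapply(dab_levels(), function(k) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_core(p, k, seed = 5000 + s * 7)
      score_core(sim$image, sim$mask)$pid_value
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_pid) >= 0))
})

test_that("cohort design lays out duplicate-core cases with unique IDs", {
  d <- cohort_design(c("0" = 2), seed = 1)
  expect_equal(nrow(d), 2)
  expect_true(all(d$true_class == "0"))
  expect_true(all(d$exclusion_reason == "none"))

  d <- cohort_design(tma208_class_counts(), n_negative_controls = 8,
                     exclusion_plan = tma208_exclusion_plan(), seed = 1)
  expect_equal(nrow(d), 216)
  expect_false(anyDuplicated(d$core_id) > 0)
  tissue <- d[!d$is_negative_control, ]
  expect_equal(sum(table(tissue$case_id) == 2), 104) # 104 cases x 2 cores
  expect_equal(sum(d$exclusion_reason != "none"), 38)
  expect_equal(as.vector(table(tissue$true_class)[dab_levels()]),
               as.vector(tma208_class_counts()))
  # duplicate cores share their case's class
  split_cls <- split(tissue$true_class, tissue$case_id)
  expect_true(all(vapply(split_cls, function(x) length(unique(x)) == 1, logical(1))))
})

test_that("exclusion plan naming an absent core fails with the ID in the message", {
  expect_error(
    cohort_design(c("0" = 4), exclusion_plan = list(dcis = "Q9"), seed = 1),
    "Q9"
  )
  expect_error(
    cohort_design(c("0" = 4), exclusion_plan = list(dcis = "A1", peeling = "A1")),
    "more than once"
  )
})

test_that("simulated cohorts are reproducible and negative controls are dimmer", {
  p <- tiny_params()
  a <- simulate_cohort(p, c("0" = 2, "1+" = 2), n_negative_controls = 2, seed = 5)
  b <- simulate_cohort(p, c("0" = 2, "1+" = 2), n_negative_controls = 2, seed = 5)
  expect_identical(lapply(a$cores, function(x) x$image$intensities),
                   lapply(b$cores, function(x) x$image$intensities))
  expect_identical(a$truth, b$truth)
  # controls run at a quarter of the class-0 point rate: fewer spots on average
  nc_ids <- a$truth$core_id[a$truth$is_negative_control]
  expect_equal(length(nc_ids), 2)
  expect_true(startsWith(nc_ids[1], "Z"))
})
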