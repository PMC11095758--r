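test_that("a perfect linear score-value relationship has R-squared 1", {
  rec <- data.frame(dab_consensus = rep(dab_levels(), each = 3))
  rec$pid_value <- 5 + 2 * dab_ordinal(rec$dab_consensus)
  fit <- suppressWarnings(fit_score_regression(rec)) # exact fit warns in summary.lm
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 5)
  expect_equal(fit$n, 12)
})

test_that("permuted labels give R-squared near zero", {
  withr::with_seed(55, {
    rec <- data.frame(
      dab_consensus = sample(dab_levels(), 400, replace = TRUE),
      pid_value = runif(400, 0, 50e3)
    )
  })
  expect_lt(fit_score_regression(rec)$r_squared, 0.02)
})

test_that("degenerate regressions are errors, not zeros", {
  rec <- data.frame(dab_consensus = rep("2+", 5), pid_value = 1:5)
  expect_error(fit_score_regression(rec), "undefined")
  expect_error(fit_score_regression(rec[1:2, ]), "at least 3")
})

test_that("R-squared is invariant under affine rescaling of PID values", {
  withr::with_seed(9, {
    rec <- data.frame(
      dab_consensus = sample(dab_levels(), 60, replace = TRUE),
      pid_value = rnorm(60)
    )
  })
  r0 <- fit_score_regression(rec)$r_squared
  rec$pid_value <- 1e4 * rec$pid_value + 3.7e3
  expect_equal(fit_score_regression(rec)$r_squared, r0)
})

test_that("contingency tables cross-tabulate with row percentages summing to 100", {
  rec <- data.frame(dab_consensus = rep(dab_levels(), times = c(4, 3, 2, 1)))
  rec$pid_score <- rec$dab_consensus
  ct <- contingency(rec)
  expect_equal(unname(diag(ct$table)), c(4, 3, 2, 1))
  expect_equal(sum(ct$table), 10)
  expect_equal(unname(diag(ct$pv_percent)), rep(100, 4))

  withr::with_seed(31, {
    rec2 <- data.frame(dab_consensus = sample(dab_levels(), 120, replace = TRUE),
                       pid_score = sample(dab_levels(), 120, replace = TRUE))
  })
  ct2 <- contingency(rec2)
  # brute-force pair counting
  for (a in dab_levels()) {
    for (b in dab_levels()) {
      expect_equal(unname(ct2$table[a, b]),
                   sum(rec2$dab_consensus == a & rec2$pid_score == b))
    }
  }
  expect_equal(unname(rowSums(ct2$pv_percent)), rep(100, 4))
  expect_equal(ct2$n, 120)
})

test_that("contingency marginals match the class counts reported elsewhere", {
  withr::with_seed(131, {
    rec <- data.frame(dab_consensus = sample(dab_levels(), 80, replace = TRUE),
                      pid_score = sample(dab_levels(), 80, replace = TRUE))
  })
  ct <- contingency(rec)
  expect_equal(unname(rowSums(ct$table)),
               as.vector(table(factor(rec$dab_consensus, dab_levels()))))
  expect_equal(unname(colSums(ct$table)),
               as.vector(table(factor(rec$pid_score, dab_levels()))))
})

test_that("two-sample comparisons match closed-form oracles to 1e-10", {
  withr::with_seed(101, {
    a <- rnorm(24, 10, 2)
    b <- rnorm(30, 12, 2)
  })
  cmp <- compare_groups(a, b)
  fo <- f_oracle(a, b)
  expect_equal(cmp$f_statistic, fo$f, tolerance = 1e-10)
  expect_equal(cmp$f_p, fo$p, tolerance = 1e-10)
  expect_equal(cmp$test_used, "student")
  so <- student_oracle(a, b)
  expect_equal(cmp$t_statistic, so$t, tolerance = 1e-10)
  expect_equal(cmp$t_p, so$p, tolerance = 1e-10)

  # variance ratio ~100 at n = 20 forces the unequal-variance branch
  withr::with_seed(102, {
    a2 <- rnorm(20, 5, 1)
    b2 <- rnorm(20, 6, 10)
  })
  cmp2 <- compare_groups(a2, b2)
  expect_equal(cmp2$test_used, "welch")
  wo <- welch_oracle(a2, b2)
  expect_equal(cmp2$t_statistic, wo$t, tolerance = 1e-10)
  expect_equal(cmp2$t_p, wo$p, tolerance = 1e-10)
})

test_that("the variance gate selects Welch exactly when the F-test rejects", {
  withr::with_seed(103, {
    for (i in 1:40) {
      a <- rnorm(sample(5:30, 1), 0, runif(1, 0.5, 4))
      b <- rnorm(sample(5:30, 1), 1, runif(1, 0.5, 4))
      cmp <- compare_groups(a, b)
      expect_equal(cmp$test_used, if (cmp$f_p >= 0.05) "student" else "welch")
      expect_equal(cmp$significant, cmp$t_p < 0.05)
    }
  })
})

test_that("identical samples compare as t = 0, p = 1", {
  x <- withr::with_seed(7, rnorm(15))
  cmp <- compare_groups(x, x)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$t_p, 1)
  expect_error(compare_groups(1, c(2, 3)), "at least 2")
})

test_that("adjacent-class comparisons cover the three class boundaries", {
  withr::with_seed(41, {
    rec <- data.frame(
      dab_consensus = rep(dab_levels(), each = 10),
      pid_value = c(rnorm(10, 3), rnorm(10, 8), rnorm(10, 20), rnorm(10, 40))
    )
  })
  cmps <- adjacent_class_comparisons(rec)
  expect_named(cmps, c("0_vs_1+", "1+_vs_2+", "2+_vs_3+"))
  expect_true(all(vapply(cmps, function(x) x$significant, logical(1))))
})

test_that("replicate runs reproduce: identical runs correlate perfectly, permuted runs do not", {
  withr::with_seed(61, {
    run <- data.frame(
      core_id = paste0("A", 1:40),
      dab_consensus = sample(dab_levels(), 40, replace = TRUE),
      pid_value = NA_real_
    )
    run$pid_value <- 3e3 + 1e4 * dab_ordinal(run$dab_consensus) + rnorm(40, 0, 500)
  })
  rep1 <- reproducibility(list(run, run))
  expect_equal(rep1$r_squared[[1]], rep1$r_squared[[2]])
  expect_equal(unname(rep1$between_run_correlation), 1)

  # independent small noise on a shared truth: correlation near 1
  noisy <- function(seed) {
    r <- run
    r$pid_value <- r$pid_value + withr::with_seed(seed, rnorm(40, 0, 100))
    r
  }
  rep2 <- reproducibility(list(noisy(1), noisy(2), noisy(3)))
  expect_length(rep2$between_run_correlation, 3)
  expect_true(all(rep2$between_run_correlation > 0.99))

  # permuted values decorrelate
  perm <- run
  perm$pid_value <- withr::with_seed(5, sample(run$pid_value))
  rep3 <- reproducibility(list(run, perm))
  expect_lt(abs(unname(rep3$between_run_correlation)), 0.35)
  expect_error(reproducibility(list(run)), "at least 2")
})
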