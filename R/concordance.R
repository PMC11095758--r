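#' Regression of PID values on ordinal DAB scores
#'
#' Ordinary least squares of `pid_value` on the DAB score encoded 0..3. The
#' linear-on-ordinals form is the minimal reading of a fitted score/value
#' relationship and is recorded in the output so alternatives can be compared.
#'
#' @param records Data frame with `pid_value` and `dab_consensus`; at least 3
#'   usable records spanning at least 2 distinct scores.
#' @return List of class `concordance_report` with `r_squared`, `slope`,
#'   `intercept`, `n` and `model = "ols_on_ordinal"`.
#' @export
fit_score_regression <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("pid_value", "dab_consensus") %in% names(records)))
  ok <- !is.na(records$pid_value) & !is.na(records$dab_consensus)
  y <- records$pid_value[ok]
  x <- dab_ordinal(records$dab_consensus[ok])
  if (length(y) < 3L) stop("need at least 3 records with value and score")
  if (length(unique(x)) < 2L) {
    stop("R^2 undefined: all DAB scores identical")
  }
  fit <- stats::lm(y ~ x)
  structure(
    list(r_squared = summary(fit)$r.squared,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n = length(y), model = "ols_on_ordinal"),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance: R^2 = %.3f, slope = %.4g, intercept = %.4g, n = %d>\n",
              x$r_squared, x$slope, x$intercept, x$n))
  invisible(x)
}

#' DAB x PID contingency table with row percentages
#'
#' Cross-tabulates pathologist DAB categories (rows) against tentative PID
#' categories (columns) over the four classes, with PV% the row-normalized
#' percentages (each row sums to 100 up to rounding; empty rows are `NA`).
#'
#' @param records Data frame with `dab_consensus` and `pid_score`.
#' @return List with `table` (4x4 integer counts), `pv_percent` (4x4 row
#'   percentages) and `n`.
#' @export
contingency <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("dab_consensus", "pid_score") %in% names(records)))
  ok <- !is.na(records$dab_consensus) & !is.na(records$pid_score)
  tab <- table(
    DAB = factor(records$dab_consensus[ok], levels = dab_levels()),
    PID = factor(records$pid_score[ok], levels = dab_levels())
  )
  rs <- rowSums(tab)
  pv <- 100 * sweep(unclass(tab), 1, ifelse(rs == 0, NA, rs), "/")
  list(table = tab, pv_percent = pv, n = sum(tab))
}

#' Variance-test-gated two-sample comparison
#'
#' Two-sided F test on the variance ratio (larger variance in the numerator);
#' if its p-value is at least `alpha` the groups are compared with Student's
#' pooled-variance t test, otherwise with Welch's t test. Both t tests are
#' two-tailed.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param alpha Gate and significance threshold, default 0.05.
#' @return List of class `group_comparison`: `f_statistic`, `f_p`,
#'   `test_used` (`"student"` or `"welch"`), `t_statistic`, `t_p`,
#'   `significant` (`t_p < alpha`) and `p_lt_001` (`t_p < 0.001`).
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    # degenerate: both samples constant; variances equal by definition
    f_statistic <- 1; f_p <- 1
    if (mean(a) == mean(b)) {
      t_statistic <- 0; t_p <- 1
    } else {
      t_statistic <- sign(mean(a) - mean(b)) * Inf; t_p <- 0
    }
    test_used <- "student"
  } else {
    ft <- if (va >= vb) stats::var.test(a, b) else stats::var.test(b, a)
    f_statistic <- unname(ft$statistic)
    f_p <- ft$p.value
    test_used <- if (f_p >= alpha) "student" else "welch"
    tt <- stats::t.test(a, b, var.equal = test_used == "student")
    t_statistic <- unname(tt$statistic)
    t_p <- tt$p.value
  }
  structure(
    list(f_statistic = f_statistic, f_p = f_p, test_used = test_used,
         t_statistic = t_statistic, t_p = t_p,
         significant = t_p < alpha, p_lt_001 = t_p < 0.001,
         alpha = alpha, n_a = length(a), n_b = length(b)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s t: t = %.4g, p = %.3g (F = %.4g, p = %.3g)%s>\n",
              x$test_used, x$t_statistic, x$t_p, x$f_statistic, x$f_p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pairwise comparisons of adjacent DAB classes
#'
#' [compare_groups()] applied to PID values of each adjacent class pair
#' (0 vs 1+, 1+ vs 2+, 2+ vs 3+); pairs with fewer than 2 cores on either
#' side are skipped.
#'
#' @param records Data frame with `pid_value` and `dab_consensus`.
#' @param alpha Significance threshold, default 0.05.
#' @return Named list of `group_comparison` objects (e.g. `"0_vs_1+"`).
#' @export
adjacent_class_comparisons <- function(records, alpha = 0.05) {
  out <- list()
  lv <- dab_levels()
  for (i in 1:3) {
    a <- records$pid_value[records$dab_consensus %in% lv[i]]
    b <- records$pid_value[records$dab_consensus %in% lv[i + 1]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) >= 2L && length(b) >= 2L) {
      out[[paste0(lv[i], "_vs_", lv[i + 1])]] <- compare_groups(a, b, alpha)
    }
  }
  out
}

#' Replicate-run reproducibility
#'
#' For consecutive-section replicate stains of the same cohort: fits the
#' score regression per run and reports the pairwise Pearson correlation of
#' PID values between runs over shared cores.
#'
#' @param runs List (>= 2) of data frames, each with `core_id`, `pid_value`
#'   and `dab_consensus`.
#' @return List with `r_squared` (per-run vector), `per_run`
#'   (`concordance_report` list) and `between_run_correlation` (named vector,
#'   one entry per run pair).
#' @export
reproducibility <- function(runs) {
  if (!is.list(runs) || length(runs) < 2L) stop("need at least 2 runs")
  per_run <- lapply(runs, fit_score_regression)
  r2 <- vapply(per_run, function(r) r$r_squared, numeric(1))
  nm <- names(runs)
  if (is.null(nm)) nm <- paste0("run", seq_along(runs))
  shared <- Reduce(intersect, lapply(runs, function(r) r$core_id))
  if (length(shared) < 3L) stop("runs share fewer than 3 core_ids")
  cors <- c()
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (j <= i) next
      vi <- runs[[i]]$pid_value[match(shared, runs[[i]]$core_id)]
      vj <- runs[[j]]$pid_value[match(shared, runs[[j]]$core_id)]
      cors[paste0(nm[i], "_vs_", nm[j])] <- stats::cor(vi, vj)
    }
  }
  names(r2) <- nm
  list(r_squared = r2, per_run = per_run, between_run_correlation = cors)
}
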