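#' Cut points for tentative PID IHC scoring
#'
#' Three ascending PID-value thresholds for classes 1+, 2+ and 3+. Strict
#' monotonicity `0 < c1 < c2 < c3` is enforced, never silently reordered.
#'
#' @param c1,c2,c3 Thresholds in arbitrary PID-value units.
#' @return An object of class `cut_points`.
#' @export
cut_points <- function(c1, c2, c3) {
  v <- c(c1, c2, c3)
  if (any(!is.finite(v))) stop("cut points must be finite")
  if (!(0 < c1 && c1 < c2 && c2 < c3)) {
    stop(sprintf(
      "cut points must satisfy 0 < c1 < c2 < c3; got c1 = %g, c2 = %g, c3 = %g",
      c1, c2, c3))
  }
  structure(list(c1 = c1, c2 = c2, c3 = c3), class = "cut_points")
}

#' @export
print.cut_points <- function(x, ...) {
  cat(sprintf("<cut_points: 1+ >= %g, 2+ >= %g, 3+ >= %g>\n", x$c1, x$c2, x$c3))
  invisible(x)
}

#' Derive cut points as per-class PID-value minima
#'
#' The tentative PID IHC score is anchored by setting the lowest PID value of
#' each DAB class (1+, 2+, 3+) as that class's cut point, over analyzable,
#' non-control cores with both a PID value and a consensus DAB score.
#'
#' @param records Data frame with `pid_value` and `dab_consensus`, at least
#'   one record in each of classes 1+, 2+ and 3+.
#' @return A [cut_points()] object.
#' @export
derive_cut_points <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("pid_value", "dab_consensus") %in% names(records)))
  ok <- !is.na(records$pid_value) & !is.na(records$dab_consensus)
  rec <- records[ok, , drop = FALSE]
  mins <- vapply(c("1+", "2+", "3+"), function(k) {
    v <- rec$pid_value[rec$dab_consensus == k]
    if (length(v) == 0L) {
      stop("cannot derive cut points: no record with DAB class ", k)
    }
    min(v)
  }, numeric(1))
  tryCatch(
    cut_points(mins[["1+"]], mins[["2+"]], mins[["3+"]]),
    error = function(e) {
      stop(sprintf(
        "per-class minima are not strictly increasing: 1+ = %g, 2+ = %g, 3+ = %g",
        mins[["1+"]], mins[["2+"]], mins[["3+"]]))
    }
  )
}

#' Assign tentative PID IHC scores
#'
#' Lower bounds are closed because the cut points are themselves class
#' minima: `value >= c3` is 3+, `c2 <= value < c3` is 2+, `c1 <= value < c2`
#' is 1+, `value < c1` is 0.
#'
#' @param pid_value Numeric vector of nonnegative PID values.
#' @param cuts A [cut_points()] object.
#' @return Character vector of categories, `NA` preserved.
#' @export
classify_pid <- function(pid_value, cuts) {
  stopifnot(inherits(cuts, "cut_points"))
  if (any(pid_value < 0, na.rm = TRUE)) stop("pid_value must be nonnegative")
  out <- rep(NA_character_, length(pid_value))
  ok <- !is.na(pid_value)
  out[ok] <- ifelse(pid_value[ok] >= cuts$c3, "3+",
             ifelse(pid_value[ok] >= cuts$c2, "2+",
             ifelse(pid_value[ok] >= cuts$c1, "1+", "0")))
  out
}

#' Negative-control PID floor
#'
#' Arithmetic mean PID value over negative-control cores (staining with the
#' primary antibody omitted); sets the detection floor used by
#' [flag_ultra_low()].
#'
#' @param records Data frame; rows with `is_negative_control == TRUE` and a
#'   `pid_value` are used.
#' @return List of class `nc_stats` with `mean_value` and `n`.
#' @export
negative_control_mean <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("pid_value", "is_negative_control") %in% names(records)))
  v <- records$pid_value[records$is_negative_control %in% TRUE]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("no negative-control record with a PID value")
  }
  structure(list(mean_value = mean(v), n = length(v)), class = "nc_stats")
}

#' Flag candidate HER2 ultra-low cores
#'
#' A DAB-0 core whose PID value strictly exceeds the negative-control mean
#' carries detectable signal despite its null visual score and is flagged as
#' candidate "ultra-low". Cores of other DAB classes are never flagged.
#'
#' @param records Classified data frame with `pid_value`, `dab_consensus` and
#'   `pid_score`.
#' @param cuts The [cut_points()] used for classification (validated for
#'   provenance; the flag itself uses only the control floor).
#' @param ncs A [negative_control_mean()] result.
#' @return `records` with a logical `ultra_low_flag` column and attribute
#'   `ultra_low_counts`, the flagged/unflagged counts among DAB-0 cores.
#' @export
flag_ultra_low <- function(records, cuts, ncs) {
  stopifnot(is.data.frame(records), inherits(cuts, "cut_points"),
            inherits(ncs, "nc_stats"))
  if (!"pid_score" %in% names(records)) {
    stop("records must be classified (pid_score column) before flagging")
  }
  is0 <- records$dab_consensus %in% "0"
  records$ultra_low_flag <- is0 & !is.na(records$pid_value) &
    records$pid_value > ncs$mean_value
  attr(records, "ultra_low_counts") <- c(
    flagged = sum(records$ultra_low_flag[is0]),
    unflagged = sum(!records$ultra_low_flag[is0])
  )
  records
}
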