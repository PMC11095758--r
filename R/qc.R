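#' Filter unanalyzable cores and account for every exclusion
#'
#' Partitions the cohort into analyzable cores (exclusion reason `"none"` and
#' not a negative control), excluded cores, and negative controls, preserving
#' input order. Exclusion is annotation-driven: the reasons arrive with the
#' cohort table (pathologists make these calls visually), this stage only
#' tabulates and filters. Percentages are computed over the evaluable (non
#' negative-control) cores.
#'
#' @param records Data frame of core records with `exclusion_reason` set for
#'   every row (`"none"` allowed) and, optionally, `is_negative_control`.
#' @return List with `analyzable` (data frame), `excluded` (data frame),
#'   `negative_controls` (data frame) and `summary`, an `exclusion_summary`
#'   with per-reason counts, `excluded_total`, `excluded_percent` (rounded to
#'   the nearest integer for reporting), and `analyzable`.
#' @export
apply_exclusions <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"exclusion_reason" %in% names(records) ||
      any(is.na(records$exclusion_reason))) {
    stop("every record must carry an exclusion_reason (\"none\" allowed)")
  }
  bad <- !records$exclusion_reason %in% exclusion_reasons()
  if (any(bad)) {
    stop("unknown exclusion_reason: ",
         paste(unique(records$exclusion_reason[bad]), collapse = ", "))
  }
  is_nc <- if ("is_negative_control" %in% names(records)) {
    records$is_negative_control %in% TRUE
  } else {
    rep(FALSE, nrow(records))
  }
  tissue <- records[!is_nc, , drop = FALSE]
  excl <- tissue$exclusion_reason != "none"
  reasons <- setdiff(exclusion_reasons(), "none")
  counts <- vapply(reasons, function(r) sum(tissue$exclusion_reason == r),
                   integer(1))
  n_in <- nrow(tissue)
  summary <- structure(
    list(counts = counts,
         excluded_total = sum(excl),
         excluded_percent = round(100 * sum(excl) / n_in),
         analyzable = sum(!excl),
         n_input = n_in,
         n_negative_controls = sum(is_nc)),
    class = "exclusion_summary"
  )
  list(analyzable = tissue[!excl, , drop = FALSE],
       excluded = tissue[excl, , drop = FALSE],
       negative_controls = records[is_nc, , drop = FALSE],
       summary = summary)
}

#' @export
print.exclusion_summary <- function(x, ...) {
  cat(sprintf("Of %d cores, %d (%d%%) excluded; %d analyzable",
              x$n_input, x$excluded_total, x$excluded_percent, x$analyzable))
  if (x$n_negative_controls > 0) {
    cat(sprintf(" (+%d negative controls)", x$n_negative_controls))
  }
  cat("\n")
  for (r in names(x$counts)) {
    if (x$counts[[r]] > 0) cat(sprintf("  %-12s %d\n", r, x$counts[[r]]))
  }
  invisible(x)
}
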