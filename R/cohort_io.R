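#' Read a cohort table (CSV or XLSX)
#'
#' The table must carry at least a `core_id` column; unknown columns are
#' preserved. Empty cells become missing values, never zero. DAB score
#' columns are validated against the `"0","1+","2+","3+"` vocabulary.
#'
#' @param path `.csv` or `.xlsx` file (XLSX requires the readxl package).
#' @return Data frame of core records.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("no such cohort table: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA")),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading XLSX requires the readxl package")
      }
      as.data.frame(readxl::read_xlsx(path), stringsAsFactors = FALSE)
    },
    stop("unsupported cohort table format: ", path)
  )
  if (!"core_id" %in% names(df)) {
    stop("cohort table ", path, " lacks a core_id column")
  }
  df$core_id <- as.character(df$core_id)
  if (anyDuplicated(df$core_id)) {
    stop("duplicate core_id in ", path, ": ",
         paste(unique(df$core_id[duplicated(df$core_id)]), collapse = ", "))
  }
  for (col in intersect(c("dab_score_p1", "dab_score_p2", "dab_consensus",
                          "true_class", "pid_score"), names(df))) {
    df[[col]] <- as_dab(df[[col]])
  }
  if ("is_negative_control" %in% names(df)) {
    df$is_negative_control <- as.logical(df$is_negative_control)
  }
  if ("exclusion_reason" %in% names(df)) {
    bad <- !df$exclusion_reason %in% exclusion_reasons()
    if (any(bad)) {
      stop("unknown exclusion_reason: ",
           paste(unique(df$exclusion_reason[bad]), collapse = ", "))
    }
  }
  df
}

# TMA-map (row-major) ordering of core IDs; unparseable IDs sort last,
# alphabetically, so negative-control rows follow the tissue grid.
core_id_order <- function(ids) {
  pos <- tryCatch(parse_core_id(ids), error = function(e) NULL)
  if (is.null(pos)) {
    ok <- grepl("^[A-Z][0-9]+$", ids)
    row <- rep(Inf, length(ids))
    col <- rep(Inf, length(ids))
    if (any(ok)) {
      p <- parse_core_id(ids[ok])
      row[ok] <- p$row
      col[ok] <- p$column
    }
    order(row, col, ids)
  } else {
    order(pos$row, pos$column)
  }
}

#' Write per-core results as CSV
#'
#' Rows are sorted in TMA-map order (row letter, then column); canonical
#' columns come first in a fixed order, any extra columns follow, so repeated
#' runs produce byte-identical files.
#'
#' @param records Data frame with at least `core_id`.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records), "core_id" %in% names(records))
  canonical <- c("core_id", "case_id", "dab_consensus", "exclusion_reason",
                 "n_tiles", "pid_value", "pid_score", "ultra_low_flag")
  first <- intersect(canonical, names(records))
  rest <- setdiff(names(records), canonical)
  df <- records[core_id_order(records$core_id), c(first, rest), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' One 16-bit grayscale TIFF and one PNG mask per core (named
#' `<core_id>.tif` / `<core_id>_mask.png`) plus `truth.csv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$cores)) {
    write_core_image(cohort$cores[[id]]$image, file.path(dir, paste0(id, ".tif")))
    write_mask(cohort$cores[[id]]$mask, file.path(dir, paste0(id, "_mask.png")))
  }
  write_results(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
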