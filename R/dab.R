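#' DAB IHC score categories
#'
#' HER2 IHC categories in ascending expression order, serialized exactly as
#' `"0"`, `"1+"`, `"2+"`, `"3+"`.
#'
#' @return Character vector of the four category labels.
#' @export
dab_levels <- function() c("0", "1+", "2+", "3+")

#' Coerce to a DAB category vector
#'
#' Validates that every non-missing entry is one of `"0"`, `"1+"`, `"2+"`,
#' `"3+"` and returns a character vector (missing values pass through as `NA`).
#'
#' @param x Character vector (or factor) of category labels.
#' @return Character vector of validated labels.
#' @export
as_dab <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% dab_levels())
  if (any(bad)) {
    stop("invalid DAB category: ", paste(unique(x[bad]), collapse = ", "),
         " (expected one of ", paste(dab_levels(), collapse = ", "), ")")
  }
  x
}

#' Ordinal encoding of DAB categories
#'
#' Maps `"0"`, `"1+"`, `"2+"`, `"3+"` to 0, 1, 2, 3 (used as the regressor in
#' score-concordance fits).
#'
#' @param x Character vector of DAB categories.
#' @return Integer vector in 0..3, `NA` preserved.
#' @export
dab_ordinal <- function(x) {
  match(as_dab(x), dab_levels()) - 1L
}

#' Consensus DAB score of two pathologists
#'
#' When the two readings disagree the default policy keeps the higher score;
#' discordant cores are reported via the `"n_discordant"` attribute. If one
#' reading is missing the other is used.
#'
#' @param p1,p2 Character vectors of DAB categories (may contain `NA`).
#' @param policy `"higher"` (default), `"p1"` or `"p2"`.
#' @return Character vector of consensus categories with attribute
#'   `n_discordant`, the number of non-missing disagreeing pairs.
#' @export
consensus_dab <- function(p1, p2, policy = c("higher", "p1", "p2")) {
  policy <- match.arg(policy)
  p1 <- as_dab(p1)
  p2 <- as_dab(p2)
  if (length(p1) != length(p2)) stop("p1 and p2 must have equal length")
  both <- !is.na(p1) & !is.na(p2)
  out <- switch(policy,
    higher = {
      o1 <- dab_ordinal(p1)
      o2 <- dab_ordinal(p2)
      o <- pmax(o1, o2, na.rm = TRUE)
      o[is.na(p1) & is.na(p2)] <- NA_integer_
      ifelse(is.na(o), NA_character_, dab_levels()[o + 1L])
    },
    p1 = ifelse(is.na(p1), p2, p1),
    p2 = ifelse(is.na(p2), p1, p2)
  )
  attr(out, "n_discordant") <- sum(both & p1 != p2)
  out
}
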