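#' Load a packaged printed-table fixture
#'
#' The package ships the four result tables of the source cohort study as
#' transcribed tab-separated fixtures: T1 (baseline clinical variables by
#' albumin group), T3 (time-averaged dietary intake with guideline
#' recommendations), T4 (per-nutrient adjusted Cox hazard ratios) and T5
#' (protective intake ranges with overall and nonlinearity P values). P
#' cells keep their printed dialect (\code{"<0.001"} bounds, \code{"-"}
#' markers).
#'
#' @param id One of \code{"T1"}, \code{"T3"}, \code{"T4"}, \code{"T5"}.
#' @return A data frame of character cells.
#' @export
load_printed_table <- function(id = c("T1", "T3", "T4", "T5")) {
  id <- match.arg(id)
  f <- switch(id,
              T1 = "table1_baseline.tsv",
              T3 = "table3_time_averaged.tsv",
              T4 = "table4_cox.tsv",
              T5 = "table5_ranges.tsv")
  path <- system.file("extdata", f, package = "dietrisk")
  if (!nzchar(path)) stop("load_printed_table: fixture not found: ", f)
  utils::read.delim(path, colClasses = "character", check.names = FALSE)
}

#' Parse a printed P-value cell
#'
#' Printed tables report P values either exactly (\code{"0.56"}), as upper
#' bounds (\code{"<0.001"}) or as absent (\code{"-"}).
#'
#' @param text Character cell(s).
#' @return For a single cell, a list with \code{value} (numeric or
#'   \code{NA}) and \code{is_bound}; vector input gives a data frame.
#' @examples
#' parse_p_cell("<0.001")
#' parse_p_cell("0.56")
#' @export
parse_p_cell <- function(text) {
  one <- function(cell) {
    cell <- trimws(cell)
    if (!nzchar(cell)) stop("parse_p_cell: empty cell")
    if (cell == "-") return(list(value = NA_real_, is_bound = FALSE))
    if (startsWith(cell, "<")) {
      v <- suppressWarnings(as.numeric(sub("^<", "", cell)))
      if (is.na(v)) stop("parse_p_cell: unparseable cell '", cell, "'")
      return(list(value = v, is_bound = TRUE))
    }
    v <- suppressWarnings(as.numeric(cell))
    if (is.na(v)) stop("parse_p_cell: unparseable cell '", cell, "'")
    list(value = v, is_bound = FALSE)
  }
  if (length(text) == 1L) return(one(text))
  res <- lapply(text, one)
  data.frame(value = vapply(res, `[[`, numeric(1), "value"),
             is_bound = vapply(res, `[[`, logical(1), "is_bound"))
}

# significance of one parsed cell at a threshold
.p_signif <- function(parsed, threshold, inclusive) {
  ifelse(is.na(parsed$value), NA,
         ifelse(parsed$is_bound, parsed$value <= threshold,
                if (inclusive) parsed$value <= threshold
                else parsed$value < threshold))
}

#' Count significant rows of a printed P column
#'
#' Counts rows whose printed P value is below the threshold. Upper-bound
#' cells \code{"<x"} count when \code{x <= threshold}; \code{inclusive}
#' controls whether a cell printed exactly at the threshold counts.
#' Absent cells (\code{"-"}) are excluded from numerator and denominator.
#'
#' @param fixture A [load_printed_table()] data frame.
#' @param column P-column name (e.g. \code{"all_p"}).
#' @param threshold Significance threshold (default 0.05).
#' @param inclusive Count cells printed exactly at the threshold?
#' @return List with \code{count}, \code{n} (parseable rows) and
#'   \code{proportion} (whole percent, half-up rounding).
#' @examples
#' \dontrun{count_significant(load_printed_table("T4"), "all_p")}
#' @export
count_significant <- function(fixture, column, threshold = 0.05,
                              inclusive = TRUE) {
  if (!column %in% names(fixture))
    stop("count_significant: no column '", column, "'")
  parsed <- parse_p_cell(fixture[[column]])
  sig <- .p_signif(parsed, threshold, inclusive)
  n <- sum(!is.na(sig))
  count <- sum(sig, na.rm = TRUE)
  list(count = count, n = n, proportion = .round_half_up(100 * count / n))
}

.round_half_up <- function(x) floor(x + 0.5)

#' Count rows jointly significant in P and P-NL
#'
#' A nonlinear association is called significant only when both the overall
#' P and the nonlinearity P clear the threshold; the convention here is the
#' strict comparison (\code{< threshold}).
#'
#' @param fixture The T5 fixture.
#' @param group One of \code{"all"}, \code{"low"}, \code{"medium"},
#'   \code{"high"}.
#' @param threshold Significance threshold (default 0.05).
#' @param strict Use strict \code{<} (default) rather than \code{<=}.
#' @return List with \code{count}, \code{n} and \code{proportion} (whole
#'   percent over all rows).
#' @export
count_joint_significant <- function(fixture, group = "low",
                                    threshold = 0.05, strict = TRUE) {
  pc <- paste0(group, "_p"); nc <- paste0(group, "_pnl")
  if (!all(c(pc, nc) %in% names(fixture)))
    stop("count_joint_significant: group columns not present")
  p <- parse_p_cell(fixture[[pc]])
  pnl <- parse_p_cell(fixture[[nc]])
  s1 <- .p_signif(p, threshold, inclusive = !strict)
  s2 <- .p_signif(pnl, threshold, inclusive = !strict)
  joint <- !is.na(s1) & !is.na(s2) & s1 & s2
  n <- nrow(fixture)
  list(count = sum(joint), n = n,
       proportion = .round_half_up(100 * sum(joint) / n))
}

#' Count nutrients lacking disease-specific intake guidance
#'
#' A nutrient lacks guidance for the dialysis population when its
#' recommended-intake cell is absent (\code{"-"}) or carries only a
#' general-population value (a \code{"Normal"}-prefixed recommendation).
#'
#' @param fixture The T3 fixture (needs a \code{recommended} column).
#' @return List with \code{count} and \code{n}.
#' @export
count_guideline_gaps <- function(fixture) {
  if (!"recommended" %in% names(fixture))
    stop("count_guideline_gaps: fixture lacks a 'recommended' column")
  rec <- trimws(fixture$recommended)
  gap <- rec == "-" | grepl("^normal\\b", rec, ignore.case = TRUE)
  list(count = sum(gap), n = nrow(fixture))
}

#' Pearson correlation matrix of nutrient intakes
#'
#' Pairwise-complete Pearson correlations across the profile's nutrient
#' columns; zero-variance columns are dropped with a warning.
#'
#' @param profiles A \code{diet_profiles} data frame.
#' @param columns Nutrient columns (default the profile's nutrient set).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(profiles, columns = attr(profiles, "nutrient_cols")) {
  if (nrow(profiles) < 3) stop("pearson_matrix: need at least 3 profiles")
  X <- as.matrix(profiles[, columns, drop = FALSE])
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  if (any(v == 0 | is.na(v))) {
    warning(sprintf("pearson_matrix: dropping zero-variance column(s): %s",
                    paste(columns[v == 0 | is.na(v)], collapse = ", ")))
    X <- X[, v > 0 & !is.na(v), drop = FALSE]
  }
  stats::cor(X, use = "pairwise.complete.obs", method = "pearson")
}

#' Recompute every fixture-derived count check
#'
#' The counts and proportions the source tables support: per-group
#' significant nutrients in the Cox table (inclusive threshold), the
#' jointly significant nonlinear associations in the range table (strict
#' threshold), significant baseline clinical variables, and nutrients
#' lacking disease-specific guidance.
#'
#' @return Nested list of check results.
#' @export
check_tables <- function() {
  t1 <- load_printed_table("T1")
  t3 <- load_printed_table("T3")
  t4 <- load_printed_table("T4")
  t5 <- load_printed_table("T5")
  list(
    t4_all = count_significant(t4, "all_p"),
    t4_low = count_significant(t4, "low_p"),
    t4_medium = count_significant(t4, "medium_p"),
    t4_high = count_significant(t4, "high_p"),
    t5_low_joint = count_joint_significant(t5, "low"),
    t5_all_joint = count_joint_significant(t5, "all"),
    t1_significant = count_significant(t1, "p"),
    t3_guideline_gaps = count_guideline_gaps(t3)
  )
}
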