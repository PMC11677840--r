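#' Build a two-way cross-tabulation from weevil records
#'
#' Tabulates record-level destructive-sampling data over two categorical
#' fields (e.g. treatment by infection outcome, or developmental stage by
#' outcome). Level order follows the declared vocabularies
#' ([treatment_levels()], [stage_levels()], [outcome_levels()]); block
#' levels sort alphabetically. Vocabulary levels with no records are kept
#' unless `drop_empty = TRUE` -- downstream chi-square analysis refuses
#' zero margins rather than silently dropping categories.
#'
#' @param records Data.frame of weevil records (columns among `block`,
#'   `treatment`, `stage`, `outcome`, `depth_cm`, `dist_bole_cm`).
#' @param row_factor,col_factor Names of the categorical fields to
#'   tabulate.
#' @param drop_empty Drop rows/columns whose margin is zero.
#' @return An object of class `crosstab`: list with `counts` (integer
#'   matrix), `row_labels`, `col_labels`, `n` (grand total), and the
#'   factor names.
#' @examples
#' rec <- simulate_destructive(simulation_config(seed = 1))
#' build_crosstab(rec, "treatment", "outcome")
#' @export
build_crosstab <- function(records, row_factor, col_factor,
                           drop_empty = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data.frame", call. = FALSE)
  }
  for (f in c(row_factor, col_factor)) {
    if (!f %in% names(records)) {
      stop("records have no field '", f, "'", call. = FALSE)
    }
  }
  rf <- record_factor(records[[row_factor]], row_factor)
  cf <- record_factor(records[[col_factor]], col_factor)
  counts <- unclass(table(rf, cf, dnn = NULL))
  if (drop_empty) {
    counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  }
  new_crosstab(counts, row_factor = row_factor, col_factor = col_factor)
}

#' Construct a cross-tabulation directly from a count matrix
#'
#' For published tables where only the aggregated counts are available
#' (no record-level data), e.g. a treatment-by-infection table as printed.
#'
#' @param counts Non-negative integer matrix with dimnames, or a
#'   data.frame whose first column holds row labels.
#' @param row_factor,col_factor Names describing the two factors.
#' @return A `crosstab` object.
#' @export
as_crosstab <- function(counts, row_factor = "rows", col_factor = "cols") {
  if (is.data.frame(counts)) {
    labs <- as.character(counts[[1]])
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- labs
  }
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  new_crosstab(counts, row_factor = row_factor, col_factor = col_factor)
}

new_crosstab <- function(counts, row_factor, col_factor) {
  structure(
    list(counts = counts,
         row_labels = rownames(counts), col_labels = colnames(counts),
         n = sum(counts), row_factor = row_factor, col_factor = col_factor),
    class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("Cross-tabulation: ", x$row_factor, " x ", x$col_factor,
      " (n = ", x$n, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Chi-square test of independence with standardized residuals
#'
#' Pearson chi-square test on a cross-tabulation, as used to relate
#' infection outcome to treatment and to developmental stage. Reports the
#' uncorrected statistic (no Yates continuity correction), upper-tail
#' p-value, expected counts, per-cell standardized residuals (Z scores,
#' conventionally flagged at |Z| > 1.96) and Cramer's V effect size
#' `sqrt(chi2 / (n * min(r - 1, c - 1)))`.
#'
#' The default residual is the Pearson residual `(O - E) / sqrt(E)`, whose
#' squares sum to the chi-square statistic; the margin-adjusted residual
#' `(O - E) / sqrt(E (1 - p_row)(1 - p_col))` is available via
#' `residual_type = "adjusted"`.
#'
#' @param tab A `crosstab`.
#' @param residual_type `"pearson"` (default) or `"adjusted"`.
#' @return An object of class `chisq_result`: statistic, df, p, expected,
#'   residuals, cramers_v, n, residual_type.
#' @examples
#' t2 <- as_crosstab(read.csv(system.file("extdata",
#'   "scotland2022_treatment_outcome.csv", package = "blisstrial")),
#'   "treatment", "outcome")
#' chi_square_independence(t2)
#' @export
chi_square_independence <- function(tab,
                                    residual_type = c("pearson",
                                                      "adjusted")) {
  stopifnot(inherits(tab, "crosstab"))
  residual_type <- match.arg(residual_type)
  counts <- tab$counts
  if (sum(counts) == 0) stop("table has no observations", call. = FALSE)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) {
    empty <- c(tab$row_labels[rs == 0], tab$col_labels[cs == 0])
    stop("zero margin for level(s): ", paste(empty, collapse = ", "),
         "; drop empty levels explicitly before testing", call. = FALSE)
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("independence test needs at least a 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  stat <- unname(ct$statistic)
  df <- unname(ct$parameter)
  resid <- switch(residual_type,
                  pearson = ct$residuals,
                  adjusted = ct$stdres)
  v <- sqrt(stat / (tab$n * min(nrow(counts) - 1, ncol(counts) - 1)))
  structure(
    list(statistic = stat, df = df,
         p = stats::pchisq(stat, df, lower.tail = FALSE),
         expected = ct$expected, residuals = resid, cramers_v = v,
         n = tab$n, residual_type = residual_type,
         row_factor = tab$row_factor, col_factor = tab$col_factor),
    class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat("Chi-square independence test: ", x$row_factor, " x ", x$col_factor,
      "\n", sep = "")
  cat("  Chi2 = ", format_round(x$statistic, 2), ", df = ", x$df,
      ", p ", if (x$p < 0.001) "< 0.001" else paste("=", format_round(x$p, 3)),
      "\n", sep = "")
  cat("  Cramer's V = ", format_round(x$cramers_v, 3), " (n = ", x$n, ")\n",
      sep = "")
  cat("Standardized residuals (", x$residual_type, "):\n", sep = "")
  print(round(x$residuals, 1))
  invisible(x)
}

#' Percentage breakdown of a cross-tabulation
#'
#' Divides each cell by its row or column margin and scales to percent,
#' matching the "% within treatment" / "% within infection" rows of a
#' published cross-tabulation.
#'
#' @param tab A `crosstab`.
#' @param axis `"rows"` (each row sums to 100) or `"columns"`.
#' @return Numeric matrix of percentages.
#' @export
percent_breakdown <- function(tab, axis = c("rows", "columns")) {
  stopifnot(inherits(tab, "crosstab"))
  axis <- match.arg(axis)
  margin <- if (axis == "rows") 1L else 2L
  sums <- apply(tab$counts, margin, sum)
  if (any(sums == 0)) {
    stop("zero margin on the chosen axis; drop empty levels first",
         call. = FALSE)
  }
  100 * prop.table(tab$counts, margin)
}

#' Per-group location summaries of depth or distance
#'
#' Classical mean/median/min/max of a numeric record field within each
#' level of a grouping field, as in the per-infection-type summaries of
#' infection depth and longitudinal distance to the stump bole.
#'
#' @param records Weevil record data.frame.
#' @param value_field Numeric field, `"depth_cm"` or `"dist_bole_cm"` (any
#'   numeric column is accepted).
#' @param group_field Categorical field, default `"outcome"`.
#' @return Data.frame with one row per group: `group`, `n`, `mean`,
#'   `median`, `min`, `max`; groups with no records get `NA` summaries.
#' @export
describe_by_group <- function(records, value_field = "depth_cm",
                              group_field = "outcome") {
  if (!value_field %in% names(records)) {
    stop("records have no field '", value_field, "'", call. = FALSE)
  }
  v <- records[[value_field]]
  if (!is.numeric(v)) stop(value_field, " is not numeric", call. = FALSE)
  g <- record_factor(records[[group_field]], group_field)
  out <- data.frame(group = levels(g),
                    n = as.integer(tabulate(g, nbins = nlevels(g))))
  smry <- function(f) {
    vapply(levels(g), function(l) {
      x <- v[g == l]
      if (length(x) == 0) NA_real_ else f(x)
    }, numeric(1))
  }
  out$mean <- smry(mean)
  out$median <- smry(stats::median)
  out$min <- smry(min)
  out$max <- smry(max)
  rownames(out) <- NULL
  out
}
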