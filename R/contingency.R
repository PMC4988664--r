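#' Build a contingency table from two categorical covariates
#'
#' Cross-tabulates two categorical covariates with row, column and grand
#' marginals.  Proportions can be displayed as percentages (SPSS style) or on
#' a 0-1 scale (SAS style); the style affects display only, never the counts
#' or any test computed from the table.
#'
#' @param ds A [survival_dataset()].
#' @param var_row,var_col Names of categorical (factor) covariates.  Numeric
#'   covariates must first be discretised with [stratify()] or merged with
#'   [regroup()].
#' @param style `"percent"` (SPSS, rows/columns sum to 100) or `"unit"`
#'   (SAS, sums to 1).
#' @return An object of class `contingency_table`: `counts` (matrix),
#'   `row_totals`, `col_totals`, `grand_total`, `row_prop`, `col_prop`,
#'   `cell_prop`, `style`.
#' @examples
#' ds <- survival_dataset(1:4, rep(1, 4),
#'                        data.frame(a = c("A", "A", "B", "B"),
#'                                   b = c("X", "Y", "X", "Y")))
#' build_table(ds, "a", "b")
#' @export
build_table <- function(ds, var_row, var_col, style = c("percent", "unit")) {
  stopifnot(inherits(ds, "survival_dataset"))
  style <- match.arg(style)
  for (v in c(var_row, var_col)) {
    if (!v %in% names(ds$covariates))
      stop("no covariate named '", v, "'", call. = FALSE)
    if (is.numeric(ds$covariates[[v]]))
      stop("covariate '", v, "' is numeric; discretise it first with ",
           "stratify() or regroup()", call. = FALSE)
  }
  counts <- table(ds$covariates[[var_row]], ds$covariates[[var_col]],
                  dnn = c(var_row, var_col))
  counts <- unclass(counts)
  scale <- if (style == "percent") 100 else 1
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand_total = sum(counts),
                 row_prop = scale * prop.table(counts, 1L),
                 col_prop = scale * prop.table(counts, 2L),
                 cell_prop = scale * prop.table(counts),
                 style = style),
            class = "contingency_table")
}

#' Construct a contingency table directly from a count matrix
#'
#' @param counts Matrix of non-negative integer cell counts (with dimnames).
#' @inheritParams build_table
#' @return A `contingency_table`.
#' @export
contingency_table <- function(counts, style = c("percent", "unit")) {
  style <- match.arg(style)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (is.null(rownames(counts))) rownames(counts) <- seq_len(nrow(counts))
  if (is.null(colnames(counts))) colnames(counts) <- seq_len(ncol(counts))
  scale <- if (style == "percent") 100 else 1
  structure(list(counts = counts, row_totals = rowSums(counts),
                 col_totals = colSums(counts), grand_total = sum(counts),
                 row_prop = scale * prop.table(counts, 1L),
                 col_prop = scale * prop.table(counts, 2L),
                 cell_prop = scale * prop.table(counts), style = style),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- cbind(rbind(x$counts, Total = x$col_totals),
             Total = c(x$row_totals, x$grand_total))
  cat("Contingency table (", x$style, " style)\n", sep = "")
  print(m)
  cat("\nRow proportions:\n")
  print(round(x$row_prop, 2))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' `sum (O - E)^2 / E` with expected counts from the marginal products,
#' `(r - 1)(c - 1)` degrees of freedom, no continuity correction by default.
#'
#' @param t A `contingency_table` with at least 2 rows and 2 columns.
#' @param correct Apply the Yates continuity correction (2x2 only)?
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  if (nrow(t$counts) < 2L || ncol(t$counts) < 2L)
    stop("need at least a 2x2 table", call. = FALSE)
  expected <- outer(t$row_totals, t$col_totals) / t$grand_total
  if (any(expected == 0))
    stop("zero expected count; merge sparse categories with regroup()",
         call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(t$counts, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided P value summing the hypergeometric probabilities (with the
#' margins fixed) of every table no more probable than the observed one.
#'
#' @param t A 2x2 `contingency_table` with all marginals >= 1.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return The P value.
#' @export
fisher_exact <- function(t, alternative = "two.sided") {
  stopifnot(inherits(t, "contingency_table"))
  if (nrow(t$counts) != 2L || ncol(t$counts) != 2L)
    stop("the Fisher exact test requires a 2x2 table", call. = FALSE)
  if (any(c(t$row_totals, t$col_totals) < 1))
    stop("all marginals must be >= 1", call. = FALSE)
  stats::fisher.test(t$counts, alternative = alternative)$p.value
}

#' McNemar test for a paired 2x2 table
#'
#' `(b - c)^2 / (b + c)` on the discordant cells, chi-square with 1 df, no
#' continuity correction by default.  Requires identically labelled row and
#' column categories (a paired design).  When both discordant cells are zero
#' the statistic is undefined and `NA` is returned.
#'
#' @param t A 2x2 `contingency_table` with matching row/column labels.
#' @param correct Apply the continuity correction?
#' @return List with `statistic`, `df`, `p_value` (all `NA` when undefined).
#' @export
mcnemar <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  if (nrow(t$counts) != 2L || ncol(t$counts) != 2L)
    stop("the McNemar test requires a 2x2 table", call. = FALSE)
  if (!identical(rownames(t$counts), colnames(t$counts)))
    stop("the McNemar test requires identically labelled row and column ",
         "categories (paired design)", call. = FALSE)
  b <- t$counts[1L, 2L]; c_ <- t$counts[2L, 1L]
  if (b + c_ == 0)
    return(list(statistic = NA_real_, df = 1L, p_value = NA_real_,
                note = "no discordant pairs; statistic undefined"))
  res <- stats::mcnemar.test(t$counts, correct = correct)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
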