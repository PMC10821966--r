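#' Pearson chi-squared test on an EF/NEF contingency table
#'
#' Uncorrected Pearson chi-squared test (no Yates continuity correction —
#' the convention that reproduces the printed clinical-table p-values) with
#' empty rows/columns dropped first, as required for tables that carry
#' structurally empty categories (T1, overall stage I).
#'
#' @param table Integer matrix of counts (rows EF/NEF, columns categories),
#'   or one of the [table1_fixtures()] entries.
#' @param drop_empty Drop all-zero rows/columns before testing.
#' @return List with `statistic`, `df`, `p`.
#' @export
pearson_chi2 <- function(table, drop_empty = TRUE) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (drop_empty) m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("table collapses to a single category; chi-squared test undefined")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H test with tie correction and the chi-squared approximation,
#' for ordered or continuous covariates across EF/NEF (or more) groups.
#' All-identical values return H = 0, p = 1.
#'
#' @param groups List of numeric vectors, one per group (>= 2 non-empty).
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L || any(!lengths(groups)))
    stop("need >= 2 non-empty groups")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Clinical characteristics report
#'
#' Runs the Pearson chi-squared test on every reconstructible categorical
#' fixture of [table1_fixtures()] and returns the tidy per-covariate report.
#'
#' @param fixtures Named list of contingency tables.
#' @return data.frame with columns `covariate`, `statistic`, `df`, `p`,
#'   `test`.
#' @export
table1_report <- function(fixtures = table1_fixtures()) {
  do.call(rbind, lapply(names(fixtures), function(nm) {
    r <- pearson_chi2(fixtures[[nm]])
    data.frame(covariate = nm, statistic = r$statistic, df = r$df, p = r$p,
               test = "pearson_chi2", row.names = NULL)
  }))
}
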