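#' Unadjusted group comparison test
#'
#' Dispatches the conventional unadjusted test for a variable compared
#' across groups: Mann--Whitney U for two groups of continuous/ordinal
#' data, Kruskal--Wallis for more than two, Pearson chi-square for
#' categorical variables (with Yates continuity correction on 2x2
#' tables), and optionally one-way analysis of variance for continuous
#' variables.
#'
#' @param data Data frame.
#' @param variable Column to test.
#' @param group Grouping column (factor).
#' @param type `"auto"` (numeric -> rank test, otherwise chi-square),
#'   `"continuous"`, `"categorical"`, or `"anova"`.
#' @return A list with `method`, `statistic`, `p.value`, `n_used`.
#' @export
group_test <- function(data, variable, group,
                       type = c("auto", "continuous", "categorical",
                                "anova")) {
  type <- match.arg(type)
  x <- data[[variable]]
  g <- droplevels(factor(data[[group]]))
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups")
  if (type == "auto")
    type <- if (is.numeric(x)) "continuous" else "categorical"
  if (type == "continuous") {
    if (nlevels(g) == 2) {
      tst <- stats::wilcox.test(x ~ g, exact = FALSE)
      method <- "Mann-Whitney U"
    } else {
      tst <- stats::kruskal.test(x, g)
      method <- "Kruskal-Wallis"
    }
  } else if (type == "anova") {
    tst <- summary(stats::aov(x ~ g))[[1]]
    return(list(method = "one-way ANOVA", statistic = tst$`F value`[1],
                p.value = tst$`Pr(>F)`[1], n_used = length(x)))
  } else {
    tab <- table(factor(x), g)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
        nrow(tab) < 2)
      stop("empty category; consider merging categories")
    correct <- all(dim(tab) == 2)
    tst <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    method <- if (correct) "Pearson chi-square (Yates)" else
      "Pearson chi-square"
  }
  list(method = method, statistic = unname(tst$statistic),
       p.value = tst$p.value, n_used = length(x))
}

quart_fmt <- function(x, digits = 1) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
  sprintf("%s [%s; %s]", format(round(q[2], digits)),
          format(round(q[1], digits)), format(round(q[3], digits)))
}

#' Group summary table (median \[Q1; Q3\] or n (\%))
#'
#' Builds an unadjusted descriptive table in the registry-report layout:
#' continuous/ordinal variables as median \[Q1; Q3\] (quartiles by the
#' linear-interpolation convention, R type 7), categorical variables as
#' n (\%) on the non-missing denominator, one column per group, with the
#' dispatched unadjusted test and the number of records used per variable.
#'
#' @param data Data frame.
#' @param variables Character vector of columns to summarize.
#' @param group Grouping column.
#' @param digits Display rounding (raw values are kept in the `raw`
#'   attribute).
#' @return A `summary_table` data frame: `variable`, `level` (for
#'   categorical rows), one formatted column per group, `test`, `p`,
#'   `n_used`.
#' @export
summarize_groups <- function(data, variables, group, digits = 1) {
  g <- droplevels(factor(data[[group]]))
  if (any(table(g) == 0)) stop("empty group: ",
                               names(which(table(g) == 0))[1])
  levs <- levels(g)
  rows <- list()
  raw <- list()
  for (v in variables) {
    x <- data[[v]]
    ok <- !is.na(x)
    tst <- group_test(data, v, group)
    if (is.numeric(x)) {
      cells <- vapply(levs, function(l) quart_fmt(x[g == l & ok], digits),
                      "")
      names(cells) <- levs
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "", t(cells), test = tst$method,
        p = tst$p.value, n_used = sum(ok), check.names = FALSE,
        stringsAsFactors = FALSE)
      raw[[v]] <- lapply(levs, function(l)
        stats::quantile(x[g == l & ok], c(0.25, 0.5, 0.75), type = 7))
    } else {
      xf <- factor(x[ok])
      gf <- g[ok]
      tab <- table(xf, gf)
      pct <- 100 * sweep(tab, 2, colSums(tab), "/")
      for (lv in rownames(tab)) {
        cells <- sprintf("%d (%s)", tab[lv, levs],
                         format(round(pct[lv, levs], digits)))
        names(cells) <- levs
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv, t(cells), test = tst$method,
          p = tst$p.value, n_used = sum(ok), check.names = FALSE,
          stringsAsFactors = FALSE)
      }
      raw[[v]] <- list(counts = tab, percent = pct)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:(2 + length(levs))] <- levs
  rownames(out) <- NULL
  attr(out, "raw") <- raw
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Share of a count within a cohort, in percent
#'
#' @param count Numerator count(s).
#' @param total Cohort size.
#' @param digits Rounding for display; `NULL` keeps full precision.
#' @return Percentage(s).
#' @export
cohort_share <- function(count, total, digits = NULL) {
  p <- 100 * count / total
  if (!is.null(digits)) p <- round(p, digits)
  p
}
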