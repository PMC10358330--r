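# Quintile summary tables and across-quintile statistics: stratum
# means/SDs or column percentages, a general-association chi-square
# (the unstratified Cochran-Mantel-Haenszel variant) for categorical
# homogeneity, and an OLS linear-trend test on the quintile index.

#' Summarise a variable by adherence quintile
#'
#' Continuous variables get mean and SD per stratum (plus the total
#' column); categorical variables get column percentages per stratum.
#'
#' @param values Per-household variable.
#' @param quintiles Per-household quintile labels (`Q1`..`Q5`).
#' @param kind `"continuous"` or `"categorical"`.
#' @param variable Label carried into the output.
#' @return Data.frame with columns `variable`, `stratum`, `level` (for
#'   categorical), `n`, and `mean`/`sd` or `percent`.
#' @export
quintile_summary <- function(values, quintiles,
                             kind = c("continuous", "categorical"),
                             variable = deparse(substitute(values))) {
  kind <- match.arg(kind)
  if (length(values) != length(quintiles)) {
    abort("values and quintile labels have different lengths",
          "dietimpact_alignment_error")
  }
  strata <- c("total", paste0("Q", 1:5))
  sel <- function(s) if (s == "total") rep(TRUE, length(values)) else
    quintiles == s
  if (kind == "continuous") {
    rows <- lapply(strata, function(s) {
      v <- values[sel(s)]
      data.frame(variable = variable, stratum = s, n = length(v),
                 mean = mean(v), sd = stats::sd(v),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    levels_ <- sort(unique(values))
    rows <- lapply(strata, function(s) {
      v <- values[sel(s)]
      counts <- table(factor(v, levels = levels_))
      data.frame(variable = variable, stratum = s,
                 level = as.character(levels_), n = as.integer(counts),
                 percent = 100 * as.numeric(counts) / length(v),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

#' General-association test of homogeneity across quintiles
#'
#' The unstratified general-association form of the
#' Cochran-Mantel-Haenszel statistic on the quintile x category
#' contingency table: \eqn{(n-1)/n} times the Pearson chi-square, with
#' \eqn{(r-1)(c-1)} degrees of freedom. With no third stratification
#' variable this is the CMH test collapsed to a single stratum.
#'
#' @param categorical Per-household category labels.
#' @param quintiles Per-household quintile labels.
#' @return List with `statistic`, `df`, `p_value`, `table`.
#' @export
homogeneity_test <- function(categorical, quintiles) {
  if (length(categorical) != length(quintiles)) {
    abort("values and quintile labels have different lengths",
          "dietimpact_alignment_error")
  }
  tab <- table(quintiles, categorical)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("homogeneity test needs at least 2 quintiles and 2 categories",
          "dietimpact_degenerate_table_error")
  }
  if (any(rowSums(tab) == 0L)) {
    abort("quintile stratum with zero households",
          "dietimpact_degenerate_table_error")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  pearson <- sum((tab - expected)^2 / expected)
  stat <- (n - 1) / n * pearson
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab)
}

#' Linear trend test across quintiles
#'
#' Ordinary least squares of the variable on the numeric quintile index
#' (1..5): slope, standard error and two-sided p-value. A zero-variance
#' response is flagged (`undefined = TRUE`) rather than reported as a
#' p-value.
#'
#' @param values Per-household continuous variable.
#' @param quintiles Per-household quintile labels (`Q1`..`Q5`).
#' @return List with `slope`, `se`, `statistic`, `df`, `p_value`,
#'   `undefined`.
#' @export
linear_trend_test <- function(values, quintiles) {
  if (length(values) != length(quintiles)) {
    abort("values and quintile labels have different lengths",
          "dietimpact_alignment_error")
  }
  x <- as.numeric(sub("^Q", "", quintiles))
  if (anyNA(x)) {
    abort("quintile labels must be Q1..Q5", "dietimpact_validation_error")
  }
  if (length(unique(x)) < 3L) {
    abort("linear trend test needs at least 3 distinct quintile indices",
          "dietimpact_degenerate_table_error")
  }
  n <- length(values)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (values - mean(values))) / sxx
  resid <- values - mean(values) - slope * (x - mean(x))
  df <- n - 2L
  sigma2 <- sum(resid^2) / df
  if (stats::sd(values) == 0) {
    return(list(slope = 0, se = 0, statistic = NA_real_, df = df,
                p_value = NA_real_, undefined = TRUE))
  }
  se <- sqrt(sigma2 / sxx)
  tstat <- slope / se
  list(slope = slope, se = se, statistic = tstat, df = df,
       p_value = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       undefined = FALSE)
}

# two-tier significance marker used on printed tables
sig_marker <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "ii", ifelse(p < 0.05, "i", "")))
}

#' Quintile report for one pattern
#'
#' Builds the standard survey-table layout for a set of variables against
#' one pattern's quintiles: per-stratum summaries plus the homogeneity
#' (categorical) or linear-trend (continuous) p-value with two-tier
#' significance flags (`i`: p < 0.05, `ii`: p < 0.01). Benjamini-Hochberg
#' adjustment across the table is available behind a flag.
#'
#' @param data Data.frame of per-household variables.
#' @param quintiles Per-household quintile labels for one pattern.
#' @param continuous,categorical Character vectors naming columns of
#'   `data` of each kind.
#' @param adjust_bh Apply Benjamini-Hochberg across the table's p-values.
#' @return Data.frame in long layout with `p_value` and `flag` columns.
#' @export
quintile_report <- function(data, quintiles, continuous = character(),
                            categorical = character(), adjust_bh = FALSE) {
  pieces <- list()
  pvals <- c()
  for (v in continuous) {
    s <- quintile_summary(data[[v]], quintiles, "continuous", variable = v)
    tt <- linear_trend_test(data[[v]], quintiles)
    s$p_value <- tt$p_value
    pieces[[v]] <- s
    pvals[v] <- tt$p_value
  }
  for (v in categorical) {
    s <- quintile_summary(data[[v]], quintiles, "categorical", variable = v)
    ht <- homogeneity_test(data[[v]], quintiles)
    s$p_value <- ht$p_value
    pieces[[v]] <- s
    pvals[v] <- ht$p_value
  }
  if (adjust_bh && length(pvals) > 0L) {
    adj <- stats::p.adjust(pvals, method = "BH")
    for (v in names(adj)) pieces[[v]]$p_value <- adj[[v]]
  }
  all_cols <- c("variable", "stratum", "level", "n", "mean", "sd",
                "percent", "p_value", "flag")
  out <- do.call(rbind, lapply(pieces, function(p) {
    p$flag <- sig_marker(p$p_value)
    for (col in setdiff(all_cols, names(p))) p[[col]] <- NA
    p[all_cols]
  }))
  rownames(out) <- NULL
  out
}
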