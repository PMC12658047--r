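#' IQR-based outlier detection on per-sample QC metrics
#'
#' A sample is flagged when ANY metric falls outside
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\], with quartiles computed per metric across
#' samples by linear interpolation (quantile type 7). This is the boxplot
#' fence rule applied to library QC metrics such as mapped reads, spike-in
#' reads, 5'-end rates and the mapped/spike-in ratio.
#'
#' @param qc data frame of numeric QC metrics; a `sample_id` column, if
#'   present, is carried through and not treated as a metric.
#' @param k fence multiplier (default 1.5).
#' @return list with `outlier` (named logical per sample), `fences` (data
#'   frame metric/lower/upper) and `flagged_by` (list of offending metrics per
#'   flagged sample).
#' @export
detect_outliers_iqr <- function(qc, k = 1.5) {
  ps_assert(is.data.frame(qc), "qc must be a data frame")
  ids <- if ("sample_id" %in% names(qc)) as.character(qc$sample_id)
         else sprintf("sample%02d", seq_len(nrow(qc)))
  metrics <- qc[, setdiff(names(qc), "sample_id"), drop = FALSE]
  ps_assert(all(vapply(metrics, is.numeric, TRUE)),
            "all QC metrics must be numeric")
  ps_assert(nrow(metrics) >= 4, "need >= 4 samples for stable quartiles")
  fences <- do.call(rbind, lapply(names(metrics), function(m) {
    q <- stats::quantile(metrics[[m]], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    data.frame(metric = m, q1 = q[1], q3 = q[2],
               lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  }))
  out_mat <- vapply(seq_along(metrics), function(j) {
    x <- metrics[[j]]
    x < fences$lower[j] | x > fences$upper[j]
  }, logical(nrow(metrics)))
  out_mat <- matrix(out_mat, nrow = nrow(metrics),
                    dimnames = list(ids, names(metrics)))
  flag <- apply(out_mat, 1, any)
  ps_log(sprintf("detect_outliers_iqr: %d/%d samples flagged on %d metrics",
                 sum(flag), length(flag), ncol(metrics)))
  list(outlier = flag,
       fences = fences,
       flagged_by = lapply(ids[flag], function(s) {
         names(metrics)[out_mat[s, ]]
       }) |> stats::setNames(ids[flag]))
}

#' Cohort characteristics table with group comparison tests
#'
#' Compares clinical covariates between the two condition groups (PE vs NP).
#' Continuous variables are tested with Welch's t-test when both groups pass
#' a Shapiro-Wilk normality check (p > 0.05 in each group), otherwise with the
#' Mann-Whitney U test. Categorical variables use the chi-square test on the
#' group-by-level contingency table (Yates continuity correction on 2x2
#' tables, the conventional default). Zero-variance variables are skipped
#' with a note.
#'
#' @param meta `sample_metadata` data frame with a PE/NP `condition` column.
#' @param variables covariate columns to summarize; default every column
#'   except `sample_id` and `condition`.
#' @param shapiro_alpha normality gate (default 0.05).
#' @return data frame: variable, type, per-group summary (mean (SD) for
#'   continuous, counts (%) for categorical), test used, p-value.
#' @export
cohort_summary <- function(meta, variables = NULL, shapiro_alpha = 0.05) {
  cond <- as.character(meta$condition)
  ps_assert(length(unique(cond)) == 2, "condition must have exactly 2 levels")
  groups <- c("PE", "NP")
  ps_assert(all(cond %in% groups), "condition must be coded PE/NP")
  if (is.null(variables)) {
    variables <- setdiff(names(meta), c("sample_id", "condition"))
  }
  rows <- lapply(variables, function(v) {
    x <- meta[[v]]
    if (is.numeric(x) && length(unique(x)) > 5) {
      xs <- split(x, cond)
      summ <- vapply(groups, function(g) {
        sprintf("%.3g (%.3g)", mean(xs[[g]]), stats::sd(xs[[g]]))
      }, "")
      if (stats::sd(x) == 0) {
        return(data.frame(variable = v, type = "continuous",
                          PE = summ["PE"], NP = summ["NP"],
                          test = "skipped (zero variance)", p = NA_real_))
      }
      ps_assert(all(lengths(xs) >= 3), "need >= 3 samples per group for ", v)
      normal <- vapply(xs, function(z) {
        if (stats::sd(z) == 0) return(FALSE)
        stats::shapiro.test(z)$p.value > shapiro_alpha
      }, TRUE)
      if (all(normal)) {
        p <- stats::t.test(xs[["PE"]], xs[["NP"]])$p.value
        test <- "Welch t-test"
      } else {
        p <- stats::wilcox.test(xs[["PE"]], xs[["NP"]], exact = FALSE,
                                correct = TRUE)$p.value
        test <- "Mann-Whitney U"
      }
      data.frame(variable = v, type = "continuous",
                 PE = summ["PE"], NP = summ["NP"], test = test, p = p)
    } else {
      xf <- factor(x)
      if (nlevels(xf) < 2) {
        return(data.frame(variable = v, type = "categorical",
                          PE = NA_character_, NP = NA_character_,
                          test = "skipped (single level)", p = NA_real_))
      }
      tab <- table(xf, factor(cond, levels = groups))
      summ <- vapply(groups, function(g) {
        n <- tab[, g]
        paste(sprintf("%s: %d (%.0f%%)", rownames(tab), n,
                      100 * n / sum(n)), collapse = "; ")
      }, "")
      p <- suppressWarnings(stats::chisq.test(t(tab))$p.value)
      data.frame(variable = v, type = "categorical",
                 PE = summ["PE"], NP = summ["NP"],
                 test = "Chi-square", p = p)
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
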