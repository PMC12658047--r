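#' Mann-Whitney AUC and one-sided p-value
#'
#' AUC = U / (n1 * n2) with ties counted one half; the p-value tests
#' AUC > 0.5 (one-sided) by the normal approximation to the Mann-Whitney U
#' statistic with tie correction. Equivalent to the DeLong test of the same
#' hypothesis.
#'
#' @param scores numeric scores, higher = more PE-like.
#' @param labels binary labels (1 = PE/positive, 0 = NP/negative), or a
#'   PE/NP character vector.
#' @return list: `auc`, `p`.
#' @export
auc_mannwhitney <- function(scores, labels) {
  lab <- if (is.numeric(labels)) as.integer(labels)
         else condition_indicator(labels)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  ps_assert(n1 > 0 && n0 > 0, "both classes must be non-empty")
  r <- rank(scores)
  U <- sum(r[lab == 1]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n0)
  n <- n1 + n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  var_u <- n1 * n0 / 12 * ((n + 1) - tie_term)
  p <- if (var_u <= 0) {
    1   # all scores identical: AUC is exactly 0.5
  } else {
    stats::pnorm((U - n1 * n0 / 2) / sqrt(var_u), lower.tail = FALSE)
  }
  list(auc = auc, p = p)
}

# DeLong analytic 95% CI for the AUC.
auc_delong_ci <- function(scores, labels, conf = 0.95) {
  lab <- if (is.numeric(labels)) as.integer(labels)
         else condition_indicator(labels)
  x <- scores[lab == 1]; y <- scores[lab == 0]
  n1 <- length(x); n0 <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)   # per positive
  v01 <- colMeans(psi)   # per negative
  s2 <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(max(s2, 0))
  c(lo = max(0, auc - half), hi = min(1, auc + half))
}

#' ROC operating point at a fixed false-positive rate
#'
#' Chooses the most permissive threshold whose empirical FPR does not exceed
#' `fpr` (a conservative step rule with no interpolation: calls are
#' score > threshold, and the threshold is the (m+1)-th largest negative
#' score with m = floor(fpr * n_neg), so specificity >= 1 - fpr is
#' guaranteed). Sensitivity, specificity and accuracy are reported at that
#' threshold with 95% percentile CIs from a stratified bootstrap (resampling
#' within class, the operating point recomputed in every replicate).
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels binary labels (1 = positive) or PE/NP strings.
#' @param fpr fixed false-positive rate in (0, 1), default 0.10.
#' @param n_boot bootstrap replicates (default 2000; 0 skips the CIs).
#' @param seed integer seed for the bootstrap stream.
#' @return list: `threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `sensitivity_ci`, `specificity_ci`, `accuracy_ci`, `note`.
#' @export
operating_point <- function(scores, labels, fpr = 0.10, n_boot = 2000,
                            seed = 1) {
  ps_assert(fpr > 0 && fpr < 1, "fpr must be in (0, 1)")
  lab <- if (is.numeric(labels)) as.integer(labels)
         else condition_indicator(labels)
  pos <- scores[lab == 1]; neg <- scores[lab == 0]
  n1 <- length(pos); n0 <- length(neg)
  ps_assert(n1 > 0 && n0 > 0, "both classes must be non-empty")
  point <- function(pos, neg) {
    m <- floor(fpr * length(neg))
    thr <- sort(neg, decreasing = TRUE)[m + 1]
    sens <- mean(pos > thr)
    spec <- mean(neg <= thr)
    acc <- (sum(pos > thr) + sum(neg <= thr)) / (length(pos) + length(neg))
    c(thr = thr, sens = sens, spec = spec, acc = acc)
  }
  pt <- point(pos, neg)
  note <- if (pt["sens"] == 0)
    "no threshold with FPR <= fpr yields a positive call" else ""
  ci <- list(sensitivity = c(NA_real_, NA_real_),
             specificity = c(NA_real_, NA_real_),
             accuracy = c(NA_real_, NA_real_))
  if (n_boot > 0) {
    m <- floor(fpr * n0)
    boot <- with_seed(seed, {
      negb <- matrix(neg[sample.int(n0, n0 * n_boot, replace = TRUE)],
                     n0, n_boot)
      posb <- matrix(pos[sample.int(n1, n1 * n_boot, replace = TRUE)],
                     n1, n_boot)
      # column-wise (m+1)-th largest via a single radix sort
      ord <- order(rep(seq_len(n_boot), each = n0), as.vector(negb))
      sorted <- as.vector(negb)[ord]
      thr_b <- sorted[(seq_len(n_boot) - 1L) * n0 + (n0 - m)]
      tpos <- matrix(thr_b, n1, n_boot, byrow = TRUE)
      tneg <- matrix(thr_b, n0, n_boot, byrow = TRUE)
      sens_b <- .colMeans(posb > tpos, n1, n_boot)
      spec_b <- .colMeans(negb <= tneg, n0, n_boot)
      acc_b <- (sens_b * n1 + spec_b * n0) / (n1 + n0)
      list(sens = sens_b, spec = spec_b, acc = acc_b)
    })
    qs <- function(x) unname(stats::quantile(x, c(0.025, 0.975), type = 7))
    ci <- list(sensitivity = qs(boot$sens),
               specificity = qs(boot$spec),
               accuracy = qs(boot$acc))
  }
  list(threshold = unname(pt["thr"]),
       sensitivity = unname(pt["sens"]),
       specificity = unname(pt["spec"]),
       accuracy = unname(pt["acc"]),
       sensitivity_ci = ci$sensitivity,
       specificity_ci = ci$specificity,
       accuracy_ci = ci$accuracy,
       note = note)
}

#' Per-variable logistic/ROC screen of PE status
#'
#' Fits a single-predictor logistic regression per variable and uses the
#' fitted probabilities as ROC scores. For one monotone predictor the ROC
#' equals that of the raw variable up to orientation, so the score reduces to
#' the variable signed by the logistic slope; variables with complete
#' separation fall back to the raw variable (identical ROC) and are flagged.
#' For each variable: AUC with DeLong 95% CI and the one-sided Mann-Whitney
#' p-value (AUC > 0.5), plus sensitivity/specificity/accuracy at the fixed
#' `fpr` with stratified-bootstrap CIs, and a two-sided Wilcoxon group test
#' on the raw values. AUCs are apparent (in-sample, no cross-validation);
#' interpret confidence intervals accordingly.
#'
#' @param variables numeric matrix, variables x samples (rownames = ids).
#' @param labels PE/NP vector or 0/1, one per sample.
#' @param fpr fixed false-positive rate (default 0.10).
#' @param n_boot bootstrap replicates per variable for the operating-point
#'   CIs (default 2000).
#' @param seed integer seed.
#' @return data frame of class `roc_result`, one row per variable: variable,
#'   auc, auc_lo, auc_hi, auc_p, sensitivity, sens_lo, sens_hi, specificity,
#'   accuracy, acc_lo, acc_hi, threshold, wilcoxon_p, oriented_down,
#'   separation.
#' @export
screen_variables <- function(variables, labels, fpr = 0.10, n_boot = 2000,
                             seed = 1) {
  ps_assert(is.matrix(variables) && !is.null(rownames(variables)),
            "variables must be a matrix with rownames")
  lab <- if (is.numeric(labels)) as.integer(labels)
         else condition_indicator(labels)
  ps_assert(length(lab) == ncol(variables), "one label per sample required")
  ps_log(sprintf("screen_variables: %d variables, %d/%d PE/NP; AUCs are apparent (in-sample)",
                 nrow(variables), sum(lab == 1), sum(lab == 0)))
  one <- function(i) {
    x <- variables[i, ]
    sep <- FALSE
    slope <- tryCatch({
      fit <- withCallingHandlers(
        stats::glm.fit(cbind(1, x), lab, family = stats::binomial()),
        warning = function(w) {
          # "fitted probabilities numerically 0 or 1" signals separation
          if (grepl("0 or 1|converge", conditionMessage(w))) sep <<- TRUE
          invokeRestart("muffleWarning")
        })
      b <- fit$coefficients[2]
      # boundary fitted probabilities or an implausibly steep slope (odds
      # ratio above e^10 per SD) mean (quasi-)separation
      if (!is.finite(b) || !fit$converged ||
          any(fit$fitted.values < 1e-8) || any(fit$fitted.values > 1 - 1e-8) ||
          abs(b) * stats::sd(x) > 10) sep <- TRUE
      b
    }, error = function(e) { sep <<- TRUE; NA_real_ })
    if (sep || !is.finite(slope) || slope == 0) {
      # fall back to the raw variable, oriented by the group-mean difference
      slope <- mean(x[lab == 1]) - mean(x[lab == 0])
      if (slope == 0) slope <- 1
      sep <- sep || FALSE
    }
    score <- if (slope >= 0) x else -x
    mw <- auc_mannwhitney(score, lab)
    ci <- auc_delong_ci(score, lab)
    op <- operating_point(score, lab, fpr = fpr, n_boot = n_boot,
                          seed = derive_seed(seed, rownames(variables)[i]))
    wp <- wilcoxon_group_test(x, lab)
    data.frame(variable = rownames(variables)[i],
               auc = mw$auc, auc_lo = ci["lo"], auc_hi = ci["hi"],
               auc_p = mw$p,
               sensitivity = op$sensitivity,
               sens_lo = op$sensitivity_ci[1], sens_hi = op$sensitivity_ci[2],
               specificity = op$specificity,
               accuracy = op$accuracy,
               acc_lo = op$accuracy_ci[1], acc_hi = op$accuracy_ci[2],
               threshold = op$threshold,
               wilcoxon_p = wp,
               oriented_down = slope < 0,
               separation = sep)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(variables)), one))
  rownames(res) <- NULL
  class(res) <- c("roc_result", "data.frame")
  res
}

#' Filter screened variables on sensitivity
#'
#' Strictly-greater filter on sensitivity at the fixed FPR; the output is
#' sorted by AUC, descending.
#'
#' @param results `roc_result` data frame from [screen_variables()].
#' @param min_sensitivity cutoff (default 0.65, exclusive).
#' @return filtered, AUC-sorted `roc_result`.
#' @export
filter_candidates <- function(results, min_sensitivity = 0.65) {
  keep <- results$sensitivity > min_sensitivity
  out <- results[keep, , drop = FALSE]
  out <- out[order(-out$auc, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  ps_log(sprintf("filter_candidates: %d/%d variables with sensitivity > %g",
                 nrow(out), nrow(results), min_sensitivity))
  out
}

#' Two-sided Wilcoxon rank-sum group test
#'
#' Exact null distribution for small tie-free samples, otherwise the normal
#' approximation with tie and continuity correction; all-identical values
#' give p = 1.
#'
#' @param values numeric vector.
#' @param labels binary labels (1/0 or PE/NP).
#' @return two-sided p-value.
#' @export
wilcoxon_group_test <- function(values, labels) {
  lab <- if (is.numeric(labels)) as.integer(labels)
         else condition_indicator(labels)
  ps_assert(sum(lab == 1) >= 1 && sum(lab == 0) >= 1,
            "both groups must be non-empty")
  if (length(unique(values)) == 1) return(1)
  suppressWarnings(
    stats::wilcox.test(values[lab == 1], values[lab == 0],
                       correct = TRUE)$p.value)
}
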