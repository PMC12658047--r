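#' Negative-binomial Wald differential-expression test
#'
#' Simplified DESeq-style arm: per gene, an NB log-linear model with the
#' condition (PE vs NP) as covariate and the log size factor as offset.
#' Dispersion is estimated per gene by maximum (Cox-Reid adjusted) profile
#' likelihood; genes whose estimate hits the grid boundary fall back to a
#' log-linear dispersion-vs-mean trend fitted across well-estimated genes.
#' The Wald z statistic on the condition coefficient gives the p-value, BH
#' adjusted across tested genes. No shrinkage of fold-changes or dispersions
#' and no independent filtering are applied: this arm's role is the
#' single-gene contrast to the PCA-GSEA route, where subtle coordinated
#' shifts typically yield no single-gene discoveries.
#'
#' @param counts a [count_matrix()], already filtered by the group rule
#'   (fewer than `min_count` counts in fewer than the smallest group size
#'   samples; see [filter_low_counts()]).
#' @param meta `sample_metadata` with PE/NP condition.
#' @param factors `size_factors` (spike-in anchored) or numeric vector.
#' @param alpha BH significance level recorded alongside (default 0.05).
#' @param exclude_spikeins drop spike-in rows from testing (default TRUE).
#' @return data frame of class `dge_result` with DESeq2-style columns:
#'   gene, baseMean, log2FoldChange, lfcSE, stat, pvalue, padj.
#' @export
run_dge <- function(counts, meta, factors, alpha = 0.05,
                    exclude_spikeins = TRUE) {
  y <- counts$counts
  m <- meta[match(colnames(y), meta$sample_id), , drop = FALSE]
  cond <- condition_indicator(m$condition)
  ps_assert(sum(cond == 1) >= 3 && sum(cond == 0) >= 3,
            "need >= 3 samples per condition")
  f <- if (inherits(factors, "size_factors")) factors$factors else factors
  ps_assert(length(f) == ncol(y) && all(f > 0), "invalid size factors")
  test_rows <- rowSums(y) > 0
  if (exclude_spikeins) test_rows <- test_rows & !counts$is_spikein
  n_allzero <- sum(rowSums(y) == 0 & (!exclude_spikeins | !counts$is_spikein))
  if (n_allzero > 0) {
    ps_log(sprintf("run_dge: %d all-zero gene(s) excluded", n_allzero))
  }
  ysub <- y[test_rows, , drop = FALSE]
  fit <- fit_nb_two_group(ysub, cond, offset = log(f))
  # dispersion trend fallback for boundary/non-converged genes
  norm_mean <- rowMeans(sweep(ysub, 2, f, "/"))
  good <- fit$converged & !fit$alpha_at_boundary & norm_mean > 0
  if (sum(good) >= 50 && any(!good)) {
    tr <- stats::lm(log(alpha_hat) ~ log(mu),
                    data = data.frame(alpha_hat = pmax(fit$alpha[good], 1e-6),
                                      mu = norm_mean[good]))
    pred <- exp(stats::predict(tr, data.frame(mu = pmax(norm_mean, 1e-3))))
    redo <- which(!good & fit$converged)
    if (length(redo) > 0) {
      # refit the affected genes with the trend dispersion held fixed
      sub <- nb_irls(ysub[redo, , drop = FALSE], cond, log(f),
                     alpha = pmin(pmax(pred[redo], 1e-6), 10))
      fit$beta1[redo] <- sub$beta1
      fit$se1[redo] <- sub$se1
      fit$alpha[redo] <- pmin(pmax(pred[redo], 1e-6), 10)
    }
  }
  stat <- fit$beta1 / fit$se1
  pval <- 2 * stats::pnorm(-abs(stat))
  pval[!fit$converged] <- NA_real_
  padj <- bh_adjust(pval)
  res <- data.frame(gene = rownames(ysub),
                    baseMean = norm_mean,
                    log2FoldChange = fit$beta1 / log(2),
                    lfcSE = fit$se1 / log(2),
                    stat = stat, pvalue = pval, padj = padj)
  rownames(res) <- NULL
  ps_log(sprintf("run_dge: %d genes tested, %d at padj < %g",
                 sum(!is.na(res$pvalue)), sum(res$padj < alpha, na.rm = TRUE),
                 alpha))
  class(res) <- c("dge_result", "data.frame")
  res
}
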