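#' Filter genes with low counts
#'
#' Two modes mirror the two filtering steps of the pipeline. `global` drops
#' genes whose total count over all samples is below `min_count`; `group`
#' drops genes that fail to reach `min_count` in at least `min_samples`
#' samples (the smallest group size, for differential expression). Spike-in
#' rows are never dropped by either filter; spike-ins with zero totals remain
#' in the matrix but are excluded later from the size-factor reference.
#'
#' @param counts a [count_matrix()].
#' @param mode `"global"` or `"group"`.
#' @param min_count count threshold (default 5).
#' @param min_samples for `mode = "group"`: number of samples that must reach
#'   `min_count` (conventionally the smallest group size).
#' @return filtered [count_matrix()].
#' @export
filter_low_counts <- function(counts, mode = c("global", "group"),
                              min_count = 5, min_samples = NULL) {
  mode <- match.arg(mode)
  ps_assert(min_count >= 0, "min_count must be >= 0")
  y <- counts$counts
  if (mode == "global") {
    keep <- rowSums(y) >= min_count
  } else {
    ps_assert(!is.null(min_samples), "min_samples required for group mode")
    ps_assert(min_samples <= ncol(y), "min_samples exceeds sample count")
    keep <- rowSums(y >= min_count) >= min_samples
  }
  keep <- keep | counts$is_spikein
  ps_log(sprintf("filter_low_counts(%s): %d -> %d genes (%d spike-ins kept)",
                 mode, nrow(y), sum(keep), sum(counts$is_spikein)))
  cm_subset(counts, genes = keep)
}

#' Spike-in anchored size factors (median of ratios)
#'
#' DESeq-style median-of-ratios restricted to spike-in rows: for each sample,
#' the factor is the median over reference spike-ins of
#' count(g, s) / geometric mean of gene g. Spike-ins with a zero count in any
#' sample are excluded from the reference (the "non-zero expressed" rule) and
#' the exclusion is logged. Factors are rescaled to geometric mean 1.
#'
#' @param counts a [count_matrix()] with flagged spike-ins.
#' @return list of class `size_factors`: `factors` (named, geometric mean 1)
#'   and `reference` (spike-in ids used).
#' @export
estimate_spikein_size_factors <- function(counts) {
  y <- counts$counts
  sp <- which(counts$is_spikein)
  ps_assert(length(sp) >= 1, "no spike-ins flagged in the count matrix")
  ys <- y[sp, , drop = FALSE]
  eligible <- rowSums(ys == 0) == 0
  if (sum(eligible) < length(sp)) {
    ps_log(sprintf("size factors: %d/%d spike-ins excluded (zero in >= 1 sample)",
                   sum(!eligible), length(sp)))
  }
  if (sum(eligible) < 2) {
    ps_stop("fewer than 2 spike-ins non-zero in all samples; ",
            "use a pseudo-reference fallback (e.g. filter samples first)")
  }
  ref <- ys[eligible, , drop = FALSE]
  log_geomean <- rowMeans(log(ref))
  ratios <- log(ref) - log_geomean
  log_factors <- apply(ratios, 2, stats::median)
  log_factors <- log_factors - mean(log_factors)   # geometric mean 1
  factors <- exp(log_factors)
  names(factors) <- colnames(y)
  ps_log(sprintf("size factors from %d spike-ins: range %.3f-%.3f",
                 sum(eligible), min(factors), max(factors)))
  structure(list(factors = factors, reference = rownames(ref)),
            class = "size_factors")
}

#' Offset-log normalization
#'
#' value(g, s) = log2(count(g, s) / factor_s + offset). With the default
#' offset 1, zero counts map to 0 and values read in log2 units.
#'
#' @param counts a [count_matrix()] (or bare matrix).
#' @param factors a `size_factors` object or positive numeric vector.
#' @param offset pseudocount added inside the log (default 1, must be > 0).
#' @return numeric matrix of normalized log2 expression.
#' @export
normalize_offset_log <- function(counts, factors, offset = 1) {
  ps_assert(offset > 0, "offset must be > 0")
  y <- if (inherits(counts, "count_matrix")) counts$counts else counts
  f <- if (inherits(factors, "size_factors")) factors$factors else factors
  ps_assert(length(f) == ncol(y), "one size factor per sample required")
  ps_assert(all(f > 0), "size factors must be positive")
  log2(sweep(y, 2, f, "/") + offset)
}

#' Correct gene-wise library bias with a negative-binomial GLM
#'
#' For each gene, fits an NB log-linear model with the log size factor as
#' offset and a library indicator (library 2 vs library 1) as covariate, then
#' divides the library-2 counts by the fitted bias factor and rounds
#' (half-to-even, floored at 0) so the result remains a valid integer count
#' matrix. Genes failing convergence pass through uncorrected and are
#' flagged.
#'
#' @param counts a [count_matrix()] with exactly two library labels.
#' @param size_factors optional `size_factors`; when NULL, spike-in factors
#'   are estimated internally (total-count factors if no usable spike-ins).
#' @return list: `counts` (corrected [count_matrix()]) and `bias` (data frame
#'   gene / log2_bias / converged).
#' @export
correct_library_bias <- function(counts, size_factors = NULL) {
  y <- counts$counts
  libs <- counts$library
  if (nlevels(libs) == 1) {
    warning("single library: bias correction is the identity", call. = FALSE)
    bias <- data.frame(gene = rownames(y), log2_bias = 0, converged = TRUE)
    return(list(counts = counts, bias = bias))
  }
  ps_assert(nlevels(libs) == 2, "exactly 2 library labels required")
  ps_assert(all(table(libs) >= 3), "need >= 3 samples per library")
  if (is.null(size_factors)) {
    size_factors <- tryCatch(estimate_spikein_size_factors(counts),
                             error = function(e) NULL)
  }
  f <- if (is.null(size_factors)) {
    cs <- colSums(y); cs / exp(mean(log(cs)))
  } else size_factors$factors
  x <- as.integer(libs == levels(libs)[2])
  fit <- fit_nb_two_group(y, x, offset = log(f))
  log2_bias <- fit$beta1 / log(2)
  conv <- fit$converged & is.finite(log2_bias)
  log2_bias[!conv] <- 0
  corrected <- y
  i2 <- which(x == 1)
  corrected[, i2] <- round(y[, i2] / 2^log2_bias)
  corrected[corrected < 0] <- 0
  ps_log(sprintf("library bias: median |log2 bias| %.3f over %d genes (%d not converged)",
                 stats::median(abs(log2_bias[conv])), nrow(y), sum(!conv)))
  out <- count_matrix(corrected, counts$is_spikein, counts$library)
  list(counts = out,
       bias = data.frame(gene = rownames(y), log2_bias = log2_bias,
                         converged = conv))
}
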