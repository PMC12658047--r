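#' Fit the technical noise curve from spike-ins
#'
#' Models the squared coefficient of variation of size-factor-normalized
#' spike-in counts as a function of the mean:
#' CV2_tech(mu) = a1 / mu + alpha0, fit by gamma-family regression of CV2 on
#' 1/mu (identity link). Spike-ins carry no biology, so their fluctuations
#' estimate the technical noise floor; a1 captures shot (counting) noise and
#' alpha0 the asymptotic CV2 at high expression. a1 is constrained to be
#' non-negative.
#'
#' @param norm_spikeins normalized (linear-scale) spike-in matrix,
#'   spike-ins x samples.
#' @param min_mean spike-ins with mean below this are excluded from the fit
#'   (default 0, i.e. only zero-mean rows drop).
#' @return list of class `noise_fit`: `a1`, `alpha0`, `n_used`,
#'   `residual_deviance`.
#' @export
fit_technical_noise <- function(norm_spikeins, min_mean = 0) {
  ps_assert(is.matrix(norm_spikeins), "norm_spikeins must be a matrix")
  ps_assert(ncol(norm_spikeins) >= 2, "CV2 undefined with a single sample")
  mu <- rowMeans(norm_spikeins)
  v <- matrixStats::rowVars(norm_spikeins)
  use <- mu > min_mean & v > 0
  ps_assert(sum(use) >= 10, "need >= 10 spike-ins with positive mean and variance")
  mu <- mu[use]
  cv2 <- v[use] / mu^2
  ps_assert(stats::sd(mu) > 0, "degenerate spike-in spread: all means equal")
  df <- data.frame(cv2 = cv2, inv_mu = 1 / mu)
  fit <- tryCatch(
    stats::glm(cv2 ~ inv_mu, data = df,
               family = stats::Gamma(link = "identity"),
               start = c(max(min(cv2), 1e-4), 1)),
    error = function(e) NULL)
  if (is.null(fit)) fit <- stats::lm(cv2 ~ inv_mu, data = df)
  co <- stats::coef(fit)
  a1 <- unname(co["inv_mu"]); alpha0 <- unname(co["(Intercept)"])
  if (!is.finite(a1) || a1 < 0) {
    # shot-noise term cannot be negative: refit as a constant floor
    a1 <- 0
    alpha0 <- mean(cv2)
  }
  alpha0 <- max(alpha0, 0)
  rd <- if (inherits(fit, "glm")) stats::deviance(fit) else sum(stats::resid(fit)^2)
  ps_log(sprintf("technical noise fit on %d spike-ins: CV2 = %.3g/mu + %.3g",
                 length(mu), a1, alpha0))
  structure(list(a1 = a1, alpha0 = alpha0, n_used = length(mu),
                 residual_deviance = rd),
            class = "noise_fit")
}

#' Predict technical CV2 at a given mean
#' @param fit a `noise_fit`.
#' @param mu vector of means.
#' @return predicted technical CV2.
#' @export
predict_cv2_tech <- function(fit, mu) fit$a1 / mu + fit$alpha0

#' Fluctuation (highly-variable-gene) test against spike-in noise
#'
#' Per gene, tests whether the observed CV2 of normalized counts exceeds the
#' technical CV2 predicted from the spike-in fit at the gene's mean. The
#' statistic (n - 1) * CV2_obs / CV2_tech(mu) is referred to the upper tail
#' of the chi-square distribution with n - 1 degrees of freedom, and p-values
#' are BH-adjusted across genes. Genes with padj < alpha are flagged
#' fluctuating. The filtered matrix keeps fluctuating genes PLUS every
#' spike-in, regardless of its p-value: spike-in fluctuations are technical
#' by construction and the downstream normalization still needs them.
#'
#' @param norm_counts normalized (linear-scale) matrix, genes x samples.
#' @param fit a `noise_fit` from [fit_technical_noise()].
#' @param is_spikein logical per row of `norm_counts`.
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @return list of class `fluctuation_result`: `table` (gene, mean, cv2,
#'   cv2_tech, p, padj, fluctuating, spikein), `keep` (logical row filter:
#'   fluctuating or spike-in).
#' @export
test_fluctuation <- function(norm_counts, fit, is_spikein = NULL,
                             alpha = 0.05) {
  ps_assert(inherits(fit, "noise_fit"), "fit must be a noise_fit")
  y <- norm_counts
  n <- ncol(y)
  if (is.null(is_spikein)) is_spikein <- rep(FALSE, nrow(y))
  mu <- rowMeans(y)
  v <- matrixStats::rowVars(y)
  cv2 <- ifelse(mu > 0, v / mu^2, NA_real_)
  cv2_tech <- predict_cv2_tech(fit, mu)
  stat <- (n - 1) * cv2 / cv2_tech
  p <- stats::pchisq(stat, df = n - 1, lower.tail = FALSE)
  p[is.na(p) | mu <= 0] <- 1   # zero-mean genes: CV2 undefined, not fluctuating
  padj <- bh_adjust(p)
  fluct <- padj < alpha
  tab <- data.frame(gene = rownames(y), mean = mu, cv2 = cv2,
                    cv2_tech = cv2_tech, p = p, padj = padj,
                    fluctuating = fluct, spikein = as.logical(is_spikein))
  keep <- fluct | is_spikein
  ps_log(sprintf("fluctuation test: %d/%d genes fluctuating at padj < %g; %d spike-ins kept unconditionally",
                 sum(fluct & !is_spikein), sum(!is_spikein), alpha,
                 sum(is_spikein)))
  structure(list(table = tab, keep = keep), class = "fluctuation_result")
}
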