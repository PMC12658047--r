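# Independent oracles, deliberately naive: each recomputes a quantity by the
# most direct possible route and is never shared with the implementation.

options(pesignal.verbose = FALSE)

# Full weighted-KS running sum by explicit stepping; returns the signed
# extremum and its position.
oracle_es <- function(metric, ids, set, p = 1) {
  ord <- order(-metric, ids)
  ids <- ids[ord]; metric <- metric[ord]
  hit <- ids %in% set
  N <- length(ids); k <- sum(hit)
  stopifnot(k >= 1)
  w <- abs(metric)^p
  nr <- sum(w[hit])
  if (nr == 0) { w[hit] <- 1; nr <- k }
  run <- numeric(N)
  s <- 0
  for (i in seq_len(N)) {
    s <- if (hit[i]) s + w[i] / nr else s - (if (k < N) 1 / (N - k) else 0)
    run[i] <- s
  }
  i_max <- which.max(run); i_min <- which.min(c(0, run))
  lo <- c(0, run)[i_min]
  # same positive tie-break convention as the implementation contract
  if (run[i_max] >= abs(lo) - 1e-9 * (run[i_max] + abs(lo))) run[i_max] else lo
}

# AUC by exhaustive pair counting, ties one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Best sensitivity over every threshold with empirical FPR <= fpr, scanning
# all candidate cutoffs (calls are score > threshold).
oracle_sens_at_fpr <- function(scores, labels, fpr = 0.10) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cand <- sort(unique(c(scores, min(scores) - 1)))
  best <- 0
  for (t in cand) {
    if (mean(neg > t) <= fpr) best <- max(best, mean(pos > t))
  }
  best
}

# Small two-library NB fixture with a known log2 bias applied to library 2.
make_bias_fixture <- function(n_genes = 400, n_per_lib = 10, log2_bias = 1,
                              seed = 1, alpha = c(0.05, 0.3)) {
  withr::with_seed(seed, {
    mu <- exp(runif(n_genes, log(20), log(500)))
    a <- exp(runif(n_genes, log(alpha[1]), log(alpha[2])))
    n <- 2 * n_per_lib
    lib2 <- rep(c(0, 1), each = n_per_lib)
    m <- outer(mu, 2^(log2_bias * lib2))
    y <- matrix(rnbinom(n_genes * n, mu = m, size = 1 / a), n_genes, n,
                dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                                sprintf("S%03d", seq_len(n))))
    count_matrix(y, rep(FALSE, n_genes),
                 ifelse(lib2 == 1, "library2", "library1"))
  })
}

# Toy 4-sample metadata for correlation tests.
toy_meta <- function(ids, condition, ...) {
  df <- data.frame(sample_id = ids, condition = condition,
                   library = "library1", ...)
  class(df) <- c("sample_metadata", "data.frame")
  df
}
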