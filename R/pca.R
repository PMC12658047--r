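#' Drop the lowest-variance variables
#'
#' Ranks variables (rows: genes) by variance across samples and removes the
#' bottom `remove_fraction`. Ties at the cut are broken by variable id
#' (lexicographically smaller ids drop first) so the result is deterministic.
#'
#' @param mat variables x samples numeric matrix with rownames.
#' @param remove_fraction fraction in \[0, 1) to drop (default 0.20).
#' @return the trimmed matrix.
#' @export
trim_low_variance <- function(mat, remove_fraction = 0.20) {
  ps_assert(remove_fraction >= 0 && remove_fraction < 1,
            "remove_fraction must be in [0, 1)")
  v <- matrixStats::rowVars(mat)
  ps_assert(any(v > 0), "all variables constant")
  if (remove_fraction == 0) return(mat)
  n_drop <- floor(remove_fraction * nrow(mat))
  if (n_drop == 0) return(mat)
  ord <- order(v, rownames(mat))   # ties: smaller id drops first
  drop_idx <- ord[seq_len(n_drop)]
  ps_log(sprintf("trim_low_variance: dropped %d/%d variables (fraction %.2f)",
                 n_drop, nrow(mat), remove_fraction))
  mat[-drop_idx, , drop = FALSE]
}

#' Principal component analysis of an expression matrix
#'
#' Centers and unit-variance scales each variable, then decomposes by
#' singular values. Loadings columns have unit norm; the sign convention is
#' that the entry of each loading vector with maximal absolute value is
#' positive (propagated to scores, so reconstruction is unchanged).
#'
#' @param mat variables (genes) x samples matrix; no missing values, no
#'   zero-variance rows (trim first).
#' @param n_pcs number of components to retain; `NULL` (default) keeps all.
#' @return list of class `pca_result`: `scores` (samples x PCs), `loadings`
#'   (genes x PCs), `pct_variance` (per retained PC), `pct_variance_all`,
#'   `n_pcs`.
#' @export
run_pca <- function(mat, n_pcs = NULL) {
  ps_assert(is.matrix(mat) && !anyNA(mat), "mat must be a complete matrix")
  ps_assert(nrow(mat) >= 2 && ncol(mat) >= 2, "need >= 2 variables and samples")
  v <- matrixStats::rowVars(mat)
  ps_assert(all(v > 0), "zero-variance variable present; trim before PCA")
  x <- t(scale(t(mat)))             # variables centered/scaled across samples
  pr <- stats::prcomp(t(x), center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  pct_all <- 100 * ev / sum(ev)
  k_max <- sum(ev > ev[1] * 1e-12)  # numerical rank
  k <- if (is.null(n_pcs)) k_max else min(n_pcs, k_max)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  # sign convention: dominant loading entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(mat)
  rownames(loadings) <- rownames(mat)
  structure(list(scores = scores, loadings = loadings,
                 pct_variance = pct_all[seq_len(k)],
                 pct_variance_all = pct_all, n_pcs = k),
            class = "pca_result")
}

#' Correlate principal components with sample covariates
#'
#' Pearson correlation of each PC score vector against each covariate
#' (point-biserial for binaries: condition is encoded PE = 1 / NP = 0, child
#' sex male = 1, library 2 = 1). PCs whose absolute correlation with the
#' condition reaches `threshold` (inclusive) are marked selected, with the
#' sign recorded for downstream direction inference. Constant covariates give
#' missing correlations and cannot select a PC.
#'
#' @param pca a `pca_result`.
#' @param meta `sample_metadata` rows matching the score rows.
#' @param threshold |r| selection cutoff against condition (default 0.25).
#' @return list of class `pc_correlation`: `r` (PC x covariate matrix),
#'   `selected` (data frame pc / r_condition / sign), `encoding` notes.
#' @export
correlate_pcs <- function(pca, meta, threshold = 0.25) {
  ps_assert(inherits(pca, "pca_result"), "pca must be a pca_result")
  ids <- rownames(pca$scores)
  ps_assert(all(ids %in% meta$sample_id), "metadata must cover all samples")
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  enc <- list()
  covars <- list(condition = condition_indicator(m$condition))
  enc$condition <- "PE=1, NP=0"
  for (col in setdiff(names(m), c("sample_id", "condition"))) {
    x <- m[[col]]
    if (is.numeric(x)) {
      covars[[col]] <- x
    } else if (col == "child_sex") {
      covars[[col]] <- as.integer(as.character(x) %in% c("male", "boy", "M"))
      enc[[col]] <- "male=1, female=0"
    } else if (col == "library") {
      lv <- sort(unique(as.character(x)))
      if (length(lv) == 2) {
        covars[[col]] <- as.integer(as.character(x) == lv[2])
        enc[[col]] <- paste0(lv[2], "=1")
      }
    } else {
      xf <- factor(x)
      if (nlevels(xf) == 2) {
        covars[[col]] <- as.integer(xf) - 1L
        enc[[col]] <- paste0(levels(xf)[2], "=1")
      }
      # >2-level categoricals are not correlation-screenable; skipped
    }
  }
  r <- vapply(covars, function(x) {
    if (stats::sd(x) == 0) return(rep(NA_real_, ncol(pca$scores)))
    as.vector(stats::cor(pca$scores, x))
  }, numeric(ncol(pca$scores)))
  r <- matrix(r, nrow = ncol(pca$scores),
              dimnames = list(colnames(pca$scores), names(covars)))
  rc <- r[, "condition"]
  # inclusive magnitude rule (|r| = threshold selects), robust to rounding
  sel <- which(!is.na(rc) & abs(rc) >= threshold - 1e-12)
  selected <- data.frame(pc = rownames(r)[sel], r_condition = rc[sel],
                         sign = sign(rc[sel]))
  ps_log(sprintf("correlate_pcs: %d PC(s) with |r| >= %.2f against condition: %s",
                 nrow(selected), threshold,
                 paste(selected$pc, collapse = ", ")))
  structure(list(r = r, selected = selected, threshold = threshold,
                 encoding = enc),
            class = "pc_correlation")
}
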