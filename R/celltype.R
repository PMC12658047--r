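#' Derive cell-type marker gene sets from a labeled reference
#'
#' One-vs-rest per cell type on a labeled single-cell-style reference matrix:
#' expression is normalized to counts-per-10k, the log2 fold-change compares
#' mean normalized expression (pseudocount 1) in the type against the rest,
#' and the p-value is a two-sided rank-sum test on log1p-normalized values,
#' BH-adjusted within each one-vs-rest comparison. Markers satisfy the strict
#' thresholds log2FC > `lfc_min` and padj < `alpha`. Progenitor-like labels
#' can be excluded via `blacklist` before derivation (circulating types
#' only).
#'
#' @param ref labeled reference: list with `counts` (genes x cells) and
#'   `cell_type` (label per cell), as returned by
#'   [generate_celltype_reference()].
#' @param lfc_min log2 fold-change threshold, exclusive (default 2.32,
#'   about five-fold).
#' @param alpha BH-adjusted p cutoff, exclusive (default 0.05).
#' @param blacklist labels to drop before derivation (default none).
#' @return named list of class `marker_sets`; per type a data frame
#'   (gene, log2fc, padj). Types with fewer than 3 cells are skipped with a
#'   warning.
#' @export
derive_markers <- function(ref, lfc_min = 2.32, alpha = 0.05,
                           blacklist = character()) {
  y <- ref$counts
  type <- as.character(ref$cell_type)
  keep <- !(type %in% blacklist)
  if (any(!keep)) {
    ps_log(sprintf("derive_markers: %d cell(s) in %d blacklisted type(s) dropped",
                   sum(!keep), length(intersect(blacklist, type))))
  }
  y <- y[, keep, drop = FALSE]
  type <- type[keep]
  types <- sort(unique(type))
  ps_assert(length(types) >= 2, "need >= 2 cell types after blacklisting")
  norm <- sweep(y, 2, colSums(y), "/") * 1e4       # counts per 10k
  logn <- log1p(norm)
  ranks <- matrixStats::rowRanks(logn, ties.method = "average")
  n <- ncol(y)
  sum_r2 <- rowSums(ranks^2)
  out <- list()
  for (tp in types) {
    in_type <- type == tp
    n1 <- sum(in_type); n0 <- n - n1
    if (n1 < 3) {
      warning("cell type ", tp, " has < 3 cells; skipped", call. = FALSE)
      next
    }
    lfc <- log2((rowMeans(norm[, in_type, drop = FALSE]) + 1) /
                  (rowMeans(norm[, !in_type, drop = FALSE]) + 1))
    # vectorized tie-corrected rank-sum z over genes
    U <- rowSums(ranks[, in_type, drop = FALSE]) - n1 * (n1 + 1) / 2
    var_u <- n1 * n0 / (n * (n - 1)) * (sum_r2 - n * (n + 1)^2 / 4)
    z <- ifelse(var_u > 0,
                (abs(U - n1 * n0 / 2) - 0.5) / sqrt(var_u), 0)
    p <- 2 * stats::pnorm(-pmax(z, 0))
    padj <- bh_adjust(p)
    is_marker <- lfc > lfc_min & padj < alpha
    out[[tp]] <- data.frame(gene = rownames(y)[is_marker],
                            log2fc = lfc[is_marker],
                            padj = padj[is_marker])
  }
  ps_log(sprintf("derive_markers: %d type(s), marker counts %s",
                 length(out),
                 paste(vapply(out, nrow, 0L), collapse = "/")))
  structure(out, class = c("marker_sets", "list"))
}

#' Convert marker sets to a gene set collection
#'
#' Types with no markers are dropped (GMT sets must be non-empty).
#' @param markers a `marker_sets` list from [derive_markers()].
#' @return a [gene_set_collection()].
#' @export
markers_to_collection <- function(markers) {
  sets <- lapply(markers, function(df) df$gene)
  sets <- sets[lengths(sets) > 0]
  ps_assert(length(sets) > 0, "no type has any marker")
  gene_set_collection(sets,
                      descriptions = sprintf("%d cell-type markers",
                                             lengths(sets)))
}

#' Rank screened biomarkers by AUC or sensitivity
#'
#' @param results `roc_result` from [screen_variables()].
#' @param by ranking metric: `"auc"` (distinguishing PE from NP) or
#'   `"sensitivity"` (detecting PE).
#' @return a [ranked_list()] tagged with its source metric.
#' @export
rank_biomarkers <- function(results, by = c("auc", "sensitivity")) {
  by <- match.arg(by)
  metric <- stats::setNames(results[[by]], results$variable)
  ranked_list(metric, source = by)
}

#' Cell-type signature enrichment in a biomarker ranking
#'
#' Runs the preranked GSEA engine with cell-type marker sets against an AUC-
#' or sensitivity-ranked biomarker list. A positive NES means the type's
#' markers concentrate among high-metric biomarkers (predictive role
#' "Positive"); negative NES means they concentrate at the bottom
#' ("Negative").
#'
#' @param ranked a [ranked_list()] from [rank_biomarkers()].
#' @param markers `marker_sets` or a [gene_set_collection()].
#' @param n_perm,min_size,max_size,seed passed to [gsea_preranked()].
#' @return `enrichment_result` data frame with a `predictive_role` column.
#' @export
celltype_gsea <- function(ranked, markers, n_perm = 10000, min_size = 5,
                          max_size = 500, seed = 1) {
  coll <- if (inherits(markers, "gene_set_collection")) markers
          else markers_to_collection(markers)
  res <- gsea_preranked(ranked, coll, n_perm = n_perm, min_size = min_size,
                        max_size = max_size, seed = seed)
  res$predictive_role <- ifelse(res$nes > 0, "Positive", "Negative")
  res
}
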