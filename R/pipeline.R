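#' Run the full analysis pipeline
#'
#' Chains every stage in study order: IQR-based QC sample exclusion, cohort
#' summary, low-count filtering, NB library-bias correction, spike-in size
#' factors, offset-log normalization, the spike-in-anchored fluctuation test,
#' low-variance trimming, PCA, PC-condition correlation screening, preranked
#' GSEA on the loadings of every selected PC with direction inference, the NB
#' Wald differential-expression arm, the per-variable logistic/ROC biomarker
#' screen (expression plus numeric metadata covariates), and - when a labeled
#' reference is supplied - cell-type marker derivation and signature
#' enrichment in the AUC- and sensitivity-ranked biomarker lists.
#'
#' @param counts a [count_matrix()].
#' @param metadata `sample_metadata` covering the count columns.
#' @param gene_sets a [gene_set_collection()] for the pathway GSEA (optional).
#' @param qc optional per-sample QC metric table; when supplied, flagged
#'   samples are excluded before any other stage.
#' @param celltype_ref optional `labeled_reference` for cell-type enrichment.
#' @param min_count low-count filter threshold (default 5).
#' @param fluctuation_alpha padj cutoff for fluctuating genes (default 0.05).
#' @param trim_fraction low-variance trim fraction (default 0.20).
#' @param pc_r_threshold |r| cutoff selecting condition-associated PCs
#'   (default 0.25).
#' @param n_pcs maximum PCs retained (default 30).
#' @param n_perm GSEA permutations (default 10000).
#' @param max_perm cap for the adaptive permutation escalation (default 1e5).
#' @param fpr fixed false-positive rate for the screen (default 0.10).
#' @param min_sensitivity candidate filter (default 0.65, exclusive).
#' @param n_boot bootstrap replicates for operating-point CIs (default 2000).
#' @param marker_lfc_min,marker_alpha cell-type marker thresholds.
#' @param do_dge,do_screen,do_celltype stage switches.
#' @param seed integer seed driving every stochastic stage.
#' @return list with per-stage results: `qc_outliers`, `cohort`, `bias`,
#'   `size_factors`, `noise_fit`, `fluctuation`, `expression` (trimmed log2
#'   matrix), `pca`, `pc_correlation`, `gsea` (per selected PC, with
#'   `direction` column), `dge`, `screen`, `candidates`, `celltype`.
#' @export
run_pipeline <- function(counts, metadata, gene_sets = NULL, qc = NULL,
                         celltype_ref = NULL,
                         min_count = 5, fluctuation_alpha = 0.05,
                         trim_fraction = 0.20, pc_r_threshold = 0.25,
                         n_pcs = 30, n_perm = 10000, max_perm = 1e5,
                         fpr = 0.10,
                         min_sensitivity = 0.65, n_boot = 2000,
                         marker_lfc_min = 2.32, marker_alpha = 0.05,
                         do_dge = TRUE, do_screen = TRUE,
                         do_celltype = !is.null(celltype_ref),
                         seed = 1) {
  out <- list()

  # 1. QC exclusion
  if (!is.null(qc)) {
    out$qc_outliers <- detect_outliers_iqr(qc)
    keep <- !out$qc_outliers$outlier[colnames(counts$counts)]
    counts <- cm_subset(counts, samples = keep)
    metadata <- metadata[metadata$sample_id %in% colnames(counts$counts), ]
    ps_log(sprintf("pipeline: %d samples after QC", ncol(counts$counts)))
  }
  meta <- metadata[match(colnames(counts$counts), metadata$sample_id), ]
  out$cohort <- cohort_summary(meta)

  # 2. low-count filter and library bias correction
  counts <- filter_low_counts(counts, mode = "global", min_count = min_count)
  bias_fit <- correct_library_bias(counts)
  counts <- bias_fit$counts
  out$bias <- bias_fit$bias

  # 3. spike-in normalization and fluctuation-based selection
  out$size_factors <- estimate_spikein_size_factors(counts)
  norm_lin <- sweep(counts$counts, 2, out$size_factors$factors, "/")
  out$noise_fit <- fit_technical_noise(norm_lin[counts$is_spikein, ,
                                                drop = FALSE])
  out$fluctuation <- test_fluctuation(norm_lin, out$noise_fit,
                                      is_spikein = counts$is_spikein,
                                      alpha = fluctuation_alpha)
  selected <- cm_subset(counts, genes = out$fluctuation$keep)

  # 4. expression matrix, trimming, PCA, PC-condition screen
  expr <- normalize_offset_log(selected, out$size_factors)
  expr <- trim_low_variance(expr, trim_fraction)
  out$expression <- expr
  out$pca <- run_pca(expr, n_pcs = n_pcs)
  out$pc_correlation <- correlate_pcs(out$pca, meta,
                                      threshold = pc_r_threshold)

  # 5. preranked GSEA on each selected PC's loadings
  out$gsea <- list()
  if (!is.null(gene_sets) && nrow(out$pc_correlation$selected) > 0) {
    for (i in seq_len(nrow(out$pc_correlation$selected))) {
      pc <- out$pc_correlation$selected$pc[i]
      r_pc <- out$pc_correlation$selected$r_condition[i]
      ranked <- ranked_list(out$pca$loadings[, pc],
                            source = paste0(pc, " loading"))
      res <- gsea_preranked(ranked, gene_sets, n_perm = n_perm,
                            max_perm = max_perm,
                            seed = derive_seed(seed, paste0("gsea_", pc)))
      res$direction <- vapply(res$nes, function(nes) {
        if (!is.finite(nes) || nes == 0) "n/a"
        else infer_direction(nes, r_pc)
      }, "")
      res$pc <- pc
      res$pc_condition_r <- r_pc
      out$gsea[[pc]] <- res
    }
  }

  # 6. differential expression (null-result arm)
  if (do_dge) {
    smallest <- min(table(meta$condition))
    dge_counts <- filter_low_counts(counts, mode = "group",
                                    min_count = min_count,
                                    min_samples = smallest)
    dge_factors <- estimate_spikein_size_factors(dge_counts)
    out$dge <- run_dge(dge_counts, meta, dge_factors)
  }

  # 7. biomarker screen on expression + numeric metadata covariates
  if (do_screen) {
    covar_cols <- names(meta)[vapply(meta, is.numeric, TRUE)]
    covars <- t(as.matrix(meta[, covar_cols, drop = FALSE]))
    colnames(covars) <- meta$sample_id
    vars <- rbind(expr[!rownames(expr) %in%
                         rownames(counts$counts)[counts$is_spikein], ,
                       drop = FALSE],
                  covars)
    ps_log(sprintf("pipeline: screening %d variables (expression + metadata)",
                   nrow(vars)))
    out$screen <- screen_variables(vars, meta$condition, fpr = fpr,
                                   n_boot = n_boot,
                                   seed = derive_seed(seed, "screen"))
    out$candidates <- filter_candidates(out$screen, min_sensitivity)
  }

  # 8. cell-type signature enrichment
  if (do_celltype && !is.null(celltype_ref) && do_screen) {
    markers <- derive_markers(celltype_ref, lfc_min = marker_lfc_min,
                              alpha = marker_alpha)
    gene_rows <- out$screen[!out$screen$variable %in% covar_cols, ]
    out$celltype <- list(markers = markers)
    for (by in c("auc", "sensitivity")) {
      ranked <- rank_biomarkers(gene_rows, by = by)
      out$celltype[[by]] <- celltype_gsea(
        ranked, markers, n_perm = n_perm,
        seed = derive_seed(seed, paste0("celltype_", by)))
    }
  }
  out
}
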