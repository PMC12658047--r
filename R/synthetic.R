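#' Simulation configuration for a synthetic maternal-blood STRT study
#'
#' The defaults ARE the study conditions being emulated: 12 PE + 52 NP
#' samples pre-QC, ~12,000 genes, 97 ERCC-style spike-ins across a ~16-fold
#' nominal concentration ladder (so a handful land at zero in some sample,
#' like the 9 spike-ins the real study lost), two libraries balanced for
#' condition with gene-wise multiplicative bias, NB overdispersion for a
#' biological fraction of genes, four planted co-varying pathway programs
#' (three up-, one down-regulated in PE) among 50 decoy sets, and 12 planted
#' single-gene biomarkers whose standardized shifts correspond to binormal
#' AUCs 0.74-0.87 (higher expression in NP, as observed). Outlier samples (2
#' PE + 13 NP) get aberrant QC metrics so that IQR-based QC recovers the
#' 10 + 39 analysis cohort.
#'
#' @param n_samples_pe,n_samples_np pre-QC group sizes (integers).
#' @param n_genes,n_spikeins matrix dimensions.
#' @param library_assignment fraction of samples assigned to library 2,
#'   balanced within condition (default 0.5).
#' @param bias_sd SD of gene-wise log2 library-2 bias factors (default 0.25).
#' @param dispersion NB dispersion for biological genes: `NULL` draws
#'   per-gene alpha log-uniform in \[0.01, 0.5\]; a scalar fixes it; a
#'   length-2 vector is a log-uniform range; a length-`n_genes` vector is
#'   used as-is.
#' @param frac_fluctuating fraction of non-planted genes given biological
#'   overdispersion (the rest are technical-only, i.e. Poisson); default 0.5.
#' @param planted_pathways data frame with columns `id`, `size`,
#'   `log2_shift` (sign = direction in PE); when omitted, three up- and one
#'   down-regulated 100-member programs at 1.0 log2 (sizes shrink
#'   proportionally for small gene universes). `NULL` plants none.
#' @param planted_biomarkers named numeric vector of standardized shifts
#'   delta on the normalized-log scale (expected AUC = pnorm(delta/sqrt(2))).
#' @param biomarker_direction +1 (higher in PE) or -1 (higher in NP,
#'   default, as in the observed candidates).
#' @param n_decoy_sets,decoy_sizes decoy gene sets for enrichment testing.
#' @param spikein_concentrations nominal molecule counts per spike-in;
#'   default a geometric ladder 0.25..4096.
#' @param depth_range per-sample sequencing-depth multiplier range (log-
#'   uniform; default 0.5-2).
#' @param program_activity_sd SD of the latent per-sample pathway program
#'   activity around its condition mean (default 0.35): members co-vary
#'   within and across samples, which is what lets PCA pick the programs up.
#' @param pathway_jitter_sd gene-wise SD around the common pathway shift
#'   (default 0.1 log2).
#' @param biomarker_log2_sd within-group log2 SD of biomarker genes
#'   (default 0.5).
#' @param n_outliers_pe,n_outliers_np samples given aberrant QC metrics.
#' @param seed integer; one global seed, all random streams derived from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples_pe = 12, n_samples_np = 52,
                              n_genes = 12000, n_spikeins = 97,
                              library_assignment = 0.5,
                              bias_sd = 0.25,
                              dispersion = NULL,
                              frac_fluctuating = 0.5,
                              planted_pathways = NULL,
                              planted_biomarkers = stats::setNames(
                                seq(0.91, 1.59, length.out = 12),
                                sprintf("BIOMARKER%02d", 1:12)),
                              biomarker_direction = -1,
                              n_decoy_sets = 50,
                              decoy_sizes = c(20, 30, 50),
                              spikein_concentrations = NULL,
                              depth_range = c(0.5, 2),
                              program_activity_sd = 0.35,
                              pathway_jitter_sd = 0.1,
                              biomarker_log2_sd = 0.5,
                              n_outliers_pe = 2, n_outliers_np = 13,
                              seed = 1) {
  if (missing(planted_pathways)) {
    # default: three up- and one down-regulated program, 100 members each
    # at study scale, shrunk proportionally for small gene universes
    sz <- min(100, max(2, (n_genes - length(planted_biomarkers)) %/% 8))
    planted_pathways <- data.frame(
      id = c("PROGRAM_UP1", "PROGRAM_UP2", "PROGRAM_UP3", "PROGRAM_DOWN1"),
      size = sz, log2_shift = c(1, 1, 1, -1))
  }
  cfg <- as.list(environment())
  ps_assert(n_samples_pe == round(n_samples_pe) &&
              n_samples_np == round(n_samples_np),
            "sample counts must be integers")
  ps_assert(n_samples_pe > 0 && n_samples_np > 0 && n_genes > 0 &&
              n_spikeins > 0, "all counts must be > 0")
  ps_assert(bias_sd >= 0, "bias_sd must be >= 0")
  ps_assert(all(depth_range > 0) && length(depth_range) == 2,
            "depth multipliers must be positive")
  ps_assert(library_assignment > 0 && library_assignment < 1,
            "library_assignment must be in (0, 1)")
  if (!is.null(planted_pathways)) {
    ps_assert(sum(planted_pathways$size) + length(planted_biomarkers) <=
                n_genes,
              "planted member count exceeds n_genes")
  }
  if (is.null(spikein_concentrations)) {
    # geometric ladder; the lowest rungs land at zero in some sample and are
    # excluded from the size-factor reference, like the real mix
    cfg$spikein_concentrations <-
      2^seq(2, 14, length.out = n_spikeins)
  } else {
    ps_assert(length(spikein_concentrations) == n_spikeins,
              "one concentration per spike-in required")
    ps_assert(all(spikein_concentrations > 0), "concentrations must be > 0")
  }
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic study with known ground truth
#'
#' Draws a genes-by-samples UMI count matrix, sample metadata with the
#' clinical covariate structure of the emulated cohort, a QC metric table
#' with planted outliers, gene-set collections (planted programs plus
#' decoys), and a ground-truth record of every planted effect.
#'
#' Count model: spike-in s has Poisson expectation concentration x depth (no
#' condition or library effect, technical noise only). A non-spike-in gene g
#' in library l of sample s is NB with expectation
#' base_g x depth_s x 2^bias(g, l) x 2^(shift_g(s)), where shift is zero
#' except for pathway members (direction x (common shift + gene jitter) x
#' latent program activity, activity = 1 in PE on average) and biomarkers
#' (delta_g x sigma on the log2 scale in PE, lognormal within-group noise).
#'
#' @param config a [simulation_config()].
#' @return list: `counts` ([count_matrix()]), `metadata`, `qc`
#'   (per-sample QC metric table), `gene_sets` ([gene_set_collection()]),
#'   `truth` (list: true_bias_factors, true_fluctuating_genes,
#'   pathway_direction, pathway_members, biomarker_auc_expected,
#'   biomarker_delta, outlier_samples, program_activity).
#' @export
generate_dataset <- function(config = simulation_config()) {
  ps_assert(inherits(config, "simulation_config"),
            "config must be a simulation_config")
  cfg <- config
  n_pe <- cfg$n_samples_pe; n_np <- cfg$n_samples_np
  n <- n_pe + n_np
  G <- cfg$n_genes; S <- cfg$n_spikeins

  sample_ids <- sprintf("S%03d", seq_len(n))
  condition <- c(rep("PE", n_pe), rep("NP", n_np))
  gene_ids <- sprintf("GENE%05d", seq_len(G))
  spike_ids <- sprintf("ERCC-%05d", seq_len(S))

  # --- planted gene assignments (deterministic stream) -----------------
  pw <- cfg$planted_pathways
  bm_delta <- cfg$planted_biomarkers
  members <- list()
  used <- integer(0)
  with_seed(derive_seed(cfg$seed, "assign"), {
    if (!is.null(pw) && nrow(pw) > 0) {
      for (i in seq_len(nrow(pw))) {
        pick <- sample(setdiff(seq_len(G), used), pw$size[i])
        members[[pw$id[i]]] <- sort(pick)
        used <- c(used, pick)
      }
    }
    bm_idx <- sort(sample(setdiff(seq_len(G), used), length(bm_delta)))
    used <- c(used, bm_idx)
  })
  if (length(bm_delta) > 0) {
    # planted biomarkers keep recognizable ids
    gene_ids[bm_idx] <- names(bm_delta)
  }

  # --- per-gene parameters ---------------------------------------------
  with_seed(derive_seed(cfg$seed, "genes"), {
    log2_base <- stats::runif(G, -5, 9)   # low tail feeds the count filter
    for (m in members) log2_base[m] <- stats::runif(length(m),
                                                    log2(50), log2(500))
    if (length(bm_delta) > 0) log2_base[bm_idx] <- stats::runif(
      length(bm_idx), 7, 9)
    alpha <- if (is.null(cfg$dispersion)) {
      exp(stats::runif(G, log(0.01), log(0.5)))
    } else if (length(cfg$dispersion) == 2 && G != 2) {
      exp(stats::runif(G, log(cfg$dispersion[1]), log(cfg$dispersion[2])))
    } else {
      rep(cfg$dispersion, length.out = G)
    }
    biological <- stats::runif(G) < cfg$frac_fluctuating
    alpha[!biological] <- 0
    alpha[unlist(members)] <- pmax(alpha[unlist(members)], 0.05)
    biological[unlist(members)] <- TRUE
    if (length(bm_delta) > 0) biological[bm_idx] <- TRUE
    bias <- stats::rnorm(G, 0, cfg$bias_sd)        # log2, library 2 vs 1
    jitter <- stats::rnorm(G, 0, cfg$pathway_jitter_sd)
  })

  # --- per-sample structure --------------------------------------------
  with_seed(derive_seed(cfg$seed, "samples"), {
    depth <- exp(stats::runif(n, log(cfg$depth_range[1]),
                              log(cfg$depth_range[2])))
    # library balanced within condition
    lib <- integer(n)
    for (g in c("PE", "NP")) {
      idx <- which(condition == g)
      n2 <- round(cfg$library_assignment * length(idx))
      lib[idx] <- c(rep(2L, n2), rep(1L, length(idx) - n2))[
        sample.int(length(idx))]
    }
    activity <- (condition == "PE") +
      stats::rnorm(n, 0, cfg$program_activity_sd)
  })

  # --- counts ------------------------------------------------------------
  is_pe <- condition == "PE"
  log2_mu <- matrix(log2_base, G, n) +
    matrix(log2(depth), G, n, byrow = TRUE) +
    outer(bias, as.numeric(lib == 2))
  if (!is.null(pw) && nrow(pw) > 0) {
    for (i in seq_len(nrow(pw))) {
      m <- members[[pw$id[i]]]
      shift_g <- sign(pw$log2_shift[i]) *
        pmax(abs(pw$log2_shift[i]) + jitter[m], 0)
      log2_mu[m, ] <- log2_mu[m, ] + outer(shift_g, activity)
    }
  }
  counts <- matrix(0L, G, n, dimnames = list(gene_ids, sample_ids))
  with_seed(derive_seed(cfg$seed, "counts"), {
    sigma <- cfg$biomarker_log2_sd
    if (length(bm_delta) > 0) {
      z <- matrix(stats::rnorm(length(bm_idx) * n), length(bm_idx), n)
      log2_mu[bm_idx, ] <- log2_mu[bm_idx, ] + sigma * z +
        cfg$biomarker_direction * sigma *
          outer(unname(bm_delta), as.numeric(is_pe))
    }
    mu <- 2^log2_mu
    pois_rows <- alpha == 0
    if (length(bm_delta) > 0) pois_rows[bm_idx] <- TRUE
    counts[pois_rows, ] <- stats::rpois(sum(pois_rows) * n,
                                        mu[pois_rows, ])
    nb_rows <- which(!pois_rows)
    if (length(nb_rows) > 0) {
      counts[nb_rows, ] <- stats::rnbinom(length(nb_rows) * n,
                                          mu = mu[nb_rows, ],
                                          size = 1 / alpha[nb_rows])
    }
    spike_mu <- outer(cfg$spikein_concentrations, depth)
    spikes <- matrix(stats::rpois(S * n, spike_mu), S, n,
                     dimnames = list(spike_ids, sample_ids))
    counts <- rbind(counts, spikes)
  })
  cm <- count_matrix(counts,
                     is_spikein = c(rep(FALSE, G), rep(TRUE, S)),
                     library = paste0("library", lib))

  # --- metadata (Table-1-like covariate structure) -----------------------
  meta <- with_seed(derive_seed(cfg$seed, "meta"), {
    pick2 <- function(pe_fun, np_fun) ifelse(is_pe, pe_fun(n), np_fun(n))
    data.frame(
      sample_id = sample_ids,
      condition = condition,
      library = paste0("library", lib),
      maternal_age = round(ifelse(is_pe, stats::rnorm(n, 35, 3.0),
                                  stats::rnorm(n, 34, 5.0)), 1),
      bmi = round(ifelse(is_pe, stats::rnorm(n, 23, 3.0),
                         stats::rnorm(n, 22, 1.6)), 1),
      bmi_category = ifelse(is_pe & stats::runif(n) < 0.3,
                            "obese", "normal"),
      parity = ifelse(is_pe,
                      sample(c("0", "1", "2+"), n, TRUE, c(.6, .3, .1)),
                      sample(c("0", "1", "2+"), n, TRUE, c(.49, .38, .13))),
      gestational_age = round(ifelse(is_pe, stats::rnorm(n, 38, 1.5),
                                     stats::rnorm(n, 40, 1.3)), 1),
      child_sex = ifelse(stats::runif(n) < ifelse(is_pe, 0.5, 0.46),
                         "boy", "girl"),
      birth_weight = round(ifelse(is_pe, stats::rnorm(n, 3100, 470),
                                  stats::rnorm(n, 3500, 360))),
      rin = round(ifelse(is_pe, stats::rnorm(n, 8.7, 0.39),
                         stats::rnorm(n, 8.3, 0.49)), 2))
  })
  class(meta) <- c("sample_metadata", "data.frame")

  # --- QC metrics with planted outliers ----------------------------------
  qc_out <- with_seed(derive_seed(cfg$seed, "qc"), {
    qc <- data.frame(
      sample_id = sample_ids,
      mapped_reads = round(3e6 * depth * exp(stats::rnorm(n, 0, 0.05))),
      spikein_reads = round(3e4 * depth * exp(stats::rnorm(n, 0, 0.05))),
      spikein_5prime_rate = pmin(pmax(stats::rnorm(n, 0.85, 0.02), 0), 1),
      mapped_rate = pmin(pmax(stats::rnorm(n, 0.75, 0.02), 0), 1),
      mapped_spikein_ratio = stats::rnorm(n, 100, 5),
      coding_5prime_rate = pmin(pmax(stats::rnorm(n, 0.7, 0.02), 0), 1))
    out_pe <- utils::head(which(is_pe), cfg$n_outliers_pe)
    out_np <- utils::head(which(!is_pe), cfg$n_outliers_np)
    out_idx <- c(out_pe, out_np)
    # degraded libraries shift the tight rate/ratio metrics; the count
    # metrics have depth-driven spread that puts the lower IQR fence below
    # zero, so excursions there would be undetectable by construction
    tight <- c("spikein_5prime_rate", "mapped_rate",
               "mapped_spikein_ratio", "coding_5prime_rate")
    for (i in out_idx) {
      colm <- sample(tight, 1)
      qc[i, colm] <- qc[i, colm] * sample(c(0.5, 1.6), 1)
    }
    list(qc = qc, outliers = sample_ids[out_idx])
  })

  # --- gene set collections ----------------------------------------------
  sets <- members
  sets <- lapply(sets, function(m) gene_ids[m])
  with_seed(derive_seed(cfg$seed, "decoys"), {
    pool <- setdiff(seq_len(G), used)
    for (d in seq_len(cfg$n_decoy_sets)) {
      sz <- sample(cfg$decoy_sizes, 1)
      sets[[sprintf("DECOY%03d", d)]] <- gene_ids[sort(sample(pool, sz))]
    }
  })
  collection <- gene_set_collection(sets)

  truth <- list(
    true_bias_factors = stats::setNames(c(bias, rep(0, S)),
                                        c(gene_ids, spike_ids)),
    true_fluctuating_genes = gene_ids[biological],
    pathway_direction = if (!is.null(pw) && nrow(pw) > 0) {
      stats::setNames(ifelse(pw$log2_shift > 0, "up", "down"), pw$id)
    } else stats::setNames(character(0), character(0)),
    pathway_members = lapply(members, function(m) gene_ids[m]),
    biomarker_auc_expected = stats::setNames(
      stats::pnorm(unname(bm_delta) / sqrt(2)), names(bm_delta)),
    biomarker_delta = bm_delta,
    biomarker_direction = cfg$biomarker_direction,
    outlier_samples = qc_out$outliers,
    program_activity = stats::setNames(activity, sample_ids))
  stopifnot(all(truth$biomarker_auc_expected >= 0.5),
            all(truth$biomarker_auc_expected <= 1))

  ps_log(sprintf("generate_dataset: %d genes + %d spike-ins x %d samples (%d PE, %d NP), %d gene sets",
                 G, S, n, n_pe, n_np, length(collection)))
  list(counts = cm, metadata = meta, qc = qc_out$qc,
       gene_sets = collection, truth = truth)
}

#' Generate a labeled blood-cell reference (synthetic stand-in)
#'
#' Stand-in for a labeled blood single-cell reference: `n_types` circulating
#' cell types, `cells_per_type` cells each, with exactly `markers_per_type`
#' genes per type whose expectation is 2^`fold` higher in that type than in
#' the others. Counts are NB with mild overdispersion and per-cell depth
#' variation.
#'
#' @param n_types number of cell types (default 24, the circulating types).
#' @param cells_per_type cells per type (default 50).
#' @param markers_per_type planted markers per type (default 20).
#' @param fold log2 enrichment of a marker in its own type (default 3).
#' @param n_genes reference gene universe size (default 2000).
#' @param gene_ids optional gene-id vector (length >= n_genes) so the
#'   reference shares a universe with a generated study.
#' @param seed integer seed.
#' @return list of class `labeled_reference`: `counts` (genes x cells),
#'   `cell_type` (label per cell), `truth` (named list of planted marker ids
#'   per type).
#' @export
generate_celltype_reference <- function(n_types = 24, cells_per_type = 50,
                                        markers_per_type = 20, fold = 3,
                                        n_genes = 2000, gene_ids = NULL,
                                        seed = 1) {
  ps_assert(fold >= 0, "fold must be >= 0")
  ps_assert(markers_per_type * n_types <= n_genes,
            "markers_per_type x n_types exceeds n_genes")
  if (is.null(gene_ids)) gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
  ps_assert(length(gene_ids) >= n_genes, "gene_ids shorter than n_genes")
  gene_ids <- gene_ids[seq_len(n_genes)]
  types <- sprintf("CT%02d", seq_len(n_types))
  n_cells <- n_types * cells_per_type
  cell_type <- rep(types, each = cells_per_type)
  with_seed(derive_seed(seed, "celltype_ref"), {
    base <- 2^stats::runif(n_genes, -1, 5.5)
    marker_idx <- matrix(sample.int(n_genes, markers_per_type * n_types),
                         markers_per_type, n_types)
    # cell-type markers are well-expressed genes; a floor on their base mean
    # keeps the pseudocount in downstream fold-change screens negligible
    base[marker_idx] <- pmax(base[marker_idx], 2^stats::runif(
      length(marker_idx), 2.5, 5.5))
    depth <- exp(stats::rnorm(n_cells, 0, 0.3))
    mu <- outer(base, depth)
    for (t in seq_len(n_types)) {
      cells_t <- which(cell_type == types[t])
      mu[marker_idx[, t], cells_t] <- mu[marker_idx[, t], cells_t] * 2^fold
    }
    counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                    size = 1 / 0.05),
                     n_genes, n_cells,
                     dimnames = list(gene_ids,
                                     sprintf("cell%05d", seq_len(n_cells))))
  })
  truth <- stats::setNames(
    lapply(seq_len(n_types), function(t) sort(gene_ids[marker_idx[, t]])),
    types)
  structure(list(counts = counts, cell_type = cell_type, truth = truth),
            class = "labeled_reference")
}

#' Write dataset components to a directory
#'
#' Counts as TSV, metadata and QC as CSV, gene sets as GMT, ground truth as
#' JSON.
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(dataset$counts, file.path(dir, "counts.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.csv"))
  utils::write.csv(dataset$qc, file.path(dir, "qc.csv"), row.names = FALSE,
                   quote = FALSE)
  write_gmt(dataset$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- dataset$truth
  truth$program_activity <- as.list(truth$program_activity)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
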