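small_cfg <- function(seed = 1, ...) {
  simulation_config(n_samples_pe = 6, n_samples_np = 14, n_genes = 300,
                    n_spikeins = 30,
                    planted_pathways = data.frame(id = "P1", size = 20,
                                                  log2_shift = 1),
                    planted_biomarkers = c(BM1 = 1.19),
                    n_decoy_sets = 3, n_outliers_pe = 0, n_outliers_np = 0,
                    seed = seed, ...)
}

test_that("generation is deterministic and structurally sound", {
  d1 <- generate_dataset(small_cfg())
  d2 <- generate_dataset(small_cfg())
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(d1$truth, d2$truth)
  y <- d1$counts$counts
  expect_true(all(y >= 0) && max(abs(y - round(y))) == 0)
  expect_equal(sum(d1$counts$is_spikein), 30)
  expect_equal(ncol(y), 20)
  expect_setequal(names(d1$truth$pathway_direction), "P1")
  # planted members and biomarkers are disjoint from spike-ins
  spikes <- rownames(y)[d1$counts$is_spikein]
  expect_length(intersect(unlist(d1$truth$pathway_members), spikes), 0)
  expect_length(intersect(names(d1$truth$biomarker_delta), spikes), 0)
})

test_that("config invariants reject bad inputs", {
  expect_error(simulation_config(n_samples_pe = 2.5), "integers")
  expect_error(simulation_config(bias_sd = -1), "bias_sd")
  expect_error(simulation_config(depth_range = c(-1, 2)), "positive")
  expect_error(simulation_config(n_genes = 30, planted_pathways =
    data.frame(id = "P", size = 40, log2_shift = 1)), "exceeds n_genes")
})

test_that("spike-ins follow concentration x depth with no condition effect", {
  cfg <- simulation_config(n_samples_pe = 30, n_samples_np = 30,
                           n_genes = 50, n_spikeins = 40,
                           planted_pathways = NULL,
                           planted_biomarkers = NULL, n_decoy_sets = 0,
                           depth_range = c(1, 1),
                           n_outliers_pe = 0, n_outliers_np = 0, seed = 9)
  d <- generate_dataset(cfg)
  sp <- d$counts$counts[d$counts$is_spikein, ]
  conc <- cfg$spikein_concentrations
  # expectation tracks nominal concentration (depth fixed at 1)
  expect_equal(unname(rowMeans(sp) / conc), rep(1, 40), tolerance = 0.2)
  # no dependence on the PE label: regression slope compatible with zero
  pe <- as.integer(d$metadata$condition == "PE")
  slopes <- apply(sp[conc > 50, ], 1, function(y) {
    f <- lm(log1p(y) ~ pe)
    coef(summary(f))["pe", "t value"]
  })
  expect_lt(mean(abs(slopes) > 2), 0.15)
  # Poisson technical noise only: dispersion index near 1
  di <- apply(sp[conc > 50, ], 1, function(y) var(y) / mean(y))
  expect_equal(median(di), 1, tolerance = 0.2)
})

test_that("planted biomarker AUC matches the closed-form binormal oracle", {
  # delta = 1.19 at 10 vs 39: E[AUC] = pnorm(1.19 / sqrt(2)) ~ 0.80;
  # averaged over seeds because a single 10v39 draw has SD(AUC) ~ 0.08
  aucs <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_samples_pe = 10, n_samples_np = 39,
                             n_genes = 100, n_spikeins = 10,
                             planted_pathways = NULL,
                             planted_biomarkers = c(BM1 = 1.19),
                             n_decoy_sets = 0, n_outliers_pe = 0,
                             n_outliers_np = 0, seed = 200 + s)
    d <- generate_dataset(cfg)
    f <- estimate_spikein_size_factors(d$counts)
    e <- normalize_offset_log(d$counts, f)
    lab <- as.integer(d$metadata$condition == "PE")
    auc_mannwhitney(-e["BM1", ], lab)$auc   # biomarkers are higher in NP
  }, 0)
  expect_equal(mean(aucs), pnorm(1.19 / sqrt(2)), tolerance = 0.08)
  expect_equal(unname(generate_dataset(small_cfg())$truth$
                        biomarker_auc_expected["BM1"]),
               pnorm(1.19 / sqrt(2)))
})

test_that("expected biomarker AUC is monotone in delta and inside [0.5, 1]", {
  cfg <- simulation_config(planted_biomarkers =
    setNames(seq(0.2, 2.5, length.out = 8), paste0("B", 1:8)))
  d <- generate_dataset(modifyList(cfg, list(n_genes = 200, n_spikeins = 10,
    n_samples_pe = 3, n_samples_np = 5, planted_pathways = NULL,
    n_decoy_sets = 0, n_outliers_pe = 0, n_outliers_np = 0)) |>
      structure(class = "simulation_config"))
  a <- d$truth$biomarker_auc_expected
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= 0.5 & a <= 1))
})

test_that("bias_sd = 0 yields zero recorded bias and unit library ratios", {
  # depth fixed at 1 so the library mean-ratio isolates the bias term
  d <- generate_dataset(small_cfg(seed = 5, bias_sd = 0,
                                  depth_range = c(1, 1)))
  expect_true(all(d$truth$true_bias_factors == 0))
  y <- d$counts$counts[!d$counts$is_spikein, ]
  lib2 <- d$counts$library == "library2"
  keep <- rowSums(y) > 200
  ratio <- rowMeans(y[keep, lib2]) / rowMeans(y[keep, !lib2])
  expect_equal(median(ratio), 1, tolerance = 0.15)
})

test_that("planted pathway shifts carry the recorded sign", {
  cfg <- simulation_config(n_samples_pe = 15, n_samples_np = 15,
                           n_genes = 500, n_spikeins = 20,
                           planted_pathways = data.frame(
                             id = c("UP", "DOWN"), size = c(25, 25),
                             log2_shift = c(1, -1)),
                           planted_biomarkers = NULL, n_decoy_sets = 0,
                           n_outliers_pe = 0, n_outliers_np = 0, seed = 8)
  d <- generate_dataset(cfg)
  f <- estimate_spikein_size_factors(d$counts)
  e <- normalize_offset_log(d$counts, f)
  pe <- d$metadata$condition == "PE"
  dm <- rowMeans(e[, pe]) - rowMeans(e[, !pe])
  expect_gt(mean(dm[d$truth$pathway_members$UP]), 0)
  expect_lt(mean(dm[d$truth$pathway_members$DOWN]), 0)
  expect_equal(unname(d$truth$pathway_direction), c("up", "down"))
})

test_that("QC outliers planted in the metrics are recovered by the IQR rule", {
  d <- generate_dataset(simulation_config(
    n_samples_pe = 12, n_samples_np = 52, n_genes = 50, n_spikeins = 10,
    planted_pathways = NULL, planted_biomarkers = NULL, n_decoy_sets = 0,
    seed = 6))
  res <- detect_outliers_iqr(d$qc)
  flagged <- names(res$outlier)[res$outlier]
  expect_gte(length(intersect(flagged, d$truth$outlier_samples)),
             0.8 * length(d$truth$outlier_samples))
})
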