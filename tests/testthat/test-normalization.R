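toy_cm <- function() {
  y <- rbind(G1 = c(1, 1, 2), G2 = c(2, 2, 1), G3 = c(10, 5, 5),
             `ERCC-1` = c(0, 0, 0))
  colnames(y) <- c("A", "B", "C")
  count_matrix(y, c(FALSE, FALSE, FALSE, TRUE), rep("library1", 3))
}

test_that("low-count filters drop by total or by group rule, sparing spike-ins", {
  cm <- toy_cm()   # totals 4, 5, 20, 0
  g <- filter_low_counts(cm, "global", min_count = 5)
  expect_setequal(rownames(g$counts), c("G2", "G3", "ERCC-1"))
  gr <- filter_low_counts(cm, "group", min_count = 5, min_samples = 2)
  expect_setequal(rownames(gr$counts), c("G3", "ERCC-1"))  # >=5 in >=2 samples
  expect_error(filter_low_counts(cm, "group", min_samples = 9),
               "exceeds sample count")
  # all-zero gene dropped in both modes (ERCC-1 exempt as spike-in)
  expect_false("G0" %in% rownames(g$counts))
})

test_that("spike-in size factors match the hand median-of-ratios oracle", {
  y <- rbind(`ERCC-1` = c(10, 20), `ERCC-2` = c(40, 80), `ERCC-3` = c(6, 12),
             G1 = c(100, 1))
  colnames(y) <- c("A", "B")
  cm <- count_matrix(y, c(TRUE, TRUE, TRUE, FALSE), c("library1", "library1"))
  f <- estimate_spikein_size_factors(cm)
  # B spike-ins exactly 2x A: factors (2^-0.5, 2^0.5)
  expect_equal(unname(f$factors), c(2^-0.5, 2^0.5), tolerance = 1e-12)
  expect_equal(exp(mean(log(f$factors))), 1, tolerance = 1e-12)
  # doubling every count leaves factors unchanged
  cm2 <- count_matrix(2 * y, cm$is_spikein, cm$library)
  expect_equal(estimate_spikein_size_factors(cm2)$factors, f$factors)
  # identical columns: all factors one
  cm3 <- count_matrix(cbind(A = y[, 1], B = y[, 1]), cm$is_spikein, cm$library)
  expect_equal(unname(estimate_spikein_size_factors(cm3)$factors), c(1, 1))
})

test_that("size factors are equivariant and exclude zero-bearing spike-ins", {
  withr::with_seed(8, {
    y <- matrix(rpois(30 * 6, 60), 30, 6,
                dimnames = list(sprintf("ERCC-%02d", 1:30), paste0("s", 1:6)))
  })
  cm <- count_matrix(y, rep(TRUE, 30), rep("library1", 6))
  f0 <- estimate_spikein_size_factors(cm)
  y2 <- y; y2[, 3] <- y[, 3] * 4
  f1 <- estimate_spikein_size_factors(count_matrix(y2, cm$is_spikein, cm$library))
  # multiplying one column by c multiplies its factor by c (up to the
  # geometric-mean renormalization, a common scalar)
  ratio <- f1$factors / f0$factors
  expect_equal(unname(ratio[3] / ratio[1]), 4, tolerance = 1e-12)
  # spike-in with a zero anywhere leaves the reference, with a log record
  y3 <- y; y3[1, 2] <- 0
  f2 <- estimate_spikein_size_factors(count_matrix(y3, cm$is_spikein, cm$library))
  expect_false("ERCC-01" %in% f2$reference)
})

test_that("offset-log transform matches arithmetic and is scale-invariant", {
  expect_equal(normalize_offset_log(matrix(0, dimnames = list("g", "s")),
                                    factors = 5), matrix(0, dimnames = list("g", "s")))
  m <- matrix(10, dimnames = list("g", "s"))
  expect_equal(unname(normalize_offset_log(m, factors = 2)[1, 1]), log2(6))
  # count and factor both scaled by c: value unchanged
  expect_equal(normalize_offset_log(m * 7, factors = 14),
               normalize_offset_log(m, factors = 2))
  # strictly monotone in counts for a fixed sample
  v <- normalize_offset_log(matrix(c(0, 1, 5, 50), 4,
                                   dimnames = list(letters[1:4], "s")),
                            factors = 1.3)
  expect_true(all(diff(v[, 1]) > 0))
  expect_error(normalize_offset_log(m, factors = -1), "positive")
  expect_error(normalize_offset_log(m, factors = 1, offset = 0), "offset")
})

test_that("library bias correction recovers a planted 2x effect", {
  # 20 samples: the per-gene estimator SE is ~ sqrt(alpha * 2/10) nats, so
  # the +/-0.15 log2 median band needs alpha below ~0.15 at this n
  cm <- make_bias_fixture(n_genes = 400, n_per_lib = 10, log2_bias = 1,
                          seed = 21, alpha = c(0.02, 0.15))
  res <- correct_library_bias(cm, size_factors = list(factors =
    setNames(rep(1, 20), colnames(cm$counts))) |> structure(class = "size_factors"))
  err <- res$bias$log2_bias - 1
  expect_lt(median(abs(err)), 0.15)
  # post-correction library mean-ratio near 1
  yc <- res$counts$counts
  lib2 <- cm$library == "library2"
  ratio <- rowMeans(yc[, lib2]) / rowMeans(yc[, !lib2])
  expect_gt(median(ratio), 0.9)
  expect_lt(median(ratio), 1.1)
  # corrected matrix remains a valid integer count matrix
  expect_true(all(yc >= 0) && max(abs(yc - round(yc))) == 0)
})

test_that("bias correction under a null is quiet and idempotent in expectation", {
  cm <- make_bias_fixture(n_genes = 400, n_per_lib = 24, log2_bias = 0,
                          seed = 22, alpha = c(0.02, 0.1))
  sf <- structure(list(factors = setNames(rep(1, 48), colnames(cm$counts))),
                  class = "size_factors")
  res <- correct_library_bias(cm, sf)
  expect_lt(median(abs(res$bias$log2_bias)), 0.1)
  # re-estimation on corrected counts sits below the estimation noise floor
  res2 <- correct_library_bias(res$counts, sf)
  expect_lt(median(abs(res2$bias$log2_bias)), 0.1)
})

test_that("bias correction edge cases: all-zero gene, single library", {
  cm <- make_bias_fixture(n_genes = 50, n_per_lib = 5, log2_bias = 1, seed = 3)
  y <- cm$counts; y["G0001", ] <- 0
  cm0 <- count_matrix(y, cm$is_spikein, cm$library)
  res <- suppressMessages(correct_library_bias(cm0,
    structure(list(factors = setNames(rep(1, 10), colnames(y))),
              class = "size_factors")))
  i <- res$bias$gene == "G0001"
  expect_false(res$bias$converged[i])
  expect_equal(res$bias$log2_bias[i], 0)
  expect_equal(res$counts$counts["G0001", ], y["G0001", ])
  cm1 <- count_matrix(y, cm$is_spikein, rep("library1", 10))
  expect_warning(r1 <- correct_library_bias(cm1), "identity")
  expect_equal(r1$counts$counts, y)
})
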