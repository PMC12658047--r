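test_that("enrichment score matches the hand examples", {
  rk <- ranked_list(c(g1 = 3, g2 = 2, g3 = 1), "toy")
  e1 <- enrichment_score(rk, "g1")
  expect_equal(e1$es, 1)
  expect_equal(e1$leading_edge, "g1")
  e3 <- enrichment_score(rk, "g3")
  expect_equal(e3$es, -1)
  expect_equal(e3$leading_edge, "g3")
  # degenerate set covering the whole ranking: no miss steps, ES = 1
  expect_equal(enrichment_score(rk, c("g1", "g2", "g3"))$es, 1)
  expect_error(enrichment_score(rk, "absent"), "empty intersection")
})

test_that("streaming ES equals the brute-force running-sum oracle", {
  withr::with_seed(31, {
    for (rep in 1:60) {
      N <- sample(5:60, 1)
      ids <- sprintf("g%02d", 1:N)
      metric <- rnorm(N)
      set <- sample(ids, sample.int(min(N, 12), 1))
      rk <- ranked_list(setNames(metric, ids), "prop")
      expect_equal(enrichment_score(rk, set)$es,
                   oracle_es(metric, ids, set), tolerance = 1e-12)
    }
  })
})

test_that("ES is antisymmetric under ranking reversal", {
  withr::with_seed(32, {
    N <- 40
    metric <- rnorm(N)
    ids <- sprintf("g%02d", 1:N)
    rk <- ranked_list(setNames(metric, ids), "fwd")
    rkr <- ranked_list(setNames(-metric, ids), "rev")
    for (k in c(1, 3, 8, 20)) {
      set <- sample(ids, k)
      expect_equal(enrichment_score(rkr, set)$es,
                   -enrichment_score(rk, set)$es, tolerance = 1e-12)
    }
  })
})

test_that("preranked GSEA respects the smoothing floor and finds planted sets", {
  withr::with_seed(33, {
    N <- 2000
    metric <- rnorm(N)
    ids <- sprintf("g%04d", 1:N)
    names(metric) <- ids
    metric[1:20] <- metric[1:20] + 5   # planted set at the top
    rk <- ranked_list(metric, "synthetic")
    sets <- gene_set_collection(list(
      PLANTED = ids[1:20],
      RANDOM = sample(ids, 30)))
  })
  res <- gsea_preranked(rk, sets, n_perm = 500, seed = 7, max_perm = 500)
  expect_true(all(res$pval >= 1 / 501))
  pl <- res[res$pathway == "PLANTED", ]
  expect_lt(pl$padj, 0.05)
  expect_gt(pl$nes, 0)
  expect_true(all(pl$leading_edge[[1]] %in% ids[1:20]))
  expect_equal(sign(res$nes), sign(res$es))
})

test_that("GSEA p-values are calibrated for random sets", {
  # random set under a random ranking: raw p approximately uniform
  withr::with_seed(34, {
    N <- 300
    ids <- sprintf("g%03d", 1:N)
    pvals <- vapply(1:500, function(i) {
      rk <- ranked_list(setNames(rnorm(N), ids), "null")
      sets <- gene_set_collection(list(S = sample(ids, 15)))
      gsea_preranked(rk, sets, n_perm = 200, seed = i, max_perm = 200)$pval
    }, 0)
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("set-size bounds and universe checks are enforced", {
  rk <- ranked_list(setNames(rnorm(50), sprintf("g%02d", 1:50)), "x")
  sets <- gene_set_collection(list(TINY = c("g01", "g02"),
                                   OK = sprintf("g%02d", 1:10)))
  res <- gsea_preranked(rk, sets, n_perm = 100, min_size = 5, seed = 1,
                        max_perm = 100)
  expect_equal(res$pathway, "OK")
  too_big <- gene_set_collection(list(HUGE = sprintf("h%03d", 1:60)))
  expect_error(gsea_preranked(rk, too_big, n_perm = 100),
               "universe smaller")
})

test_that("direction rule reproduces the reported sign combinations", {
  # PC negatively correlated with PE, negative NES: upregulated in PE
  expect_equal(infer_direction(-2.83, -0.25), "Upregulated")
  expect_equal(infer_direction(-2.26, -0.25), "Upregulated")
  expect_equal(infer_direction(-2.10, -0.25), "Upregulated")
  # PC positively correlated, negative NES: downregulated
  expect_equal(infer_direction(-1.87, 0.30), "Downregulated")
  expect_equal(infer_direction(-2.08, 0.30), "Downregulated")
  # PC positively correlated, positive NES: upregulated
  expect_equal(infer_direction(2.06, 0.30), "Upregulated")
  expect_warning(expect_equal(infer_direction(0, 0.3), "n/a"), "n/a")
})

test_that("z-score matrix is ordered by PC coordinates with unit rows", {
  withr::with_seed(35, {
    m <- matrix(rnorm(12 * 8), 12, 8,
                dimnames = list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:8)))
  })
  p <- run_pca(m)
  zm <- zscore_matrix(m, rownames(m)[1:6], p, "PC1",
                      leading_edge = c("g01", "g03"))
  expect_equal(unname(rowMeans(zm$z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(zm$z, 1, sd)), rep(1, 6), tolerance = 1e-12)
  expect_equal(colnames(zm$z),
               names(sort(p$scores[, "PC1"], decreasing = TRUE)))
  expect_equal(rownames(zm$z),
               names(sort(p$loadings[rownames(m)[1:6], "PC1"],
                          decreasing = TRUE)))
  expect_equal(sum(zm$leading), 2)
  # constant gene: zero row, flagged
  m2 <- m; m2["g02", ] <- 4
  zm2 <- zscore_matrix(m2, rownames(m)[1:6], p, "PC1")
  expect_true(zm2$constant[["g02"]])
  expect_equal(unname(zm2$z["g02", ]), rep(0, 8))
})
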