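test_that("Mann-Whitney AUC matches hand examples and symmetries", {
  # PE {3,4,5} vs NP {1,2,3}: 8.5 of 9 pairs
  r <- auc_mannwhitney(c(3, 4, 5, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$auc, 8.5 / 9)
  # all ties
  expect_equal(auc_mannwhitney(rep(2, 8), rep(c(1, 0), 4))$auc, 0.5)
  # label swap maps AUC to 1 - AUC
  withr::with_seed(51, { s <- rnorm(30); l <- rbinom(30, 1, 0.4) })
  expect_equal(auc_mannwhitney(s, l)$auc, 1 - auc_mannwhitney(s, 1 - l)$auc)
  expect_error(auc_mannwhitney(s, rep(1, 30)), "both classes")
})

test_that("rank-based AUC equals brute-force pair counting, with ties", {
  withr::with_seed(52, {
    for (i in 1:200) {
      n <- sample(6:30, 1)
      s <- sample(1:8, n, replace = TRUE)   # integer scores force ties
      l <- c(rep(1, 2), rep(0, 2), rbinom(n - 4, 1, 0.5))[1:n]
      expect_identical(auc_mannwhitney(s, l)$auc, oracle_auc(s, l))
    }
  })
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(53, { s <- rnorm(40); l <- rbinom(40, 1, 0.3) })
  a <- auc_mannwhitney(s, l)$auc
  expect_equal(auc_mannwhitney(exp(s), l)$auc, a)
  expect_equal(auc_mannwhitney(qlogis(plogis(s)) * 3 + 2, l)$auc, a)
})

test_that("operating point reproduces the exhaustive threshold-scan example", {
  scores <- c(1:10, 4.5, 9.5, 10.5)
  labels <- c(rep(0, 10), rep(1, 3))
  op <- operating_point(scores, labels, fpr = 0.10, n_boot = 0)
  expect_equal(op$sensitivity, 2 / 3)
  expect_equal(op$specificity, 0.9)
  expect_equal(op$threshold, 9)
  # perfectly separated classes
  op2 <- operating_point(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1), n_boot = 0)
  expect_equal(op2$sensitivity, 1)
  expect_equal(op2$specificity, 1)
})

test_that("operating-point sensitivity equals the scan oracle on random data", {
  withr::with_seed(54, {
    for (i in 1:150) {
      n0 <- sample(5:25, 1); n1 <- sample(3:12, 1)
      s <- c(sample(1:12, n0, TRUE), sample(1:12, n1, TRUE) + rnorm(n1, 1))
      l <- c(rep(0, n0), rep(1, n1))
      op <- operating_point(s, l, fpr = 0.10, n_boot = 0)
      expect_identical(op$sensitivity, oracle_sens_at_fpr(s, l, 0.10))
      expect_gte(op$specificity, 0.9)
    }
  })
})

test_that("bootstrap CIs are proper intervals bracketing the estimate", {
  withr::with_seed(55, {
    s <- c(rnorm(39), rnorm(10, 1.6))
    l <- c(rep(0, 39), rep(1, 10))
  })
  op <- operating_point(s, l, fpr = 0.10, n_boot = 500, seed = 9)
  expect_true(all(op$sensitivity_ci >= 0 & op$sensitivity_ci <= 1))
  expect_lte(op$sensitivity_ci[1], op$sensitivity)
  expect_gte(op$sensitivity_ci[2], op$sensitivity)
  expect_true(all(op$accuracy_ci >= 0 & op$accuracy_ci <= 1))
  # deterministic given the seed
  op2 <- operating_point(s, l, fpr = 0.10, n_boot = 500, seed = 9)
  expect_identical(op, op2)
})

test_that("screen orients anti-correlated variables and fills every field", {
  withr::with_seed(56, {
    lab <- c(rep("PE", 10), rep("NP", 39))
    vars <- rbind(
      down_in_pe = c(rnorm(10, -1.4), rnorm(39)),  # higher in NP
      null_var = rnorm(49),
      perfect = c(rep(1, 10), rep(0, 39)))
    colnames(vars) <- sprintf("s%02d", 1:49)
  })
  res <- screen_variables(vars, lab, n_boot = 100, seed = 2)
  expect_equal(nrow(res), 3)
  expect_false(anyNA(res[, c("auc", "auc_lo", "auc_hi", "auc_p",
                             "sensitivity", "specificity", "accuracy")]))
  d <- res[res$variable == "down_in_pe", ]
  expect_gt(d$auc, 0.5)       # oriented score
  expect_true(d$oriented_down)
  p <- res[res$variable == "perfect", ]
  expect_equal(p$auc, 1)
  expect_equal(p$sensitivity, 1)
  expect_true(p$separation)
  expect_true(all(res$auc_lo <= res$auc & res$auc <= res$auc_hi))
})

test_that("candidate filter is strict at 0.65 and sorts by AUC", {
  res <- data.frame(variable = c("a", "b", "c", "d"),
                    auc = c(0.7, 0.9, 0.8, 0.6),
                    sensitivity = c(0.7, 0.66, 0.65, 0.9))
  out <- filter_candidates(res)
  expect_equal(out$variable, c("b", "a", "d"))  # 0.65 exactly excluded
  expect_equal(nrow(filter_candidates(res[0, ])), 0)
})

test_that("Wilcoxon group test: disjoint supports, permutation invariance, ties", {
  withr::with_seed(57, {
    v <- c(rnorm(10) + 100, rnorm(39))   # disjoint supports, n = 10 vs 39
    l <- c(rep(1, 10), rep(0, 39))
  })
  expect_lt(wilcoxon_group_test(v, l), 1e-6)
  perm <- withr::with_seed(2, sample.int(49))
  expect_identical(wilcoxon_group_test(v[perm], l[perm]),
                   wilcoxon_group_test(v, l))
  expect_equal(wilcoxon_group_test(rep(3, 12), rep(c(1, 0), 6)), 1)
})

test_that("planted binormal biomarkers rank at the top of a null screen", {
  # delta = 1.6 (population AUC ~ 0.87) among 2000 null variables, 10 vs 39;
  # 2,000 null variables rather than 5,000 for test budget; same property
  ranks <- vapply(1:5, function(s) {
    withr::with_seed(100 + s, {
      lab <- c(rep(1, 10), rep(0, 39))
      null_vars <- matrix(rnorm(2000 * 49), 2000, 49,
                          dimnames = list(sprintf("N%04d", 1:2000), NULL))
      marker <- rnorm(49) + 1.6 * lab
      vars <- rbind(null_vars, MARKER = marker)
      colnames(vars) <- sprintf("s%02d", 1:49)
    })
    res <- screen_variables(vars, ifelse(lab == 1, "PE", "NP"), n_boot = 0,
                            seed = s)
    rank(-res$auc)[res$variable == "MARKER"] / nrow(res)
  }, 0)
  expect_gte(mean(ranks <= 0.01), 0.8)
})
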