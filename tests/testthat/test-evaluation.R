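test_that("performance indices match hand arithmetic", {
  rep1 <- performance_report(tp = 9, fp = 2, tn = 8, fn = 1, n_boot = 0)
  idx <- setNames(rep1$indices$value, rep1$indices$index)
  expect_equal(idx[["se"]], 0.9)
  expect_equal(idx[["sp"]], 0.8)
  expect_equal(idx[["ppv"]], 9 / 11)
  expect_equal(idx[["npv"]], 8 / 9)
  expect_equal(idx[["acc"]], 0.85)
  expect_equal(idx[["f1"]], 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11),
               tolerance = 1e-12)
  expect_equal(idx[["lr_pos"]], 0.9 / 0.2, tolerance = 1e-12)
  expect_equal(idx[["lr_neg"]], 0.1 / 0.8, tolerance = 1e-12)
  # F1 is exactly the harmonic mean of Se and PPV
  expect_equal(idx[["f1"]], 2 / (1 / idx[["se"]] + 1 / idx[["ppv"]]),
               tolerance = 1e-12)
  # count conservation: se * (tp + fn) returns tp
  expect_equal(idx[["se"]] * 10, 9, tolerance = 1e-15)
})

test_that("degenerate confusion tables flag undefined indices", {
  perf <- performance_report(tp = 10, fp = 0, tn = 10, fn = 0, n_boot = 0)
  idx <- setNames(perf$indices$value, perf$indices$index)
  expect_true(all(idx[c("se", "sp", "ppv", "npv", "f1", "acc")] == 1))
  expect_equal(idx[["lr_neg"]], 0)
  none <- performance_report(tp = 0, fp = 0, tn = 8, fn = 2, n_boot = 0)
  expect_true(all(c("ppv", "f1") %in% none$undefined))
  expect_error(performance_report(tp = 0, fp = 0, tn = 0, fn = 0), "empty")
})

test_that("AUC equals brute-force pair counting", {
  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  # 12-point hand set with ties
  s <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8, 8, 9)
  y <- c(0, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1)
  expect_equal(roc_analysis(s, y)$auc, pair_auc(s, y), tolerance = 1e-12)
  set.seed(120)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    s <- round(rnorm(n), 1)  # induce ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_analysis(s, y)$auc, pair_auc(s, y),
                 tolerance = 1e-12)
  }
})

test_that("ROC extremes behave correctly", {
  expect_equal(roc_analysis(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1))$auc, 1)
  set.seed(121)
  s <- rnorm(2000)
  y <- rbinom(2000, 1, 0.5)
  a <- roc_analysis(s, y)
  expect_gt(a$auc, 0.47)
  expect_lt(a$auc, 0.53)
  expect_true(a$ci[1] <= a$auc && a$auc <= a$ci[2])
  expect_error(roc_analysis(s, rep(1, 2000)), "both outcome classes")
})

test_that("AUC and its interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(122)
  s <- round(rnorm(150), 1)
  y <- rbinom(150, 1, stats::plogis(s))
  a <- roc_analysis(s, y)
  ref <- suppressMessages(pROC::roc(y, s, direction = "<"))
  expect_equal(a$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci_ref <- as.numeric(suppressWarnings(pROC::ci.auc(ref,
                                                     method = "delong")))
  expect_equal(a$ci, ci_ref[c(1, 3)], tolerance = 1e-6)
})

test_that("two-proportion test reproduces printed comparison cells", {
  r1 <- prop_test_2x2(27, 56, 15, 71)
  expect_lt(abs(r1$p1 - 0.482), 1e-3)
  expect_lt(abs(r1$p2 - 0.211), 1e-3)
  expect_lt(max(abs(r1$conf_int - c(0.093, 0.449))), 1e-3)
  r2 <- prop_test_2x2(1, 56, 58, 71)
  expect_lt(abs(r2$p1 - 0.018), 1e-3)
  expect_lt(abs(r2$p2 - 0.817), 1e-3)
  expect_lt(max(abs(r2$conf_int - c(-0.911, -0.687))), 1e-3)
  # no events on either side
  r3 <- prop_test_2x2(0, 56, 0, 71)
  expect_identical(r3$p_value, 1)
  expect_true(all(r3$conf_int >= -1 & r3$conf_int <= 1))
})

test_that("the proportion test is antisymmetric in the groups", {
  a <- prop_test_2x2(27, 56, 15, 71)
  b <- prop_test_2x2(15, 71, 27, 56)
  expect_equal(a$diff, -b$diff)
  expect_equal(a$conf_int, -rev(b$conf_int))
  expect_equal(a$p_value, b$p_value)
})

test_that("Wilcoxon shift equals the median of pairwise differences", {
  r <- wilcoxon_shift(c(1, 2, 3), c(11, 12, 13))
  expect_equal(r$shift_estimate, 10)
  same <- wilcoxon_shift(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$shift_estimate, 0, tolerance = 1e-6)
  expect_equal(same$p_value, 1)
  tied <- wilcoxon_shift(rep(2, 4), rep(2, 5))
  expect_true(tied$degenerate)
  expect_identical(tied$p_value, 1)

  set.seed(130)
  a <- rnorm(8)
  b <- rnorm(8, mean = 1)
  r2 <- wilcoxon_shift(a, b)
  diffs <- as.vector(outer(b, a, "-"))
  expect_equal(r2$shift_estimate, median(diffs), tolerance = 1e-9)
})

test_that("the packaged comparison table reproduces within tolerance", {
  tab <- reproduce_table1()
  expect_identical(nrow(tab), 33L)
  expect_true(attr(tab, "all_pass"))
  expect_lt(max(tab$max_dev), 0.001)
})
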