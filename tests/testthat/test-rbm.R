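test_that("intercept-only model predicts the prevalence", {
  coh <- generate_cohort(seed = 1)
  fit <- fit_rbm(coh, n_boot = 0, predictors = character(0))
  expect_equal(unname(fit$risks), rep(mean(coh$profiles$outcome),
                                      nrow(coh$profiles)),
               tolerance = 1e-8)
})

test_that("predicted risk equals the inverse-logit closed form", {
  m <- rbm_model(c("(Intercept)" = -1.5, short_axis = 0.25,
                   echogenicity = 0.8, nodal_core_sign_absent = 1.1))
  p <- us_profile(short_axis = 9.3, cortical_thickness = 2,
                  echogenicity = 2, nodal_core_sign_absent = 1)
  # echogenicity enters dichotomized: code 2 -> 1
  lp <- -1.5 + 0.25 * 9.3 + 0.8 * 1 + 1.1 * 1
  expect_equal(predict_risk(m, p), stats::plogis(lp), tolerance = 1e-12)

  zero <- rbm_model(c("(Intercept)" = 0, short_axis = 0))
  expect_equal(predict_risk(zero, p), 0.5)
  sat <- rbm_model(c("(Intercept)" = 0, short_axis = 10))
  expect_gt(predict_risk(sat, us_profile(short_axis = 10)), 0.999)
  expect_error(rbm_model(c(bogus = 1)), "bogus")
})

test_that("symmetric data give a centred linear predictor", {
  # mirrored construction: profiles at short_axis x and 20 - x carry
  # flipped outcomes, so the fitted risk at the centre (10) must be 1/2
  set.seed(2)
  n <- 1000
  x <- runif(n, 0, 10)
  prob <- stats::plogis(0.6 * (x - 10))
  y <- rbinom(n, 1, prob)
  prof <- data.frame(short_axis = c(x, 20 - x))
  yy <- c(y, 1L - y)
  base <- us_profile()
  for (f in setdiff(us_feature_names(), "short_axis"))
    prof[[f]] <- base[[f]]
  prof$outcome <- yy
  fit <- fit_rbm(us_cohort(prof), n_boot = 0,
                 predictors = "short_axis")
  lp_centre <- fit$coefficients[["(Intercept)"]] +
    10 * fit$coefficients[["short_axis"]]
  expect_lt(abs(lp_centre), 0.05)
})

test_that("threshold selection matches the exhaustive oracle", {
  # brute-force scan over the same candidate definition, computed
  # independently from confusion counts
  oracle <- function(r, y) {
    u <- sort(unique(r))
    cand <- c(u[1], if (length(u) > 1) (u[-length(u)] + u[-1]) / 2)
    best_f1 <- -1; t_f1 <- NA
    best_mm <- -1; best_sum <- -1; t_mm <- NA
    for (t in cand) {
      tp <- sum(r >= t & y == 1); fp <- sum(r >= t & y == 0)
      fn <- sum(r < t & y == 1); tn <- sum(r < t & y == 0)
      se <- tp / (tp + fn); sp <- tn / (tn + fp)
      f1 <- if (tp == 0) 0 else {
        ppv <- tp / (tp + fp); 2 * se * ppv / (se + ppv)
      }
      if (f1 > best_f1) { best_f1 <- f1; t_f1 <- t }
      mm <- min(se, sp)
      if (mm > best_mm || (mm == best_mm && se + sp > best_sum)) {
        best_mm <- mm; best_sum <- se + sp; t_mm <- t
      }
    }
    c(t_f1 = t_f1, t_sesp = t_mm)
  }
  set.seed(3)
  for (i in 1:25) {
    r <- runif(200)
    y <- rbinom(200, 1, stats::plogis(3 * (r - 0.5)))
    if (length(unique(y)) < 2) next
    expect_identical(select_thresholds(r, y), oracle(r, y))
  }
})

test_that("threshold selection handles separation and null signal", {
  th <- select_thresholds(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(unname(th), c(0.5, 0.5))
  # outcome independent of risk: predict-all-positive maximizes F1
  set.seed(4)
  r <- runif(500)
  y <- rbinom(500, 1, 0.3)
  th2 <- select_thresholds(r, y)
  # the F1 optimum collapses toward predicting everyone positive
  expect_lt(th2[["t_f1"]], stats::quantile(r, 0.1))
  f1_at <- function(t) {
    tp <- sum(r >= t & y == 1)
    2 * tp / (sum(r >= t) + sum(y == 1))
  }
  expect_lt(f1_at(th2[["t_f1"]]) - f1_at(min(r)), 0.02)
  expect_error(select_thresholds(r, rep(1, 500)), "both outcome classes")
})

test_that("risk stratification uses inclusive moderate boundaries", {
  expect_identical(stratify_risk(c(0.22, 0.23, 0.26, 0.29, 0.291)),
                   c("low", "moderate", "moderate", "moderate", "high"))
  m <- rbm_model(c(short_axis = 1), threshold_f1 = 0.4,
                 threshold_sesp = 0.6)
  expect_identical(stratify_risk(0.5, m), "moderate")
  expect_identical(unname(rbm_published_thresholds()), c(0.23, 0.29))
})

test_that("F1 at the F1-optimal threshold dominates", {
  f1_at <- function(r, y, t) {
    tp <- sum(r >= t & y == 1); fp <- sum(r >= t & y == 0)
    fn <- sum(r < t & y == 1)
    if (tp == 0) 0 else {
      se <- tp / (tp + fn); ppv <- tp / (tp + fp)
      2 * se * ppv / (se + ppv)
    }
  }
  set.seed(5)
  for (i in 1:10) {
    r <- runif(150)
    y <- rbinom(150, 1, stats::plogis(2 * (r - 0.4)))
    if (length(unique(y)) < 2) next
    th <- select_thresholds(r, y)
    expect_gte(f1_at(r, y, th[["t_f1"]]) + 1e-12,
               f1_at(r, y, th[["t_sesp"]]))
  }
})

test_that("the fit survives complete separation with a flag", {
  coh <- make_separable_cohort(n = 200, seed = 6)
  fit <- fit_rbm(coh, n_boot = 0, predictors = "short_axis")
  expect_true(fit$separation)
  expect_true(all(fit$risks >= 0 & fit$risks <= 1))
  # still a good classifier
  expect_gt(.5, mean(abs((fit$risks > 0.5) - coh$profiles$outcome)))
})
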