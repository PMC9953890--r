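test_that("feature PPV is the metastatic fraction among positives", {
  prof <- do.call(rbind, replicate(12, us_profile(), simplify = FALSE))
  prof$cortical_interruption <- c(rep(1L, 10), 0L, 0L)
  prof$outcome <- c(rep(1L, 9), 0L, 1L, 0L)
  prof$n_positive_nodes <- prof$outcome
  ppv <- compute_feature_ppv(us_cohort(prof))
  expect_equal(ppv[["cortical_interruption"]], 0.9)
  # never-positive features are undefined, not zero
  expect_true(is.na(ppv[["perinodal_hyperechogenic_ring"]]))
})

test_that("marker extraction thresholds at 0.85 inclusive", {
  expect_identical(extract_markers(c(A = 0.86, B = 0.84)), "A")
  expect_identical(extract_markers(c(A = 0.85)), "A")
  expect_length(extract_markers(c(A = 0.5, B = NA)), 0L)
})

test_that("the calibrated generator yields exactly the three markers", {
  coh <- generate_cohort(n_groins = 20000, seed = 30)
  markers <- extract_markers(compute_feature_ppv(coh))
  expect_setequal(markers, us_marker_names())
})

test_that("the tree root recovers a separating threshold", {
  coh <- make_separable_cohort(n = 400, cut = 8.3, seed = 31)
  tree <- build_tree(coh, n_boot = 0)
  fit <- tree$rpart
  root_var <- as.character(fit$frame$var[1])
  expect_identical(root_var, "short_axis")
  x <- coh$profiles$short_axis
  y <- coh$profiles$outcome
  cut_est <- fit$splits[1, "index"]
  expect_gt(cut_est, max(x[y == 0]))
  expect_lt(cut_est, min(x[y == 1]))

  # exhaustive-scan oracle: weighted Gini over every midpoint cut
  gini_of <- function(cut) {
    g <- function(idx) {
      if (length(idx) == 0) return(0)
      p <- mean(y[idx])
      length(idx) * 2 * p * (1 - p)
    }
    (g(which(x < cut)) + g(which(x >= cut))) / length(y)
  }
  u <- sort(unique(x))
  mids <- (u[-length(u)] + u[-1]) / 2
  best <- mids[which.min(vapply(mids, gini_of, numeric(1)))]
  expect_equal(gini_of(cut_est), gini_of(best), tolerance = 1e-12)
})

test_that("uninformative cohorts collapse to a prevalence leaf", {
  prof <- do.call(rbind, replicate(60, us_profile(), simplify = FALSE))
  set.seed(32)
  prof$outcome <- rbinom(60, 1, 0.3)
  prof$n_positive_nodes <- prof$outcome
  tree <- build_tree(us_cohort(prof), n_boot = 0)
  expect_identical(nrow(tree$leaves), 1L)
  expect_equal(tree$leaves$risk, mean(prof$outcome))
  # pure single-class cohort: one leaf labelled by that class
  prof$outcome <- 1L
  prof$n_positive_nodes <- 1L
  pure <- build_tree(us_cohort(prof), n_boot = 0)
  expect_identical(pure$leaves$label, "HMR")
})

test_that("leaves are labelled HMR/MMR/LMR by descending risk", {
  coh <- generate_cohort(n_groins = 2000, seed = 33)
  dt <- fit_signature_model(coh, n_boot = 0)
  lv <- dt$tree$leaves
  expect_lte(nrow(lv), 3L)
  expect_identical(lv$label, c("HMR", "MMR", "LMR")[seq_len(nrow(lv))])
  expect_true(all(diff(lv$risk) <= 0))
})

test_that("marker screen and escalation drive signature assignment", {
  m <- make_stub_signature_model()
  one <- us_profile(cortical_interruption = 1)
  r1 <- assign_signature(m, one)
  expect_identical(r1$signature, "MET")
  expect_true(r1$point_risk >= 0.86 && r1$point_risk <= 0.90)

  two <- us_profile(nodal_core_sign_absent = 1,
                    perinodal_hyperechogenic_ring = 1)
  r2 <- assign_signature(m, two)
  expect_identical(r2$signature, "MET")
  expect_equal(r2$point_risk, 1.00)

  # no markers, MMR leaf, three positive covariates -> escalated risk
  esc <- us_profile(vfa_pattern = 4, shape = 3, echogenicity = 2)
  r3 <- assign_signature(m, esc)
  expect_identical(r3$signature, "MMR")
  expect_true(r3$escalated)
  expect_equal(r3$point_risk, 0.55)
  expect_equal(c(r3$lo, r3$hi), c(0.46, 0.64))

  # one positive covariate is not enough to escalate
  r4 <- assign_signature(m, us_profile(echogenicity = 2))
  expect_false(r4$escalated)
  expect_equal(r4$point_risk, 0.16)

  # MET depends only on the marker block
  r5 <- assign_signature(m, us_profile(cortical_interruption = 1,
                                       vfa_pattern = 4, shape = 3))
  expect_identical(r5$signature, "MET")
})

test_that("trained signature risks are strictly ordered", {
  for (s in 1:3) {
    coh <- generate_cohort(n_groins = 2000, seed = 40 + s)
    dt <- fit_signature_model(coh, risk_source = "trained", n_boot = 0)
    rk <- dt$signature_risk
    risk_of <- function(sig) rk$risk[rk$signature == sig]
    expect_gt(risk_of("MET_multi"), risk_of("HMR"))
    expect_gt(risk_of("MET_single"), risk_of("HMR"))
    expect_gt(risk_of("HMR"), risk_of("MMR"))
    expect_gt(risk_of("MMR"), risk_of("LMR"))
    if (!is.na(risk_of("MMR_escalated"))) {
      expect_gt(risk_of("MMR_escalated"), risk_of("MMR"))
      expect_lt(risk_of("MMR_escalated"), risk_of("HMR"))
    }
  }
})

test_that("MET groins carry more multi-node disease than HMR", {
  coh <- generate_cohort(n_groins = 20000, seed = 50)
  dt <- fit_signature_model(coh, n_boot = 0)
  sig <- assign_signature(dt, coh$profiles)$signature
  multi <- coh$profiles$n_positive_nodes > 1
  met_pos <- sig == "MET" & coh$profiles$outcome == 1
  hmr_pos <- sig == "HMR" & coh$profiles$outcome == 1
  expect_gt(mean(multi[met_pos]), mean(multi[hmr_pos]))
})

test_that("tree JSON export round-trips structure", {
  coh <- generate_cohort(n_groins = 1000, seed = 60)
  dt <- fit_signature_model(coh, n_boot = 0)
  f <- tempfile(fileext = ".json")
  export_tree_json(dt, f)
  obj <- jsonlite::read_json(f)
  expect_setequal(unlist(obj$markers), dt$markers)
  leaves <- Filter(function(nd) isTRUE(nd$leaf), obj$tree)
  expect_identical(length(leaves), nrow(dt$tree$leaves))
})
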