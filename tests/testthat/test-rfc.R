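test_that("stratified 5-subset split balances sizes and classes", {
  coh <- generate_cohort(seed = 1)
  coh <- split_subsets(coh, seed = 2)
  sizes <- sort(tabulate(coh$partition, 5L), decreasing = TRUE)
  expect_identical(sizes, c(48L, 48L, 47L, 47L, 47L))
  # same seed, same partition
  coh2 <- split_subsets(generate_cohort(seed = 1), seed = 2)
  expect_identical(coh$partition, coh2$partition)

  # minimal stratified case: 10 groins, 5 positives -> 1 positive each
  prof <- generate_cohort(n_groins = 10, seed = 3)$profiles
  prof$outcome <- rep(c(0L, 1L), 5)
  prof$n_positive_nodes <- prof$outcome
  small <- split_subsets(us_cohort(prof), seed = 4)
  pos_per <- tapply(prof$outcome, small$partition, sum)
  expect_true(all(pos_per == 1))
})

test_that("each member trains on four subsets and is reproducible", {
  coh <- split_subsets(generate_cohort(seed = 5), seed = 6)
  ens <- train_ensemble(coh, seed = 7, ntree = 150, tune = FALSE)
  expect_length(ens$members, 5L)
  train_sizes <- vapply(1:5, function(v) sum(coh$partition != v),
                        integer(1))
  forest_n <- vapply(ens$members, function(m) length(m$y), integer(1))
  expect_identical(forest_n, train_sizes)
  expect_true(all(train_sizes %in% 189:190))

  ens2 <- train_ensemble(coh, seed = 7, ntree = 150, tune = FALSE)
  expect_identical(ens$held_out, ens2$held_out)
})

test_that("a separable threshold rule is learned perfectly", {
  coh <- split_subsets(make_separable_cohort(n = 500, seed = 8), seed = 9)
  ens <- train_ensemble(coh, seed = 10, ntree = 300, tune = FALSE)
  expect_true(all(ens$held_out_accuracy == 1.0))
  far_pos <- us_profile(short_axis = 20, cortical_thickness = 3)
  far_neg <- us_profile(short_axis = 3, cortical_thickness = 3)
  expect_identical(predict_vote(ens, far_pos)$label, 1L)
  expect_identical(predict_vote(ens, far_neg)$label, 0L)
})

test_that("majority vote is the 3-of-5 rule and monotone", {
  coh <- split_subsets(make_separable_cohort(n = 300, seed = 11),
                       seed = 12)
  ens <- train_ensemble(coh, seed = 13, ntree = 150, tune = FALSE)
  res <- predict_vote(ens, coh$profiles[1:20, ])
  expect_identical(res$label, as.integer(rowSums(res$votes) >= 3L))
  expect_identical(dim(res$votes), c(20L, 5L))
})

test_that("feature ranking isolates a single informative feature", {
  coh <- make_separable_cohort(n = 400, seed = 14)
  coh <- split_subsets(coh, seed = 15)
  ens <- train_ensemble(coh, seed = 16, ntree = 300, tune = FALSE)
  rk <- ens$ranking
  expect_identical(rk$feature[1], "short_axis")
  expect_equal(rk$score[1], 1.0)
  expect_true(all(rk$score >= 0 & rk$score <= 1))
  expect_identical(nrow(rk), 14L)
})

test_that("size features rank high on calibrated cohorts", {
  coh <- split_subsets(generate_cohort(n_groins = 1000, seed = 17),
                       seed = 18)
  ens <- train_ensemble(coh, seed = 19, ntree = 300, tune = FALSE)
  rk <- ens$ranking
  # the two size measurements sit in the upper half of the ranking and
  # dominate the ordinal morphology block (the clean binary markers may
  # outrank them on synthetic cohorts; see the methods vignette)
  pos <- match(c("short_axis", "cortical_thickness"), rk$feature)
  expect_true(all(pos <= 6))
  ord_scores <- rk$score[rk$feature %in% setdiff(us_covariate_names(),
                                                 "focal_intranodal_deposit")]
  expect_true(all(rk$score[pos] > ord_scores))
})

test_that("degenerate cohorts are rejected", {
  prof <- generate_cohort(n_groins = 20, seed = 20)$profiles
  prof$outcome <- 0L
  prof$n_positive_nodes <- 0L
  expect_error(split_subsets(us_cohort(prof)), "both outcome classes")
  coh <- generate_cohort(n_groins = 50, seed = 21)
  coh$profiles$cmid[1] <- NA
  expect_error(train_ensemble(us_cohort(coh$profiles, strict = FALSE)),
               "impute_missing")
})
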