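#' Partition a cohort into five stratified random subsets
#'
#' Splits a labelled cohort into 5 disjoint subsets of near-equal size
#' (difference at most 1), stratified by outcome, for the nested
#' cross-validation of the random-forest ensemble.
#'
#' @param cohort Labelled \code{\link{us_cohort}} with n >= 10.
#' @param seed Integer seed; the same seed reproduces the partition.
#' @return The cohort with its \code{partition} slot set (integer 1..5 per
#'   profile).
#' @examples
#' coh <- generate_cohort(seed = 1)
#' coh <- split_subsets(coh, seed = 2)
#' table(coh$partition)
#' @export
split_subsets <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "us_cohort"))
  y <- .outcomes(cohort)
  if (length(y) < 10L) stop("cohort must have at least 10 profiles")
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present for a stratified split")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  part <- integer(length(y))
  totals <- integer(5L)
  for (cls in c(1L, 0L)) {
    idx <- sample(which(y == cls))
    n_c <- length(idx)
    base <- n_c %/% 5L
    extra <- n_c %% 5L
    sizes <- rep(base, 5L)
    if (extra > 0L) {
      # give the leftover members to the currently smallest folds
      ord <- order(totals, seq_len(5L))
      sizes[ord[seq_len(extra)]] <- base + 1L
    }
    fold <- rep.int(seq_len(5L), sizes)
    part[idx] <- fold
    totals <- totals + sizes
  }
  cohort$partition <- part
  cohort
}

#' Train the five-member random-forest ensemble
#'
#' Nested cross-validation over the cohort's 5-subset partition: for each
#' left-out subset, one random-forest member is trained on the remaining
#' four subsets (with an internal 4-fold cross-validation over those
#' subsets to choose the features-per-split parameter) and evaluated on
#' the left-out subset. Majority vote over the five members gives the
#' ensemble prediction (\code{\link{predict_vote}}).
#'
#' @param cohort Labelled \code{\link{us_cohort}}; partitioned with
#'   \code{\link{split_subsets}} (done automatically otherwise). All 14
#'   modelling features must be complete.
#' @param seed Master integer seed; all forest and tuning randomness
#'   derives from it.
#' @param ntree Trees per member forest (default 500).
#' @param mtry_grid Candidate features-per-split values tuned by the
#'   internal cross-validation (default c(2, 3, 5, 7)).
#' @param tune If FALSE, skip tuning and use \code{floor(sqrt(14))}.
#' @param classwt Optional class weights (\code{c("0" = w0, "1" = w1)});
#'   none by default.
#' @return Object of class \code{rfc_ensemble}: members, their held-out
#'   confusion matrices and accuracies, the subset assignment, and the
#'   feature ranking (see \code{\link{rank_features}}).
#' @export
train_ensemble <- function(cohort, seed = 1L, ntree = 500L,
                           mtry_grid = c(2L, 3L, 5L, 7L), tune = TRUE,
                           classwt = NULL) {
  stopifnot(inherits(cohort, "us_cohort"))
  y <- .outcomes(cohort)
  feats <- us_feature_names()
  X <- cohort$profiles[feats]
  if (anyNA(X))
    stop("cohort has missing features; run impute_missing() first")
  if (is.null(cohort$partition)) cohort <- split_subsets(cohort, seed = seed)
  part <- cohort$partition

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max, 5L)

  yf <- factor(y, levels = c(0L, 1L))
  members <- vector("list", 5L)
  held_out <- vector("list", 5L)
  acc <- numeric(5L)
  mtry_used <- integer(5L)
  for (v in seq_len(5L)) {
    set.seed(member_seeds[v])
    tr <- which(part != v)
    te <- which(part == v)
    mtry <- max(1L, floor(sqrt(length(feats))))
    if (tune && length(mtry_grid) > 1L) {
      inner_folds <- setdiff(seq_len(5L), v)
      cv_err <- vapply(mtry_grid, function(m) {
        errs <- vapply(inner_folds, function(g) {
          itr <- which(part != v & part != g)
          ite <- which(part == g)
          fit <- randomForest::randomForest(
            x = X[itr, , drop = FALSE], y = yf[itr],
            ntree = max(150L, ntree %/% 3L), mtry = m, classwt = classwt)
          mean(stats::predict(fit, X[ite, , drop = FALSE]) != yf[ite])
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      mtry <- mtry_grid[which.min(cv_err)]
    }
    fit <- randomForest::randomForest(
      x = X[tr, , drop = FALSE], y = yf[tr], ntree = ntree, mtry = mtry,
      importance = TRUE, classwt = classwt)
    pred <- stats::predict(fit, X[te, , drop = FALSE])
    cm <- table(predicted = factor(pred, levels = c(0, 1)),
                observed = factor(yf[te], levels = c(0, 1)))
    members[[v]] <- fit
    held_out[[v]] <- cm
    acc[v] <- sum(diag(cm)) / sum(cm)
    mtry_used[v] <- mtry
  }
  ens <- structure(list(members = members, subset_assignment = part,
                        held_out = held_out, held_out_accuracy = acc,
                        mtry = mtry_used, seed = seed),
                   class = "rfc_ensemble")
  ens$ranking <- rank_features(ens)
  ens
}

#' @export
print.rfc_ensemble <- function(x, ...) {
  cat("Random-forest majority-vote ensemble: 5 members\n")
  cat("Held-out accuracy per member:",
      paste(sprintf("%.3f", x$held_out_accuracy), collapse = ", "), "\n")
  cat("Top-ranked features:",
      paste(utils::head(x$ranking$feature, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Majority-vote prediction
#'
#' Each of the five ensemble members casts a binary vote; the predicted
#' label is 1 (metastatic) when at least three members vote 1.
#'
#' @param ensemble A trained \code{rfc_ensemble}.
#' @param profiles Complete profile data.frame (one or more rows).
#' @return List with \code{label} (integer vector) and \code{votes}
#'   (n x 5 integer matrix, one column per member).
#' @export
predict_vote <- function(ensemble, profiles) {
  stopifnot(inherits(ensemble, "rfc_ensemble"))
  X <- as.data.frame(profiles)[us_feature_names()]
  if (anyNA(X))
    stop("profile has missing features; run impute_missing() first")
  votes <- vapply(ensemble$members, function(m)
    as.integer(as.character(stats::predict(m, X))),
    integer(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X), ncol = 5L)
  list(label = as.integer(rowSums(votes) >= 3L), votes = votes)
}

#' Ensemble feature ranking
#'
#' Permutation importance (mean decrease in accuracy) and impurity
#' importance (mean decrease in Gini) are averaged over the five members,
#' each index is min-max normalized to [0,1] across the 14 features, and
#' the two normalized indices are averaged. Output is sorted by
#' descending score, ties broken lexicographically by feature name.
#'
#' @param ensemble A trained \code{rfc_ensemble}.
#' @return Data.frame with columns \code{feature}, \code{score},
#'   \code{mda_norm}, \code{mdg_norm}.
#' @export
rank_features <- function(ensemble) {
  stopifnot(inherits(ensemble, "rfc_ensemble"))
  imp <- lapply(ensemble$members, randomForest::importance)
  mda <- rowMeans(vapply(imp, function(m) m[, "MeanDecreaseAccuracy"],
                         numeric(nrow(imp[[1]]))))
  mdg <- rowMeans(vapply(imp, function(m) m[, "MeanDecreaseGini"],
                         numeric(nrow(imp[[1]]))))
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1]) / diff(rng)
  }
  mda_n <- norm01(mda)
  mdg_n <- norm01(mdg)
  out <- data.frame(feature = names(mda), score = (mda_n + mdg_n) / 2,
                    mda_norm = mda_n, mdg_norm = mdg_n,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature), ]
  rownames(out) <- NULL
  out
}
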