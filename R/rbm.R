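#' Published malignancy-risk thresholds
#'
#' The two fixed risk cut-offs shipped for inference mode: 0.23 (maximum
#' F1 score) and 0.29 (maximum joint sensitivity/specificity). Groins are
#' stratified as low (< 0.23), moderate (0.23--0.29 inclusive) and high
#' (> 0.29) malignancy risk. Retraining recomputes both from data via
#' \code{\link{select_thresholds}}.
#'
#' @return Named numeric vector \code{c(f1 = 0.23, sesp = 0.29)}.
#' @export
rbm_published_thresholds <- function() c(f1 = 0.23, sesp = 0.29)

#' Construct a binomial risk model from known coefficients
#'
#' Builds an \code{rbm_model} directly from a coefficient vector, e.g. for
#' scoring with externally estimated parameters. Coefficients are on the
#' logit scale; \code{"(Intercept)"} is optional and defaults to 0.
#'
#' @param coefficients Named numeric vector; names are modelling features
#'   (any subset) plus optionally \code{"(Intercept)"}.
#' @param threshold_f1,threshold_sesp Risk thresholds (defaults: the
#'   published 0.23 / 0.29).
#' @return Object of class \code{rbm_model}.
#' @export
rbm_model <- function(coefficients,
                      threshold_f1 = rbm_published_thresholds()[["f1"]],
                      threshold_sesp = rbm_published_thresholds()[["sesp"]]) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  feats <- setdiff(names(coefficients), "(Intercept)")
  bad <- setdiff(feats, us_feature_names())
  if (length(bad) > 0L)
    stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  if (!"(Intercept)" %in% names(coefficients))
    coefficients <- c("(Intercept)" = 0, coefficients)
  structure(list(coefficients = coefficients, predictors = feats,
                 threshold_f1 = threshold_f1,
                 threshold_sesp = threshold_sesp,
                 bootstrap_ci = NULL, separation = FALSE),
            class = "rbm_model")
}

# Firth bias-reduced logistic regression by adjusted-score IWLS; used as
# the documented fallback when the ML fit shows (quasi-)separation.
.firth_logit <- function(X, y, max_iter = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    h <- rowSums((XW %*% solve(XtWX)) * XW)  # hat diagonal
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- solve(XtWX, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# single binomial fit with separation detection and Firth fallback;
# returns list(coef, separated)
.fit_binomial <- function(X, y) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  if (sep || !fit$converged || any(is.na(beta)) || max(abs(beta)) > 15) {
    beta <- .firth_logit(X, y)
    sep <- TRUE
  }
  names(beta) <- colnames(X)
  list(coef = beta, separated = sep)
}

#' Fit the binomial regression risk model
#'
#' Maximum-likelihood binomial GLM (logit link) of the metastatic outcome
#' on the dichotomized categorical block plus the raw continuous features.
#' Under complete or quasi-complete separation the fit falls back to
#' Firth's bias-reduced estimator and the model is flagged. Percentile 95%
#' confidence intervals per coefficient come from a nonparametric
#' bootstrap resampling groins. The two risk thresholds (F1-maximizing and
#' joint sensitivity/specificity-maximizing) are estimated from the
#' training risks via \code{\link{select_thresholds}}.
#'
#' @param cohort Labelled, complete \code{\link{us_cohort}}.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param predictors Modelling features to use (default all 14); an empty
#'   character vector fits the intercept-only model, whose fitted risk is
#'   the prevalence.
#' @return Object of class \code{rbm_model} with elements
#'   \code{coefficients}, \code{bootstrap_ci} (2 x p matrix),
#'   \code{threshold_f1}, \code{threshold_sesp}, \code{separation} flag
#'   and training \code{risks}.
#' @export
fit_rbm <- function(cohort, n_boot = 2000L, seed = 1L,
                    predictors = us_feature_names()) {
  stopifnot(inherits(cohort, "us_cohort"))
  y <- .outcomes(cohort)
  D <- dichotomize(cohort$profiles)
  X <- cbind("(Intercept)" = 1, as.matrix(D[predictors]))
  base <- .fit_binomial(X, y)

  ci <- NULL
  if (n_boot > 0L) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    boots <- matrix(NA_real_, n_boot, ncol(X),
                    dimnames = list(NULL, colnames(X)))
    n <- length(y)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2L) next  # degenerate resample
      boots[b, ] <- .fit_binomial(X[idx, , drop = FALSE], y[idx])$coef
    }
    ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
  }

  model <- rbm_model(base$coef)
  model$separation <- base$separated
  model$bootstrap_ci <- ci
  model$risks <- stats::plogis(drop(X %*% base$coef))
  if (length(unique(y)) == 2L) {
    th <- select_thresholds(model$risks, y)
    model$threshold_f1 <- th[["t_f1"]]
    model$threshold_sesp <- th[["t_sesp"]]
  }
  model
}

#' @export
print.rbm_model <- function(x, ...) {
  cat("Binomial regression risk model\n")
  cat(sprintf("  %d predictor(s)%s\n", length(x$predictors),
              if (x$separation) " [separation: bias-reduced fit]" else ""))
  cat(sprintf("  thresholds: F1-optimal %.3f, Se/Sp-optimal %.3f\n",
              x$threshold_f1, x$threshold_sesp))
  invisible(x)
}

#' Predict malignancy risk
#'
#' Inverse-logit of the linear predictor under the model's stored
#' dichotomized encoding.
#'
#' @param model An \code{rbm_model}.
#' @param profiles Complete profile data.frame (one or more rows).
#' @return Numeric vector of risks in [0,1].
#' @export
predict_risk <- function(model, profiles) {
  stopifnot(inherits(model, "rbm_model"))
  D <- dichotomize(profiles)
  missing_pred <- setdiff(model$predictors, names(D))
  if (length(missing_pred) > 0L)
    stop("encoding mismatch; profile lacks predictor(s): ",
         paste(missing_pred, collapse = ", "))
  X <- cbind(1, as.matrix(D[model$predictors]))
  beta <- model$coefficients[c("(Intercept)", model$predictors)]
  stats::plogis(drop(X %*% beta))
}

#' Select the two risk thresholds
#'
#' Scans candidate cut-offs (the midpoints of the sorted unique risks,
#' plus the smallest risk itself so that a predict-all-positive rule is
#' attainable) for two optima on the rule "predict metastatic when risk >=
#' t": the cut-off maximizing the F1 score, and the cut-off maximizing the
#' smaller of sensitivity and specificity (ties broken by larger Se + Sp,
#' then by lower t). F1 ties are broken by lower t. F1 is defined as 0
#' when no true positives are predicted.
#'
#' @param risks Numeric vector of predicted risks.
#' @param outcomes Binary outcome vector of equal length, both classes
#'   present.
#' @param sesp_rule \code{"maxmin"} (default) maximizes min(Se, Sp);
#'   \code{"youden"} maximizes Se + Sp - 1.
#' @return Named numeric vector \code{c(t_f1, t_sesp)}.
#' @examples
#' select_thresholds(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))  # both 0.5
#' @export
select_thresholds <- function(risks, outcomes,
                              sesp_rule = c("maxmin", "youden")) {
  sesp_rule <- match.arg(sesp_rule)
  stopifnot(length(risks) == length(outcomes))
  outcomes <- as.integer(outcomes)
  if (length(unique(outcomes)) < 2L)
    stop("both outcome classes must be present")
  u <- sort(unique(risks))
  cand <- c(u[1], if (length(u) > 1L) (u[-length(u)] + u[-1]) / 2)
  n_pos <- sum(outcomes == 1L)
  n_neg <- sum(outcomes == 0L)
  stats_at <- function(t) {
    pred <- risks >= t
    tp <- sum(pred & outcomes == 1L)
    fp <- sum(pred & outcomes == 0L)
    se <- tp / n_pos
    sp <- (n_neg - fp) / n_neg
    ppv <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    f1 <- if (tp > 0L) 2 * se * ppv / (se + ppv) else 0
    c(f1 = f1, se = se, sp = sp)
  }
  m <- vapply(cand, stats_at, numeric(3))
  t_f1 <- cand[which.max(m["f1", ])]
  crit <- if (sesp_rule == "maxmin") pmin(m["se", ], m["sp", ]) else
    m["se", ] + m["sp", ] - 1
  best <- which(crit == max(crit))
  if (length(best) > 1L) {
    sesp_sum <- m["se", best] + m["sp", best]
    best <- best[sesp_sum == max(sesp_sum)]
    best <- best[1]  # candidates sorted ascending: lowest t
  }
  c(t_f1 = t_f1, t_sesp = cand[best])
}

#' Stratify a malignancy risk into three tiers
#'
#' Low when the risk is below the F1-optimal threshold, moderate between
#' the two thresholds (both boundaries inclusive), high above the joint
#' sensitivity/specificity threshold.
#'
#' @param r Numeric risk(s) in [0,1].
#' @param model An \code{rbm_model}, or a numeric length-2 vector of
#'   thresholds \code{c(f1, sesp)}; defaults to the published 0.23 / 0.29.
#' @return Character vector: \code{"low"}, \code{"moderate"} or
#'   \code{"high"}.
#' @examples
#' stratify_risk(c(0.22, 0.23, 0.29, 0.291))
#' @export
stratify_risk <- function(r, model = rbm_published_thresholds()) {
  if (inherits(model, "rbm_model"))
    th <- c(model$threshold_f1, model$threshold_sesp)
  else th <- unname(as.numeric(model)[1:2])
  stopifnot(all(r >= 0 & r <= 1, na.rm = TRUE))
  ifelse(r < th[1], "low", ifelse(r <= th[2], "moderate", "high"))
}
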