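#' Logistic loss
#'
#' Cross-entropy between a binary label and a predicted probability,
#' \eqn{L = -(y \ln p + (1-y) \ln(1-p))}, natural log, with p clipped to
#' \eqn{[\epsilon, 1-\epsilon]}, \eqn{\epsilon = 10^{-15}}. Used to
#' measure the divergence between the random-forest label and the binomial
#' risk estimate: the larger the disagreement, the larger the loss.
#'
#' @param y Binary label(s) 0/1.
#' @param p Predicted probability (vector recycled against y).
#' @param eps Clipping bound (default 1e-15).
#' @return Non-negative numeric vector.
#' @examples
#' logistic_loss(1, 0.5)   # ln 2
#' logistic_loss(1, 0.99)  # -ln 0.99
#' @export
logistic_loss <- function(y, p, eps = 1e-15) {
  stopifnot(all(y %in% c(0, 1)))
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Calibrate the prediction-error model
#'
#' Fits the parametric reliability model \eqn{E = b_0 + bL} on a labelled
#' cohort with trained modules. Per groin, the observed error is the Brier
#' score \eqn{(p - \mathrm{outcome})^2} of the binomial risk estimate p;
#' the baseline term \eqn{b_0[s]} is the mean observed error within each
#' signature group s (MET, HMR, MMR, LMR); the slope b is the
#' least-squares (through-the-origin) coefficient of the residual observed
#' error \eqn{(\mathrm{Brier} - b_0[s])} on the logistic loss L between
#' the random-forest label y and p. A negative slope would reward
#' disagreement between the modules, so b is clamped at 0 (and flagged).
#'
#' @param cohort Labelled, complete \code{\link{us_cohort}}.
#' @param rfc Trained \code{rfc_ensemble}.
#' @param rbm Trained \code{rbm_model}.
#' @param dt Trained \code{signature_model}.
#' @param cutoff Reliability threshold on E (default 1).
#' @return Object of class \code{error_model}: \code{b0} (named numeric,
#'   one entry per signature), \code{b}, \code{cutoff}, and \code{flags}
#'   (empty signature groups filled with the global mean; negative slope
#'   clamped).
#' @export
calibrate_error_model <- function(cohort, rfc, rbm, dt, cutoff = 1) {
  stopifnot(inherits(cohort, "us_cohort"), cutoff > 0)
  y_obs <- .outcomes(cohort)
  prof <- cohort$profiles
  p <- predict_risk(rbm, prof)
  y_rfc <- predict_vote(rfc, prof)$label
  sig <- assign_signature(dt, prof)$signature

  brier <- (p - y_obs)^2
  L <- logistic_loss(y_rfc, p)

  groups <- c("MET", "HMR", "MMR", "LMR")
  flags <- character(0)
  b0 <- vapply(groups, function(s) {
    inb <- sig == s
    if (!any(inb)) NA_real_ else mean(brier[inb])
  }, numeric(1))
  if (anyNA(b0)) {
    flags <- c(flags, paste0("empty signature group(s): ",
                             paste(groups[is.na(b0)], collapse = ", "),
                             "; b0 set to global mean"))
    b0[is.na(b0)] <- mean(brier)
  }
  resid <- brier - b0[sig]
  b <- if (sum(L^2) > 0) sum(resid * L) / sum(L^2) else 0
  if (b < 0) {
    flags <- c(flags, "unconstrained slope negative; clamped to 0")
    b <- 0
  }
  structure(list(b0 = b0, b = b, cutoff = cutoff, flags = flags),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("Prediction-error model E = b0[signature] + b * L\n")
  cat("  b0:", paste(sprintf("%s %.4f", names(x$b0), x$b0),
                     collapse = ", "), "\n")
  cat(sprintf("  b: %.4f   reliability cutoff: %.2f\n", x$b, x$cutoff))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Prediction error and reliability flag
#'
#' Evaluates \eqn{E = b_0[\mathrm{signature}] + b \cdot L(y, p)} for a new
#' prediction, where y is the random-forest label and p the binomial risk
#' estimate. Predictions with E at or above the cutoff (default 1) should
#' not be considered feasible and are flagged unreliable.
#'
#' @param model A calibrated \code{error_model}.
#' @param y Random-forest predicted label(s) 0/1.
#' @param p Binomial risk estimate(s).
#' @param signature Signature(s): \code{"MET"}, \code{"HMR"},
#'   \code{"MMR"} or \code{"LMR"}.
#' @return List with numeric \code{E} and logical \code{reliable}.
#' @export
prediction_error <- function(model, y, p, signature) {
  stopifnot(inherits(model, "error_model"))
  bad <- setdiff(unique(signature), names(model$b0))
  if (length(bad) > 0L)
    stop("unknown signature(s): ", paste(bad, collapse = ", "))
  E <- unname(model$b0[signature] + model$b * logistic_loss(y, p))
  list(E = E, reliable = E < model$cutoff)
}
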