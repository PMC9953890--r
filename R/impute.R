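#' Impute missing features of a profile
#'
#' Fills missing modelling features of a single profile using a complete,
#' labelled reference cohort. Continuous features (mm) are imputed by an
#' L1-penalized (LASSO) linear regression on the remaining 13 features,
#' with the penalty weight chosen by 5-fold cross-validation and the final
#' coefficients refitted by ordinary least squares on the selected support
#' (relaxed LASSO). Categorical/binary features are imputed by the
#' predicted class of a classification tree grown on the reference.
#'
#' Missing features of "Necessary" or "Very high" priority degrade the
#' downstream prediction disproportionately; imputing them attaches a
#' warning to the returned profile.
#'
#' @param reference A complete \code{\link{us_cohort}} (no missing
#'   modelling features).
#' @param profile One-row data.frame with at least one missing modelling
#'   feature.
#' @param seed Integer seed for the cross-validation folds.
#' @return The completed profile, with attributes \code{imputed} (character
#'   vector of filled fields) and, when a high-priority feature was filled,
#'   \code{imputation_warning}.
#' @examples
#' ref <- generate_cohort(n_groins = 300, seed = 1)
#' p <- us_profile(short_axis = 9, cortical_thickness = 3)
#' p$color_score <- NA
#' impute_missing(ref, p)
#' @export
impute_missing <- function(reference, profile, seed = 1L) {
  stopifnot(inherits(reference, "us_cohort"))
  info <- us_features()
  ref <- reference$profiles[info$feature]
  if (anyNA(ref))
    stop("reference cohort must be complete")
  profile <- as.data.frame(profile)
  for (f in setdiff(info$feature, names(profile))) profile[[f]] <- NA_real_
  x <- unlist(profile[1, info$feature])
  miss <- info$feature[is.na(x)]
  if (length(miss) == 0L)
    stop("profile has no missing modelling feature")
  if (length(miss) == nrow(info))
    stop("all modelling features missing; nothing to condition on")

  obs <- setdiff(info$feature, miss)
  for (f in miss) {
    type <- info$type[info$feature == f]
    X <- as.matrix(ref[obs])
    newx <- matrix(as.numeric(x[obs]), nrow = 1,
                   dimnames = list(NULL, obs))
    if (type == "continuous") {
      set.seed(seed)
      cv <- glmnet::cv.glmnet(X, ref[[f]], nfolds = 5L, alpha = 1)
      beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
      support <- obs[beta[-1] != 0]
      # relaxed refit: OLS on the LASSO-selected support removes the
      # shrinkage bias of the penalized coefficients
      if (length(support) > 0L) {
        fit <- stats::lm(stats::reformulate(support, response = f),
                         data = ref)
        val <- as.numeric(stats::predict(fit, profile[1, obs, drop = FALSE]))
      } else {
        val <- mean(ref[[f]])
      }
      val <- max(val, 0)
    } else if (length(unique(ref[[f]])) == 1L) {
      val <- ref[[f]][1]  # constant feature: the majority class trivially
    } else {
      dat <- ref[c(f, obs)]
      dat[[f]] <- factor(dat[[f]])
      fit <- rpart::rpart(stats::reformulate(obs, response = f),
                          data = dat, method = "class")
      cls <- stats::predict(fit, profile[1, obs, drop = FALSE],
                            type = "class")
      val <- as.numeric(as.character(cls))
    }
    profile[[f]] <- val
  }
  attr(profile, "imputed") <- miss
  high <- miss[info$priority[match(miss, info$feature)] %in%
                 c("Necessary", "Very high")]
  if (length(high) > 0L) {
    msg <- paste0("imputed high-priority feature(s): ",
                  paste(high, collapse = ", "),
                  "; prediction error will be inflated")
    attr(profile, "imputation_warning") <- msg
    warning(msg, call. = FALSE)
  }
  profile
}
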