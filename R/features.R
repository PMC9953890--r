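#' Ultrasound feature code book
#'
#' Metadata for the 14 modelling features of a groin ultrasound profile:
#' feature type, legal code range, the range of positivity used for
#' dichotomization and covariate counting, and the input priority class.
#'
#' The two continuous features (\code{short_axis}, \code{cortical_thickness},
#' both in mm) are "Necessary" priority; the three binary metastatic markers
#' (\code{nodal_core_sign_absent}, \code{perinodal_hyperechogenic_ring},
#' \code{cortical_interruption}) are "Very high"; the nine ordinal/categorical
#' morphology and vascular features carry "High" or "Low" priority. Two
#' further measurements (\code{medulla}, \code{long_axis}, mm) are recorded
#' but excluded from modelling.
#'
#' Positivity ranges for the categorical features: vascular flow architecture
#' pattern 2--4 (scattered/branched/chaotic), vascular flow localization 2--4
#' (peripheral/extranodal/combined), cortical--medullar interface distortion
#' >= 2 (focal, diffused, or medulla not visible), cortical thickening 2--4
#' (focal/concentric/eccentric), echogenicity = 2 (inhomogeneous), focal
#' intranodal deposit 1--3 (hyperechoic/anechoic/both), shape = 3
#' (irregular), grouping 2--3 (moderate/complete), color score 3--4.
#'
#' @return A data.frame with one row per modelling feature and columns
#'   \code{feature}, \code{type} (\code{"continuous"}, \code{"binary"} or
#'   \code{"ordinal"}), \code{min}, \code{max} (legal code range; \code{Inf}
#'   for continuous), \code{pos_lo}, \code{pos_hi} (positivity range; NA for
#'   continuous features, which are never dichotomized), and \code{priority}.
#' @examples
#' us_features()
#' @export
us_features <- function() {
  data.frame(
    feature = c("short_axis", "cortical_thickness",
                "nodal_core_sign_absent", "perinodal_hyperechogenic_ring",
                "cortical_interruption",
                "echogenicity", "focal_intranodal_deposit",
                "vascular_flow_localization", "cortical_thickening",
                "vfa_pattern", "cmid", "shape", "grouping", "color_score"),
    type = c("continuous", "continuous",
             "binary", "binary", "binary",
             "ordinal", "ordinal", "ordinal", "ordinal",
             "ordinal", "ordinal", "ordinal", "ordinal", "ordinal"),
    min = c(0, 0, 0, 0, 0, 1, 0, 0, 1, 1, 1, 1, 1, 1),
    max = c(Inf, Inf, 1, 1, 1, 2, 3, 4, 4, 4, 4, 3, 3, 4),
    pos_lo = c(NA, NA, 1, 1, 1, 2, 1, 2, 2, 2, 2, 3, 2, 3),
    pos_hi = c(NA, NA, 1, 1, 1, 2, 3, 4, 4, 4, 4, 3, 3, 4),
    priority = c("Necessary", "Necessary",
                 "Very high", "Very high", "Very high",
                 "High", "High", "High", "High", "High", "High",
                 "Low", "Low", "Low"),
    stringsAsFactors = FALSE
  )
}

#' Names of the 14 modelling features
#'
#' @return Character vector, in canonical column order.
#' @export
us_feature_names <- function() us_features()$feature

#' Names of the three metastatic-marker features
#'
#' The binary features whose positivity alone implies a metastatic (MET)
#' signature: absence of the nodal core sign, perinodal hyperechogenic ring,
#' and cortical interruption.
#'
#' @return Character vector of length 3.
#' @export
us_marker_names <- function() {
  c("nodal_core_sign_absent", "perinodal_hyperechogenic_ring",
    "cortical_interruption")
}

#' Names of the nine diagnostic covariates
#'
#' The ordinal/categorical features whose positivity (at least two of them)
#' escalates a moderate-metastatic-risk signature.
#'
#' @return Character vector of length 9.
#' @export
us_covariate_names <- function() {
  info <- us_features()
  info$feature[info$type == "ordinal"]
}

#' Dichotomize ultrasound profiles
#'
#' Maps each of the nine categorical/ordinal features to 1 when its code
#' lies in the feature's range of positivity (see \code{\link{us_features}})
#' and 0 otherwise. The three binary markers pass through unchanged, as do
#' the two continuous features (mm), which are never dichotomized.
#'
#' @param profiles A data.frame of profiles (rows = groins) containing the
#'   14 modelling feature columns, or a single profile as a one-row
#'   data.frame. Additional columns are dropped.
#' @return A data.frame with the 14 modelling feature columns in canonical
#'   order; categorical entries are 0/1.
#' @examples
#' p <- us_profile(short_axis = 8, cortical_thickness = 3, vfa_pattern = 3)
#' dichotomize(p)$vfa_pattern  # 1: "branched" is in the positivity range
#' @export
dichotomize <- function(profiles) {
  info <- us_features()
  profiles <- as.data.frame(profiles)
  miss_col <- setdiff(info$feature, names(profiles))
  if (length(miss_col) > 0L)
    stop("missing feature column(s): ", paste(miss_col, collapse = ", "))
  x <- profiles[info$feature]
  if (anyNA(x))
    stop("profile contains missing features; run impute_missing() first")
  for (i in seq_len(nrow(info))) {
    if (info$type[i] == "ordinal") {
      v <- x[[info$feature[i]]]
      x[[info$feature[i]]] <-
        as.integer(v >= info$pos_lo[i] & v <= info$pos_hi[i])
    }
  }
  x
}

#' Count positive diagnostic covariates
#'
#' Number of the nine diagnostic covariates (ordinal features) whose value
#' lies in its range of positivity. A moderate-metastatic-risk (MMR)
#' signature supported by at least two positive covariates is escalated to
#' a higher point risk.
#'
#' @param profiles Profile data.frame (one or more rows) with complete
#'   modelling features.
#' @return Integer vector (0..9), one count per profile.
#' @examples
#' p <- us_profile(vfa_pattern = 4, shape = 3)
#' count_escalation_covariates(p)  # 2
#' @export
count_escalation_covariates <- function(profiles) {
  d <- dichotomize(profiles)
  as.integer(rowSums(d[us_covariate_names()]))
}

#' Construct a single ultrasound profile
#'
#' Convenience constructor returning a one-row data.frame with all 14
#' modelling features, defaulting every feature to its baseline
#' (least-suspicious) code: continuous features 0 mm, markers absent,
#' ordinal features at the bottom of their code range.
#'
#' @param ... Named feature values overriding the baseline defaults;
#'   optional metadata (\code{outcome}, \code{n_positive_nodes},
#'   \code{patient_id}, \code{side}, \code{medulla}, \code{long_axis}) may
#'   also be given.
#' @param validate Check feature ranges (default TRUE).
#' @return One-row data.frame.
#' @examples
#' us_profile(short_axis = 12.5, cortical_thickness = 4.1, echogenicity = 2)
#' @export
us_profile <- function(..., validate = TRUE) {
  info <- us_features()
  p <- as.list(stats::setNames(info$min, info$feature))
  over <- list(...)
  extra <- setdiff(names(over),
                   c(info$feature, "outcome", "n_positive_nodes",
                     "patient_id", "side", "medulla", "long_axis"))
  if (length(extra) > 0L)
    stop("unknown field(s): ", paste(extra, collapse = ", "))
  p[names(over)] <- over
  p <- as.data.frame(p, stringsAsFactors = FALSE)
  if (validate) validate_profiles(p, strict = TRUE)
  p
}

#' Validate profile feature values
#'
#' Checks that every non-missing modelling feature lies within its declared
#' code range, that continuous features are non-negative, and that (when
#' both are present) \code{outcome == 1} exactly when
#' \code{n_positive_nodes > 0}.
#'
#' @param profiles Profile data.frame.
#' @param strict If TRUE, out-of-range codes raise an error naming the
#'   field; if FALSE they are reported as warnings.
#' @return Invisibly, a logical vector flagging rows with any missing
#'   modelling feature.
#' @export
validate_profiles <- function(profiles, strict = TRUE) {
  info <- us_features()
  profiles <- as.data.frame(profiles)
  report <- function(msg) if (strict) stop(msg, call. = FALSE) else
    warning(msg, call. = FALSE)
  for (i in seq_len(nrow(info))) {
    f <- info$feature[i]
    if (!f %in% names(profiles)) next
    v <- profiles[[f]]
    bad <- !is.na(v) & (v < info$min[i] | v > info$max[i])
    if (info$type[i] != "continuous")
      bad <- bad | (!is.na(v) & v != round(v))
    if (any(bad))
      report(sprintf("feature '%s' out of range [%g, %g] in row(s) %s",
                     f, info$min[i], info$max[i],
                     paste(which(bad), collapse = ", ")))
  }
  if (all(c("outcome", "n_positive_nodes") %in% names(profiles))) {
    y <- profiles$outcome
    m <- profiles$n_positive_nodes
    ok <- is.na(y) | is.na(m) | (y == 1) == (m > 0)
    if (!all(ok))
      report(sprintf("outcome and n_positive_nodes disagree in row(s) %s",
                     paste(which(!ok), collapse = ", ")))
  }
  present <- intersect(info$feature, names(profiles))
  has_na <- rowSums(is.na(profiles[present])) > 0 |
    length(present) < nrow(info)
  invisible(has_na)
}
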