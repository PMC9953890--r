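#' Construct a cohort of ultrasound profiles
#'
#' A cohort bundles a data.frame of groin profiles (rows) with an optional
#' 5-subset partition used by the nested cross-validation of the
#' random-forest ensemble.
#'
#' @param profiles Data.frame with the 14 modelling feature columns and,
#'   for cohorts used in fitting, an \code{outcome} column (1 = metastatic
#'   groin). Extra columns are carried along as metadata.
#' @param partition Optional integer vector (values 1..5, one per row)
#'   assigning each profile to a subset; must be a disjoint cover with
#'   subset sizes differing by at most 1.
#' @param strict Passed to \code{\link{validate_profiles}}.
#' @return Object of class \code{us_cohort}: a list with elements
#'   \code{profiles} and \code{partition}.
#' @export
us_cohort <- function(profiles, partition = NULL, strict = TRUE) {
  profiles <- as.data.frame(profiles)
  missing_flag <- validate_profiles(profiles, strict = strict)
  if (!is.null(partition)) {
    if (length(partition) != nrow(profiles))
      stop("partition length must equal the number of profiles")
    sizes <- tabulate(partition, nbins = 5L)
    if (sum(sizes) != nrow(profiles) || any(partition < 1 | partition > 5))
      stop("partition must assign every profile to one of 5 subsets")
    if (diff(range(sizes)) > 1L)
      stop("partition subset sizes must differ by at most 1")
  }
  structure(list(profiles = profiles, partition = partition,
                 has_missing = missing_flag),
            class = "us_cohort")
}

#' @export
print.us_cohort <- function(x, ...) {
  n <- nrow(x$profiles)
  cat(sprintf("Ultrasound cohort: %d groins", n))
  if ("outcome" %in% names(x$profiles) && !anyNA(x$profiles$outcome)) {
    pos <- sum(x$profiles$outcome == 1)
    cat(sprintf(" (%d metastatic, %d non-metastatic)", pos, n - pos))
  }
  cat("\n")
  if (!is.null(x$partition))
    cat("Partition subset sizes:",
        paste(tabulate(x$partition, 5L), collapse = ", "), "\n")
  if (any(x$has_missing))
    cat(sum(x$has_missing), "profile(s) with missing features\n")
  invisible(x)
}

# columns recognised by the CSV schema beyond the 14 modelling features
.meta_columns <- c("medulla", "long_axis", "outcome", "n_positive_nodes",
                   "patient_id", "side")

#' Read a cohort from CSV
#'
#' Reads a `morphonode_profiles.csv`-schema file: one row per groin, one
#' column per feature (header names matched case-insensitively), UTF-8,
#' decimal point, missing cells empty or "NA". Unknown columns are kept as
#' metadata.
#'
#' @param path Path to the CSV file.
#' @param strict If TRUE, out-of-range feature codes raise a validation
#'   error naming the field; malformed numeric cells always raise a parse
#'   error naming row and column.
#' @return A \code{\link{us_cohort}}.
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  canonical <- c(us_feature_names(), .meta_columns)
  lookup <- match(tolower(names(raw)), tolower(canonical))
  names(raw)[!is.na(lookup)] <- canonical[lookup[!is.na(lookup)]]
  numeric_cols <- intersect(names(raw),
                            setdiff(canonical, c("patient_id", "side")))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0L)
      stop(sprintf("malformed numeric cell in column '%s', row %d: '%s'",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    raw[[col]] <- v
  }
  for (col in setdiff(names(raw), numeric_cols))
    raw[[col]] <- utils::type.convert(raw[[col]], as.is = TRUE)
  us_cohort(raw, strict = strict)
}

#' Write a cohort to CSV
#'
#' Inverse of \code{\link{read_cohort}}: canonical feature columns first,
#' metadata columns after, missing values as empty cells.
#'
#' @param cohort A \code{\link{us_cohort}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "us_cohort"))
  df <- cohort$profiles
  canonical <- c(us_feature_names(), .meta_columns)
  ord <- c(intersect(canonical, names(df)), setdiff(names(df), canonical))
  utils::write.csv(df[ord], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

# internal: labelled outcome vector or informative error
.outcomes <- function(cohort) {
  y <- cohort$profiles$outcome
  if (is.null(y) || anyNA(y))
    stop("cohort must carry a complete outcome label for every profile")
  as.integer(y)
}
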