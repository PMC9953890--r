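#' Top-k similar reference profiles
#'
#' Compares a query profile with every profile of a reference cohort in a
#' common vector space: the two continuous features standardized by the
#' reference mean and standard deviation, and the categorical block as
#' dichotomized 0/1 entries. By default cosine similarity ranks the
#' reference; Pearson correlation is available as an alternative metric.
#' A zero-norm vector has similarity 0 to every record. Ties are broken by
#' reference order.
#'
#' @param profile One-row complete profile data.frame.
#' @param reference \code{\link{us_cohort}} with at least k profiles.
#' @param k Number of profiles to return (default 5).
#' @param metric \code{"cosine"} (default) or \code{"pearson"}.
#' @return Data.frame of the k most similar reference profiles:
#'   \code{index} (row in the reference), \code{similarity}, and
#'   \code{phenotype} (reference outcome, NA when unlabelled), sorted by
#'   non-increasing similarity.
#' @export
similarity_top_k <- function(profile, reference, k = 5L,
                             metric = c("cosine", "pearson")) {
  metric <- match.arg(metric)
  stopifnot(inherits(reference, "us_cohort"))
  n <- nrow(reference$profiles)
  if (n < k) stop("reference must contain at least k profiles")
  R <- as.matrix(dichotomize(reference$profiles))
  q <- as.matrix(dichotomize(profile))
  if (nrow(q) != 1L) stop("profile must be a single row")

  cont <- c("short_axis", "cortical_thickness")
  mu <- colMeans(R[, cont, drop = FALSE])
  sd_ <- apply(R[, cont, drop = FALSE], 2, stats::sd)
  sd_[sd_ == 0] <- 1
  R[, cont] <- sweep(sweep(R[, cont, drop = FALSE], 2, mu), 2, sd_, "/")
  q[, cont] <- (q[, cont] - mu) / sd_

  if (metric == "pearson") {
    R <- R - rowMeans(R)
    q <- q - rowMeans(q)
  }
  qn <- sqrt(sum(q^2))
  rn <- sqrt(rowSums(R^2))
  sim <- if (qn == 0) rep(0, n) else drop(R %*% t(q)) / (rn * qn)
  sim[rn == 0] <- 0

  ord <- order(-sim, seq_len(n))[seq_len(k)]
  pheno <- if ("outcome" %in% names(reference$profiles))
    reference$profiles$outcome[ord] else rep(NA_integer_, k)
  data.frame(index = ord, similarity = sim[ord], phenotype = pheno)
}

#' Similarity-profiling majority vote
#'
#' Assigns the majority phenotype of the top-k similar profiles; k must be
#' odd so the vote cannot tie.
#'
#' @param top5 Result of \code{\link{similarity_top_k}}, or a vector of
#'   binary phenotypes.
#' @return 0 or 1.
#' @examples
#' sp_majority(c(1, 1, 1, 0, 0))
#' @export
sp_majority <- function(top5) {
  pheno <- if (is.data.frame(top5)) top5$phenotype else top5
  if (length(pheno) %% 2L == 0L)
    stop("k must be odd for a majority vote")
  if (anyNA(pheno)) stop("phenotypes must be labelled")
  as.integer(mean(pheno) > 0.5)
}
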