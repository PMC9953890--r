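#' Published signature point risks
#'
#' The frozen inference-mode point risks (with 95% bootstrap confidence
#' intervals) of the four metastatic-risk signatures: MET with two or more
#' markers ~1.00; MET with exactly one marker 0.88 (0.86--0.90, interval
#' midpoint); HMR 0.81 (0.52--0.90); MMR 0.16 (0.06--0.25); MMR escalated
#' by >= 2 positive diagnostic covariates 0.55 (0.46--0.64); LMR 0.04
#' (0.00--0.10).
#'
#' @return Data.frame with columns \code{signature}, \code{risk},
#'   \code{lo}, \code{hi}.
#' @export
signature_published_risks <- function() {
  data.frame(
    signature = c("MET_multi", "MET_single", "HMR", "MMR_escalated",
                  "MMR", "LMR"),
    risk = c(1.00, 0.88, 0.81, 0.55, 0.16, 0.04),
    lo = c(1.00, 0.86, 0.52, 0.46, 0.06, 0.00),
    hi = c(1.00, 0.90, 0.90, 0.64, 0.25, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Per-feature positive predictive value
#'
#' Malignancy risk of each dichotomizable ultrasound feature, estimated as
#' its positive predictive value P(metastatic | feature positive) on a
#' labelled cohort. Features that are never positive have an undefined
#' ratio and are returned as NA (excluded from marker candidacy).
#'
#' @param cohort Labelled \code{\link{us_cohort}}.
#' @return Named numeric vector over the 12 binary/ordinal features.
#' @export
compute_feature_ppv <- function(cohort) {
  stopifnot(inherits(cohort, "us_cohort"))
  y <- .outcomes(cohort)
  if (length(y) == 0L) stop("empty cohort")
  D <- dichotomize(cohort$profiles)
  feats <- setdiff(us_feature_names(),
                   c("short_axis", "cortical_thickness"))
  vapply(feats, function(f) {
    pos <- D[[f]] == 1
    if (!any(pos)) return(NA_real_)
    mean(y[pos] == 1L)
  }, numeric(1))
}

#' Extract metastatic markers
#'
#' Features whose positive predictive value reaches the marker threshold
#' (0.85, inclusive); their presence alone leads directly to a malignant
#' (MET) diagnosis. On calibrated data the expected set is nodal core sign
#' absence, perinodal hyperechogenic ring and cortical interruption.
#'
#' @param ppvs Named PPV vector from \code{\link{compute_feature_ppv}}.
#' @param threshold Marker PPV threshold (default 0.85).
#' @return Character vector of marker feature names (possibly empty).
#' @export
extract_markers <- function(ppvs, threshold = 0.85) {
  names(ppvs)[!is.na(ppvs) & ppvs >= threshold]
}

# map rpart frame rows (internal nodes) to their primary-split rows in
# fit$splits: each internal node consumes 1 + ncompete + nsurrogate rows
.primary_split_rows <- function(fit) {
  fr <- fit$frame
  internal <- which(fr$var != "<leaf>")
  counts <- 1L + fr$ncompete[internal] + fr$nsurrogate[internal]
  stats::setNames(c(0L, cumsum(counts))[seq_along(internal)] + 1L,
                  rownames(fr)[internal])
}

# route complete numeric profiles through an rpart tree; returns the leaf
# node number (rpart frame row name) per row
.route_rpart <- function(fit, newdata) {
  fr <- fit$frame
  srow <- .primary_split_rows(fit)
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- 1L
    repeat {
      k <- match(as.character(node), rownames(fr))
      if (fr$var[k] == "<leaf>") return(node)
      s <- fit$splits[srow[[as.character(node)]], ]
      x <- newdata[[as.character(fr$var[k])]][i]
      go_left <- if (s["ncat"] < 0) x < s["index"] else x >= s["index"]
      node <- if (go_left) 2L * node else 2L * node + 1L
    }
  }, integer(1))
}

#' Build the Gini risk tree
#'
#' Recursive binary partitioning of the marker-negative cohort by Gini
#' impurity (via rpart), pruned to at most \code{max_leaves} leaves using
#' the complexity sequence. Leaf risks are the leaf metastatic fractions,
#' with percentile bootstrap confidence intervals obtained by resampling
#' groins and re-dropping them through the fixed tree. Leaves are labelled
#' HMR / MMR / LMR by descending risk (HMR and LMR only when two leaves,
#' HMR or LMR alone for a pure single-leaf tree).
#'
#' @param cohort Labelled \code{\link{us_cohort}}, restricted to profiles
#'   with no positive metastatic marker.
#' @param max_leaves Maximum number of risk groups (default 3).
#' @param n_boot Bootstrap resamples for leaf-risk CIs (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param minbucket Minimum leaf size passed to rpart (default 7).
#' @return Object of class \code{risk_tree}: the rpart fit (NULL for a
#'   degenerate single-leaf tree) and a \code{leaves} data.frame with
#'   columns \code{node}, \code{label}, \code{risk}, \code{lo}, \code{hi},
#'   \code{n}.
#' @export
build_tree <- function(cohort, max_leaves = 3L, n_boot = 2000L, seed = 1L,
                       minbucket = 7L) {
  stopifnot(inherits(cohort, "us_cohort"))
  y <- .outcomes(cohort)
  D <- dichotomize(cohort$profiles)
  dat <- cbind(outcome = factor(y, levels = c(0L, 1L)), D)

  single_leaf <- function(risk_vec) {
    risk <- mean(risk_vec)
    data.frame(node = 1L, label = if (risk >= 0.5) "HMR" else "LMR",
               risk = risk, lo = NA_real_, hi = NA_real_,
               n = length(risk_vec), stringsAsFactors = FALSE)
  }
  if (length(unique(y)) < 2L) {
    return(structure(list(rpart = NULL, leaves = single_leaf(y),
                          where = rep(1L, length(y))),
                     class = "risk_tree"))
  }

  # for a 0/1 outcome the anova split criterion (within-node sum of
  # squares, n*p*(1-p)) is exactly the weighted Gini impurity up to a
  # factor 2, and its complexity sequence tracks impurity reduction, so
  # pruning selects the lowest-impurity subtree even at low prevalence
  dat$outcome <- y
  fit <- rpart::rpart(outcome ~ ., data = dat, method = "anova",
                      control = rpart::rpart.control(cp = 0.001,
                                                     minbucket = minbucket,
                                                     xval = 0L))
  # prune to the best subtree with at most max_leaves leaves
  ct <- fit$cptable
  ok <- ct[, "nsplit"] <= max_leaves - 1L
  cp_use <- ct[max(which(ok)), "CP"]
  fit <- rpart::prune(fit, cp = cp_use)

  fr <- fit$frame
  leaf_rows <- which(fr$var == "<leaf>")
  if (length(leaf_rows) < 2L) {
    return(structure(list(rpart = NULL, leaves = single_leaf(y),
                          where = rep(1L, length(y))),
                     class = "risk_tree"))
  }
  nodes <- as.integer(rownames(fr)[leaf_rows])
  where_nodes <- as.integer(rownames(fr)[fit$where])
  risk <- vapply(nodes, function(nd) mean(y[where_nodes == nd]), numeric(1))
  nn <- vapply(nodes, function(nd) sum(where_nodes == nd), numeric(1))

  lo <- hi <- rep(NA_real_, length(nodes))
  if (n_boot > 0L) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    bmat <- matrix(NA_real_, n_boot, length(nodes))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(length(y), replace = TRUE)
      wb <- where_nodes[idx]
      yb <- y[idx]
      bmat[b, ] <- vapply(nodes, function(nd) {
        inb <- wb == nd
        if (!any(inb)) NA_real_ else mean(yb[inb])
      }, numeric(1))
    }
    qs <- apply(bmat, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    lo <- qs[1, ]
    hi <- qs[2, ]
  }

  labels_for <- function(k) switch(as.character(k),
                                   "1" = "HMR", "2" = c("HMR", "LMR"),
                                   c("HMR", "MMR", "LMR"))
  ord <- order(-risk, nodes)
  leaves <- data.frame(node = nodes[ord],
                       label = labels_for(length(nodes))[seq_along(nodes)],
                       risk = risk[ord], lo = lo[ord], hi = hi[ord],
                       n = nn[ord], stringsAsFactors = FALSE)
  structure(list(rpart = fit, leaves = leaves, where = where_nodes),
            class = "risk_tree")
}

#' @export
print.risk_tree <- function(x, ...) {
  cat("Gini risk tree with", nrow(x$leaves), "leaf/leaves\n")
  print(x$leaves, row.names = FALSE)
  invisible(x)
}

#' Fit the signature model
#'
#' Combines the metastatic-marker screen with the Gini risk tree: features
#' with training PPV >= 0.85 become markers; profiles without a positive
#' marker are partitioned by \code{\link{build_tree}} into the HMR / MMR /
#' LMR risk groups. Point risks attached to the signatures come either
#' from the published constants (inference mode, default) or are
#' re-estimated from the training cohort with percentile bootstrap CIs.
#'
#' @param cohort Labelled, complete \code{\link{us_cohort}}.
#' @param risk_source \code{"published"} (default) or \code{"trained"}.
#' @param max_leaves,n_boot,seed,minbucket Passed to
#'   \code{\link{build_tree}} (and the trained-risk bootstrap).
#' @return Object of class \code{signature_model}: \code{markers},
#'   \code{tree} (a \code{risk_tree}), \code{signature_risk} table,
#'   \code{covariate_list}.
#' @export
fit_signature_model <- function(cohort, risk_source = c("published",
                                                        "trained"),
                                max_leaves = 3L, n_boot = 2000L, seed = 1L,
                                minbucket = 7L) {
  risk_source <- match.arg(risk_source)
  stopifnot(inherits(cohort, "us_cohort"))
  y <- .outcomes(cohort)
  ppvs <- compute_feature_ppv(cohort)
  markers <- extract_markers(ppvs)
  D <- dichotomize(cohort$profiles)
  n_mark <- if (length(markers) > 0L)
    rowSums(D[, markers, drop = FALSE]) else rep(0L, length(y))
  keep <- n_mark == 0L
  sub <- us_cohort(cohort$profiles[keep, , drop = FALSE], strict = FALSE)
  tree <- build_tree(sub, max_leaves = max_leaves, n_boot = n_boot,
                     seed = seed, minbucket = minbucket)

  risks <- signature_published_risks()
  if (risk_source == "trained") {
    cov_n <- count_escalation_covariates(cohort$profiles)
    est <- c(
      MET_multi = if (any(n_mark >= 2L)) mean(y[n_mark >= 2L]) else NA,
      MET_single = if (any(n_mark == 1L)) mean(y[n_mark == 1L]) else NA,
      MMR_escalated = NA
    )
    lv <- tree$leaves
    for (i in seq_len(nrow(lv))) {
      est[lv$label[i]] <- lv$risk[i]
    }
    mmr_node <- lv$node[lv$label == "MMR"]
    if (length(mmr_node) == 1L) {
      in_mmr <- keep & seq_along(y) %in%
        which(keep)[tree$where == mmr_node]
      esc <- in_mmr & cov_n >= 2L
      if (any(esc)) est["MMR_escalated"] <- mean(y[esc])
    }
    risks <- risks[risks$signature %in% names(est), ]
    risks$risk <- est[risks$signature]
    risks$lo <- risks$hi <- NA_real_
  }

  structure(list(markers = markers, tree = tree, signature_risk = risks,
                 covariate_list = us_covariate_names(), ppvs = ppvs,
                 risk_source = risk_source),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Metastatic-risk signature model\n")
  cat("  markers (PPV >= 0.85):",
      if (length(x$markers)) paste(x$markers, collapse = ", ") else "none",
      "\n")
  cat("  point risks (", x$risk_source, "):\n", sep = "")
  print(x$signature_risk, row.names = FALSE)
  invisible(x)
}

#' Assign a metastatic-risk signature
#'
#' The marker screen decides first: one or more positive metastatic
#' markers yield the MET signature (point risk 0.88 with exactly one
#' marker, ~1.00 with two or more). Marker-negative profiles are routed
#' through the Gini tree to HMR, MMR or LMR; an MMR profile with at least
#' two positive diagnostic covariates is escalated to the higher MMR point
#' risk.
#'
#' @param model A \code{signature_model}.
#' @param profiles Complete profile data.frame (one or more rows).
#' @return Data.frame with columns \code{signature} (MET/HMR/MMR/LMR),
#'   \code{escalated} (logical, MMR only), \code{point_risk}, \code{lo},
#'   \code{hi}.
#' @export
assign_signature <- function(model, profiles) {
  stopifnot(inherits(model, "signature_model"))
  D <- dichotomize(profiles)
  n <- nrow(D)
  n_mark <- if (length(model$markers) > 0L)
    rowSums(D[, model$markers, drop = FALSE]) else rep(0L, n)
  cov_n <- count_escalation_covariates(profiles)

  rk <- model$signature_risk
  row_of <- function(sig) rk[match(sig, rk$signature), c("risk", "lo", "hi")]

  out <- data.frame(signature = character(n), escalated = logical(n),
                    point_risk = numeric(n), lo = numeric(n),
                    hi = numeric(n), stringsAsFactors = FALSE)
  tree_leaf <- rep(NA_integer_, n)
  need_tree <- which(n_mark == 0L)
  if (length(need_tree) > 0L) {
    if (is.null(model$tree$rpart)) {
      tree_leaf[need_tree] <- 1L
    } else {
      tree_leaf[need_tree] <- .route_rpart(model$tree$rpart,
                                           D[need_tree, , drop = FALSE])
    }
  }
  for (i in seq_len(n)) {
    if (n_mark[i] >= 2L) {
      sig <- "MET"; r <- row_of("MET_multi")
    } else if (n_mark[i] == 1L) {
      sig <- "MET"; r <- row_of("MET_single")
    } else {
      lv <- model$tree$leaves
      sig <- lv$label[match(tree_leaf[i], lv$node)]
      if (identical(sig, "MMR") && cov_n[i] >= 2L) {
        out$escalated[i] <- TRUE
        r <- row_of("MMR_escalated")
      } else {
        r <- lv[match(tree_leaf[i], lv$node), c("risk", "lo", "hi")]
        pub <- row_of(sig)
        if (model$risk_source == "published" && !is.na(pub$risk)) r <- pub
      }
    }
    out$signature[i] <- sig
    out$point_risk[i] <- r$risk
    out$lo[i] <- r$lo
    out$hi[i] <- r$hi
  }
  out
}
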