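# rank-statistic AUC with ties counted one half
.auc_rank <- function(scores, outcomes) {
  y <- as.integer(outcomes)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Diagnostic performance report from a confusion table
#'
#' The eight indices used to evaluate the classifiers: sensitivity
#' tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp), NPV tn/(tn+fn),
#' positive and negative likelihood ratios Se/(1-Sp) and (1-Se)/Sp, the
#' F1 score (harmonic mean of sensitivity and PPV), and accuracy
#' (tp+tn)/total. Proportion indices carry exact (Clopper--Pearson)
#' binomial 95% confidence intervals; likelihood ratios carry log-normal
#' intervals; the F1 interval comes from a seeded multinomial bootstrap of
#' the confusion counts. Empty denominators yield NA with a flag.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (total > 0). A single
#'   list/vector with those names may be passed as \code{tp}.
#' @param n_boot Bootstrap resamples for the F1 interval (default 2000).
#' @param seed Seed for that bootstrap (default 1).
#' @return Object of class \code{performance_report}: data.frame
#'   \code{indices} (index, value, lo, hi), the counts, and
#'   \code{undefined} (names of indices with empty denominators).
#' @examples
#' performance_report(tp = 9, fp = 2, tn = 8, fn = 1)
#' @export
performance_report <- function(tp, fp = NULL, tn = NULL, fn = NULL,
                               n_boot = 2000L, seed = 1L) {
  if (is.list(tp) || length(tp) == 4L) {
    cc <- as.list(tp)
    tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  }
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  total <- tp + fp + tn + fn
  if (total == 0) stop("confusion table is empty")

  prop_ci <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    ci <- stats::binom.test(x, n)$conf.int
    c(x / n, ci[1], ci[2])
  }
  se <- prop_ci(tp, tp + fn)
  sp <- prop_ci(tn, tn + fp)
  ppv <- prop_ci(tp, tp + fp)
  npv <- prop_ci(tn, tn + fn)
  acc <- prop_ci(tp + tn, total)

  z <- stats::qnorm(0.975)
  lr_pos <- c(NA_real_, NA_real_, NA_real_)
  if (!is.na(se[1]) && !is.na(sp[1]) && sp[1] < 1) {
    est <- se[1] / (1 - sp[1])
    if (tp > 0 && fp > 0) {
      s <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
      lr_pos <- c(est, est * exp(-z * s), est * exp(z * s))
    } else lr_pos <- c(est, NA_real_, NA_real_)
  }
  lr_neg <- c(NA_real_, NA_real_, NA_real_)
  if (!is.na(se[1]) && !is.na(sp[1]) && sp[1] > 0) {
    est <- (1 - se[1]) / sp[1]
    if (fn > 0 && tn > 0) {
      s <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
      lr_neg <- c(est, est * exp(-z * s), est * exp(z * s))
    } else lr_neg <- c(est, NA_real_, NA_real_)
  }

  f1_of <- function(tp2, fp2, fn2) {
    if (tp2 == 0) return(if (tp2 + fp2 == 0 || tp2 + fn2 == 0)
      NA_real_ else 0)
    se2 <- tp2 / (tp2 + fn2)
    ppv2 <- tp2 / (tp2 + fp2)
    2 * se2 * ppv2 / (se2 + ppv2)
  }
  f1 <- c(if (tp + fp == 0 || tp + fn == 0) NA_real_ else
    f1_of(tp, fp, fn), NA_real_, NA_real_)
  if (!is.na(f1[1]) && n_boot > 0L) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    draws <- stats::rmultinom(n_boot, total,
                              c(tp, fp, tn, fn) / total)
    f1b <- apply(draws, 2, function(d) f1_of(d[1], d[2], d[4]))
    f1[2:3] <- stats::quantile(f1b, c(0.025, 0.975), na.rm = TRUE)
  }

  idx <- rbind(se = se, sp = sp, ppv = ppv, npv = npv, lr_pos = lr_pos,
               lr_neg = lr_neg, f1 = f1, acc = acc)
  indices <- data.frame(index = rownames(idx), value = idx[, 1],
                        lo = idx[, 2], hi = idx[, 3],
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(indices = indices,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 undefined = indices$index[is.na(indices$value)]),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Diagnostic performance (tp =", x$counts["tp"], ", fp =",
      x$counts["fp"], ", tn =", x$counts["tn"], ", fn =",
      x$counts["fn"], ")\n")
  print(transform(x$indices, value = round(value, 4), lo = round(lo, 4),
                  hi = round(hi, 4)), row.names = FALSE)
  if (length(x$undefined) > 0L)
    cat("undefined (empty denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC analysis
#'
#' Area under the ROC curve by the rank statistic (the probability that a
#' random positive outscores a random negative, ties counted one half),
#' an asymptotic confidence interval from the DeLong placement variance,
#' and the optimal cut-point by the max-sensitivity/max-specificity
#' criterion (maximize min(Se, Sp), ties broken by larger Se + Sp, then
#' lower threshold).
#'
#' @param scores Numeric score vector.
#' @param outcomes Binary outcome vector; both classes must be present.
#' @return List with \code{auc}, \code{ci} (length 2), and
#'   \code{optimal_cutpoint}.
#' @export
roc_analysis <- function(scores, outcomes) {
  y <- as.integer(outcomes)
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present")
  auc <- .auc_rank(scores, y)
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  n1 <- length(pos)
  n0 <- length(neg)
  # DeLong placements
  v10 <- vapply(pos, function(s) (sum(neg < s) + 0.5 * sum(neg == s)) / n0,
                numeric(1))
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / n1,
                numeric(1))
  v <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(0.975)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(v), 0), 1)
  th <- select_thresholds(scores, y)
  list(auc = auc, ci = ci, optimal_cutpoint = unname(th["t_sesp"]))
}

#' Two-proportion test with continuity correction
#'
#' Two-sided test for equality of proportions x1/n1 vs x2/n2 with the
#' Yates continuity correction, as used for the cohort count comparisons:
#' the 95% interval for p1 - p2 is the normal approximation widened by
#' (1/n1 + 1/n2)/2, and the p-value comes from the continuity-corrected
#' chi-squared statistic (via \code{stats::prop.test}). A zero margin
#' (no events, or all events) yields p-value 1 with the interval clamped
#' to [-1, 1].
#'
#' @param x1,n1 Events and size of group 1.
#' @param x2,n2 Events and size of group 2.
#' @return List with \code{p1}, \code{p2}, \code{diff}, \code{conf_int}
#'   (95% CI for p1 - p2) and \code{p_value}.
#' @examples
#' prop_test_2x2(27, 56, 15, 71)  # CI (0.093, 0.449)
#' @export
prop_test_2x2 <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2, n1 > 0, n2 > 0)
  p1 <- x1 / n1
  p2 <- x2 / n2
  if ((x1 + x2 == 0) || (x1 == n1 && x2 == n2)) {
    hw <- 0.5 * (1 / n1 + 1 / n2)  # correction term alone; variance is 0
    ci <- pmin(pmax(c(p1 - p2 - hw, p1 - p2 + hw), -1), 1)
    return(list(p1 = p1, p2 = p2, diff = p1 - p2, conf_int = ci,
                p_value = 1))
  }
  pt <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                          correct = TRUE))
  list(p1 = p1, p2 = p2, diff = p1 - p2,
       conf_int = as.numeric(pt$conf.int), p_value = pt$p.value)
}

#' Wilcoxon rank-sum shift estimate
#'
#' Two-sided Wilcoxon rank-sum test with the Hodges--Lehmann location
#' shift estimate (the median of all pairwise differences b - a) and its
#' distribution-free 95% confidence interval. The sign convention is the
#' second sample minus the first.
#'
#' @param a,b Non-empty numeric vectors (reference group first).
#' @return List with \code{shift_estimate}, \code{ci_95}, \code{p_value},
#'   and logical \code{degenerate} (all values tied).
#' @examples
#' wilcoxon_shift(c(1, 2, 3), c(11, 12, 13))  # shift 10
#' @export
wilcoxon_shift <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1L)
    return(list(shift_estimate = 0, ci_95 = c(0, 0), p_value = 1,
                degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(b, a, conf.int = TRUE,
                                            conf.level = 0.95))
  list(shift_estimate = unname(wt$estimate),
       ci_95 = as.numeric(wt$conf.int),
       p_value = wt$p.value, degenerate = FALSE)
}

#' Recompute the cohort-comparison table from printed counts
#'
#' Re-runs the continuity-corrected two-proportion test on every count row
#' of the packaged study comparison table (metastatic vs non-metastatic
#' patient groups, denominators 56 and 71) and checks the recomputed
#' proportions and 95% confidence intervals against the printed cells at
#' tolerance 0.001 (0.0005 printed rounding plus numeric slack). P-values
#' are recomputed and reported but not gated (several are printed as
#' inequalities).
#'
#' @param path CSV of printed counts and cells; defaults to the packaged
#'   fixture.
#' @param tol Comparison tolerance (default 0.001).
#' @return Data.frame with one row per table row: recomputed and printed
#'   cells, absolute deviations, and a logical \code{pass}; the attribute
#'   \code{"all_pass"} summarizes the table.
#' @export
reproduce_table1 <- function(path = system.file("extdata",
                                                "table1_counts.csv",
                                                package = "morphonode"),
                             tol = 0.001) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    pt <- prop_test_2x2(r$x1, r$n1, r$x2, r$n2)
    data.frame(
      label = r$label, p1 = pt$p1, p2 = pt$p2,
      ci_lo = pt$conf_int[1], ci_hi = pt$conf_int[2],
      p_value = pt$p_value,
      p1_printed = r$p1, p2_printed = r$p2,
      ci_lo_printed = r$ci_lo, ci_hi_printed = r$ci_hi,
      p_value_printed = r$p_value,
      max_dev = max(abs(pt$p1 - r$p1), abs(pt$p2 - r$p2),
                    abs(pt$conf_int[1] - r$ci_lo),
                    abs(pt$conf_int[2] - r$ci_hi)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$pass <- out$max_dev <= tol
  attr(out, "all_pass") <- all(out$pass)
  out
}
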