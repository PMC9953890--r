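#' Combine the three module verdicts into a final diagnosis
#'
#' The majority-wins rule over the random-forest label, the risk stratum
#' and the signature, evaluated after the metastatic-marker override:
#' \itemize{
#'   \item any MET signature forces a malignant diagnosis, whatever the
#'     other modules say;
#'   \item module verdicts otherwise are RFC: malignant (1) /
#'     non-malignant (0); RBM: malignant if the stratum is high,
#'     non-malignant if low, intermediate if moderate; DT: malignant for
#'     HMR, non-malignant for LMR, intermediate for MMR;
#'   \item the diagnosis is the majority of the non-intermediate verdicts,
#'     with two exceptions yielding an indeterminate,
#'     biopsy-advised outcome: (i) RBM and DT both intermediate;
#'     (ii) two opposite verdicts plus one intermediate.
#' }
#'
#' @param rfc_label 0/1 random-forest majority vote.
#' @param stratum \code{"low"}, \code{"moderate"} or \code{"high"}.
#' @param signature \code{"MET"}, \code{"HMR"}, \code{"MMR"} or
#'   \code{"LMR"}.
#' @return \code{"malignant"}, \code{"non-malignant"} or
#'   \code{"indeterminate-biopsy-advised"}.
#' @examples
#' majority_diagnosis(1, "high", "HMR")      # malignant
#' majority_diagnosis(0, "moderate", "MMR")  # indeterminate
#' @export
majority_diagnosis <- function(rfc_label, stratum, signature) {
  stopifnot(rfc_label %in% c(0, 1),
            stratum %in% c("low", "moderate", "high"),
            signature %in% c("MET", "HMR", "MMR", "LMR"))
  if (signature == "MET") return("malignant")
  verdicts <- c(rfc = as.integer(rfc_label),
                rbm = switch(stratum, low = 0L, moderate = NA_integer_,
                             high = 1L),
                dt = switch(signature, LMR = 0L, MMR = NA_integer_,
                            HMR = 1L))
  decided <- verdicts[!is.na(verdicts)]
  if (length(decided) == 1L)   # RBM and DT both intermediate
    return("indeterminate-biopsy-advised")
  if (length(decided) == 2L && decided[1] != decided[2])
    return("indeterminate-biopsy-advised")  # opposite + intermediate
  if (mean(decided) > 0.5) "malignant" else "non-malignant"
}

#' Full Morphonode prediction for one profile
#'
#' Runs every module on a single complete profile and assembles the output
#' scheme: random-forest majority vote, binomial risk with its stratum,
#' metastatic-risk signature (with escalation flag), prediction error E
#' with reliability flag, the top-k most similar reference profiles, and
#' the majority-wins final diagnosis. An unreliable prediction (E at or
#' above the cutoff) is flagged but still reported.
#'
#' @param profile One-row complete profile data.frame (impute first if
#'   needed).
#' @param rfc Trained \code{rfc_ensemble}.
#' @param rbm Trained \code{rbm_model}.
#' @param dt Trained \code{signature_model}.
#' @param error_model Optional calibrated \code{error_model}.
#' @param reference Optional labelled \code{\link{us_cohort}} for
#'   similarity profiling.
#' @param k,metric Passed to \code{\link{similarity_top_k}}.
#' @return Object of class \code{morphonode_output}.
#' @export
predict_full <- function(profile, rfc, rbm, dt, error_model = NULL,
                         reference = NULL, k = 5L, metric = "cosine") {
  profile <- as.data.frame(profile)
  if (nrow(profile) != 1L) stop("profile must be a single row")
  vote <- predict_vote(rfc, profile)
  risk <- predict_risk(rbm, profile)
  stratum <- stratify_risk(risk, rbm)
  sig <- assign_signature(dt, profile)

  err <- NULL
  if (!is.null(error_model))
    err <- prediction_error(error_model, vote$label, risk, sig$signature)
  top <- NULL
  if (!is.null(reference))
    top <- similarity_top_k(profile, reference, k = k, metric = metric)

  out <- list(
    rfc_label = vote$label, votes = drop(vote$votes),
    rbm_risk = unname(risk), risk_stratum = stratum,
    signature = sig$signature, signature_escalated = sig$escalated,
    signature_risk = sig$point_risk,
    signature_ci = c(sig$lo, sig$hi),
    prediction_error = if (is.null(err)) NA_real_ else err$E,
    reliable = if (is.null(err)) NA else err$reliable,
    top_similar = top,
    sp_vote = if (!is.null(top) && !anyNA(top$phenotype) && k %% 2L == 1L)
      sp_majority(top) else NA_integer_,
    final_diagnosis = majority_diagnosis(vote$label, stratum,
                                         sig$signature)
  )
  structure(out, class = "morphonode_output")
}

#' @export
print.morphonode_output <- function(x, ...) {
  cat("Morphonode prediction\n")
  cat(sprintf("  RFC vote:        %d (votes %s)\n", x$rfc_label,
              paste(x$votes, collapse = "")))
  cat(sprintf("  RBM risk:        %.3f (%s risk)\n", x$rbm_risk,
              x$risk_stratum))
  cat(sprintf("  DT signature:    %s%s, point risk %.2f\n", x$signature,
              if (isTRUE(x$signature_escalated)) " (escalated)" else "",
              x$signature_risk))
  if (!is.na(x$prediction_error))
    cat(sprintf("  Prediction error %.3f (%s)\n", x$prediction_error,
                if (isTRUE(x$reliable)) "reliable" else "UNRELIABLE"))
  if (!is.null(x$top_similar)) {
    cat("  Top similar profiles (index, similarity, phenotype):\n")
    for (i in seq_len(nrow(x$top_similar)))
      cat(sprintf("    #%d  %.4f  %s\n", x$top_similar$index[i],
                  x$top_similar$similarity[i],
                  x$top_similar$phenotype[i]))
  }
  cat("  Final diagnosis:", x$final_diagnosis, "\n")
  invisible(x)
}

#' Export a signature model's tree as JSON
#'
#' Serializes the marker set, the pruned Gini tree (split feature, cut
#' point, children, leaf label/risk) and the signature risk table.
#'
#' @param model A \code{signature_model}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
export_tree_json <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  lv <- model$tree$leaves
  nodes <- lapply(seq_len(nrow(lv)), function(j)
    list(node = lv$node[j], leaf = TRUE, label = lv$label[j],
         risk = lv$risk[j]))
  fit <- model$tree$rpart
  if (!is.null(fit)) {
    fr <- fit$frame
    srow <- .primary_split_rows(fit)
    nodes <- lapply(seq_len(nrow(fr)), function(k) {
      node <- as.integer(rownames(fr)[k])
      if (fr$var[k] == "<leaf>") {
        j <- match(node, lv$node)
        list(node = node, leaf = TRUE, label = lv$label[j],
             risk = lv$risk[j])
      } else {
        s <- fit$splits[srow[[as.character(node)]], ]
        list(node = node, leaf = FALSE,
             feature = as.character(fr$var[k]),
             cut = unname(s["index"]),
             left_if = if (s["ncat"] < 0) "lt" else "ge",
             children = c(2L * node, 2L * node + 1L))
      }
    })
  }
  obj <- list(markers = model$markers, tree = nodes,
              signature_risk = model$signature_risk)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
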