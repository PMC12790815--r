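pair_key <- function(drug, outcome) paste(drug, outcome, sep = "\r")

#' Compare predicted drug effects against a reference side-effect list
#'
#' True positives are predicted (drug, outcome) pairs present in the
#' reference; false negatives are reference pairs inside the evaluated
#' universe that were not predicted. The universe defaults to the testable
#' hypothesis pairs when supplied, otherwise to the reference itself —
#' reference pairs the pipeline never had a chance to test are not counted
#' against recall.
#'
#' @param predictions data frame with columns \code{drug}, \code{outcome}.
#' @param reference data frame with columns \code{drug}, \code{outcome}
#'   (e.g. a side-effect edge table with columns renamed).
#' @param universe optional data frame of testable \code{drug},
#'   \code{outcome} pairs restricting the recall denominator.
#' @return object of class \code{evaluation_report}: \code{tp}, \code{fp},
#'   \code{fn}, \code{precision}, \code{recall}, \code{f1} (metrics are
#'   \code{NA} when undefined, e.g. no predictions).
#' @export
match_reference <- function(predictions, reference, universe = NULL) {
  stopifnot(all(c("drug", "outcome") %in% names(predictions)),
            all(c("drug", "outcome") %in% names(reference)))
  pred <- unique(pair_key(predictions$drug, predictions$outcome))
  ref <- unique(pair_key(reference$drug, reference$outcome))
  uni <- if (is.null(universe)) ref else
    unique(pair_key(universe$drug, universe$outcome))
  ref_in_uni <- intersect(ref, uni)

  tp <- length(intersect(pred, ref))
  fp <- length(setdiff(pred, ref))
  fn <- length(setdiff(ref_in_uni, pred))
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, n_predictions = length(pred),
                 n_reference = length(ref_in_uni)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation: TP=%d FP=%d FN=%d | precision=%.3f recall=%.3f F1=%.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

rank_auc <- function(scores, labels) {
  # Mann-Whitney identity: AUC = U / (n1 * n0)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

pr_auc <- function(scores, labels) {
  n1 <- sum(labels)
  if (n1 == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  # average precision: mean of precision at each positive hit
  sum(prec[lab]) / n1
}

#' Side-effect-similarity prediction of shared indications
#'
#' For every pair of drugs, computes the Jaccard similarity of their binary
#' side-effect profiles and asks how well that score ranks pairs that share
#' at least one indication above pairs that do not: ROC AUC via the
#' Mann-Whitney rank identity, average-precision PR AUC, and a Mann-Whitney
#' U test comparing the score distributions of sharing vs non-sharing
#' pairs.
#'
#' @param side_effects named list mapping drug id to its set of
#'   side-effect disease ids (or a binary drug-by-effect matrix with row
#'   names).
#' @param indications named list mapping drug id to its set of indicated
#'   disease ids.
#' @return object of class \code{similarity_analysis} with the per-pair
#'   table (\code{drug_a}, \code{drug_b}, \code{similarity},
#'   \code{shared_indication}), \code{roc_auc}, \code{pr_auc},
#'   \code{p_value}. AUCs are \code{NA} when all labels coincide.
#' @export
shared_indication_auc <- function(side_effects, indications) {
  if (is.matrix(side_effects)) {
    side_effects <- apply(side_effects > 0, 1L, function(r)
      colnames(side_effects)[r], simplify = FALSE)
  }
  drugs <- names(side_effects)
  stopifnot(length(drugs) >= 2L)
  cmb <- utils::combn(drugs, 2L)
  sim <- apply(cmb, 2L, function(p)
    jaccard(side_effects[[p[1]]], side_effects[[p[2]]]))
  lab <- apply(cmb, 2L, function(p)
    length(intersect(indications[[p[1]]], indications[[p[2]]])) > 0L)
  pairs <- data.frame(drug_a = cmb[1L, ], drug_b = cmb[2L, ],
                      similarity = sim, shared_indication = lab,
                      stringsAsFactors = FALSE)
  roc <- rank_auc(sim, lab)
  pr <- pr_auc(sim, lab)
  pv <- if (!is.na(roc)) {
    suppressWarnings(stats::wilcox.test(sim[lab], sim[!lab],
                                        alternative = "greater")$p.value)
  } else NA_real_
  structure(list(pairs = pairs, roc_auc = roc, pr_auc = pr, p_value = pv),
            class = "similarity_analysis")
}

#' @export
print.similarity_analysis <- function(x, ...) {
  cat(sprintf(
    "Shared-indication analysis on %d drug pairs: ROC AUC = %.3f, PR AUC = %.3f, p = %.3g\n",
    nrow(x$pairs), x$roc_auc, x$pr_auc, x$p_value))
  invisible(x)
}
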