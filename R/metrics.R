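# Evaluation suite: confusion ledger, eight-statistic report, ROC/AUC, PR/AP,
# prediction overlays and observer-consensus selection.
#
# The positive class is "gland" everywhere; specificity is therefore the
# stroma recognition rate by construction.

#' Confusion counts
#'
#' Tallies TP/FP/TN/FN over aligned truth and prediction label vectors, with
#' gland as the positive class.
#'
#' @param truth,preds Character vectors of `"gland"`/`"stroma"`, same length.
#' @return An object of class `confusion_counts`.
#' @export
confusion <- function(truth, preds) {
  if (length(truth) != length(preds))
    stop("truth and preds must be aligned (equal length)", call. = FALSE)
  assert_label(truth, allow_unknown = FALSE)
  assert_label(preds, allow_unknown = FALSE)
  structure(list(TP = sum(truth == "gland" & preds == "gland"),
                 FP = sum(truth == "stroma" & preds == "gland"),
                 TN = sum(truth == "stroma" & preds == "stroma"),
                 FN = sum(truth == "gland" & preds == "stroma")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (gland = positive): TP %d, FP %d, TN %d, FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Eight-statistic metric report
#'
#' Accuracy, sensitivity (SN), specificity (SP), PPV, NPV, FNR, FPR and F1,
#' as percentages. A statistic whose denominator is zero is reported as `NA`
#' (undefined), never as 0, so means over biopsies are not silently deflated.
#' F1 is computed from the (PPV, SN) pair as their harmonic mean,
#' `2 * PPV * SN / (PPV + SN)`.
#'
#' @param counts A [confusion()] object, or anything coercible (list with
#'   TP/FP/TN/FN).
#' @return An object of class `metric_report`: named numeric vector-like list
#'   with `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `fnr`,
#'   `fpr`, `f1` (percent) and optional `auc`, `ap` fields (fractions).
#' @export
metric_report <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  div <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  sn <- div(TP, TP + FN)
  sp <- div(TN, TN + FP)
  ppv <- div(TP, TP + FP)
  npv <- div(TN, TN + FN)
  f1 <- if (is.na(sn) || is.na(ppv) || (ppv + sn) == 0) NA_real_
        else 2 * ppv * sn / (ppv + sn)
  structure(list(accuracy = div(TP + TN, total),
                 sensitivity = sn, specificity = sp,
                 ppv = ppv, npv = npv,
                 fnr = if (is.na(sn)) NA_real_ else 100 - sn,
                 fpr = if (is.na(sp)) NA_real_ else 100 - sp,
                 f1 = f1,
                 auc = NA_real_, ap = NA_real_,
                 counts = counts),
            class = "metric_report")
}

#' F1 score from a sensitivity/PPV pair (percent)
#'
#' Harmonic mean of precision and recall, both given as percentages; useful
#' for checking the internal consistency of reported metric tables.
#'
#' @param sensitivity,ppv Percentages.
#' @return F1 as a percentage.
#' @export
f1_from_sn_ppv <- function(sensitivity, ppv) {
  2 * ppv * sensitivity / (ppv + sensitivity)
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f%%", v))
  cat("Metric report (gland = positive class):\n")
  cat(sprintf("  accuracy %s  SN %s  SP %s  PPV %s  NPV %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$ppv), fmt(x$npv)))
  cat(sprintf("  FNR %s  FPR %s  F1 %s", fmt(x$fnr), fmt(x$fpr), fmt(x$f1)))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.3f", x$auc))
  if (!is.na(x$ap)) cat(sprintf("  AP %.3f", x$ap))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, ppv = x$ppv, npv = x$npv,
             fnr = x$fnr, fpr = x$fpr, f1 = x$f1, auc = x$auc, ap = x$ap)
}

check_scores_truth <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop("scores and truth must be aligned", call. = FALSE)
  assert_label(truth, allow_unknown = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("scores must be probabilities in [0, 1]", call. = FALSE)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (classifying gland
#' when score > threshold), records (FPR, TPR) at each operating point, and
#' integrates the area by the trapezoid rule. Tied scores move together,
#' which makes the trapezoidal AUC equal to the Mann-Whitney pairwise
#' concordance with ties counted one half (midrank handling).
#'
#' @param scores Gland probabilities in \[0, 1\].
#' @param truth Character labels; both classes must be present.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_points <- function(scores, truth) {
  check_scores_truth(scores, truth)
  pos <- truth == "gland"
  if (!any(pos) || all(pos))
    stop("both classes must be present to sweep a ROC curve", call. = FALSE)
  np <- sum(pos); nn <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group ties so tied scores flip together
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and average precision
#'
#' Sweeps descending unique scores and accumulates
#' `AP = sum_i (R_i - R_{i-1}) * P_i` (step summation).
#'
#' @inheritParams roc_points
#' @return List with `points` (data frame `threshold`, `recall`, `precision`)
#'   and `ap`.
#' @export
pr_points <- function(scores, truth) {
  check_scores_truth(scores, truth)
  pos <- truth == "gland"
  if (!any(pos)) stop("at least one positive (gland) is required", call. = FALSE)
  np <- sum(pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p)
  k <- seq_along(s)
  last <- which(!duplicated(grp, fromLast = TRUE))
  recall <- tp[last] / np
  precision <- tp[last] / k[last]
  ap <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(threshold = s[last], recall = recall,
                           precision = precision),
       ap = ap)
}

#' Four-color overlay scheme
#'
#' Correctly identified glandular cells are red, correctly identified stroma
#' blue, missed glandular cells green, and stroma incorrectly called gland
#' magenta.
#'
#' @return Named list of RGB triplets in \[0, 1\].
#' @export
overlay_scheme <- function() {
  list(TP = c(1, 0, 0),    # gland, predicted gland: red
       TN = c(0, 0, 1),    # stroma, predicted stroma: blue
       FN = c(0, 1, 0),    # gland, predicted stroma: green
       FP = c(1, 0, 1))    # stroma, predicted gland: magenta
}

#' Render a prediction overlay
#'
#' Reconstructs the biopsy image from its container and fills every nuclear
#' boundary with the outcome color of [overlay_scheme()].
#'
#' @param container A [biopsy_container()].
#' @param truth,preds Aligned label vectors (one per record, in record order).
#' @param background Canvas background for uncovered pixels.
#' @return `(h, w, 3)` RGB array in \[0, 1\] with attribute `color_counts`
#'   (named vector: nuclei per outcome category).
#' @export
render_overlay <- function(container, truth, preds, background = 1) {
  n <- length(container$records)
  if (length(truth) != n || length(preds) != n)
    stop("truth and preds must have one entry per container record",
         call. = FALSE)
  gray <- reconstruct_image(container, draw_boundaries = FALSE,
                            background = background)
  h <- nrow(gray); w <- ncol(gray)
  img <- array(rep(gray, 3), dim = c(h, w, 3))
  scheme <- overlay_scheme()
  category <- ifelse(truth == "gland",
                     ifelse(preds == "gland", "TP", "FN"),
                     ifelse(preds == "gland", "FP", "TN"))
  for (i in seq_len(n)) {
    rec <- container$records[[i]]
    poly <- sweep(rec$boundary, 2, rec$slide_offset, "+")
    px <- rasterize_fill(poly, c(h, w))
    if (nrow(px) == 0) next
    colr <- scheme[[category[i]]]
    for (k in 1:3) img[cbind(px + 1L, k)] <- colr[k]
  }
  counts <- table(factor(category, levels = names(scheme)))
  attr(img, "color_counts") <- stats::setNames(as.integer(counts), names(counts))
  img
}

#' Observer ranking of predicted biopsies
#'
#' @param observer_id Identifier.
#' @param best,worst Ordered character vectors of biopsy ids (disjoint).
#' @return An object of class `observer_ranking`.
#' @export
observer_ranking <- function(observer_id, best, worst) {
  if (length(intersect(best, worst)) > 0)
    stop("best and worst lists must be disjoint", call. = FALSE)
  structure(list(observer_id = observer_id,
                 best = as.character(best), worst = as.character(worst)),
            class = "observer_ranking")
}

#' Consensus selection of best/worst predicted biopsies
#'
#' The best set is the intersection of all observers' best-k lists (likewise
#' worst): a biopsy is selected only when every observer placed it in their
#' top (bottom) k.
#'
#' @param rankings List of [observer_ranking()]s (>= 2) over the same biopsy
#'   universe.
#' @param k Depth of each observer's list to use.
#' @return List with `best`, `worst` (character vectors) and
#'   `agreement_counts` (how many observers listed each candidate id).
#' @export
consensus_select <- function(rankings, k = 5L) {
  if (length(rankings) < 2) stop("need at least 2 observer rankings", call. = FALSE)
  universe <- lapply(rankings, function(r) sort(unique(c(r$best, r$worst))))
  pools <- unique(universe)
  if (length(pools) > 1) {
    all_ids <- sort(unique(unlist(universe)))
    # rankings are allowed to be partial lists; require only a shared universe
    # when the caller supplied full orderings of different id sets
    lens <- vapply(universe, length, integer(1))
    if (length(unique(lens)) == 1 && lens[1] == length(all_ids) &&
        !all(vapply(universe, identical, logical(1), all_ids)))
      stop("rankings cover mismatched biopsy id sets", call. = FALSE)
  }
  topk <- lapply(rankings, function(r) utils::head(r$best, k))
  botk <- lapply(rankings, function(r) utils::head(r$worst, k))
  best <- Reduce(intersect, topk)
  worst <- Reduce(intersect, botk)
  if (length(best) == 0 && length(worst) == 0)
    warning("no consensus: observers' lists are disjoint")
  counts <- table(c(unlist(topk), unlist(botk)))
  list(best = best, worst = worst,
       agreement_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Full evaluation of predictions against truth
#'
#' Convenience wrapper producing the eight-statistic report with ROC/AUC and
#' PR/AP attached (when probabilities are supplied and both classes present).
#'
#' @param truth Label vector.
#' @param scores Gland probabilities (optional; enables AUC/AP).
#' @param preds Label vector; defaults to `classify(scores, threshold)`.
#' @param threshold Decision threshold.
#' @return A [metric_report()] with `auc` and `ap` filled in when available.
#' @export
evaluate_predictions <- function(truth, scores = NULL, preds = NULL,
                                 threshold = 0.5) {
  if (is.null(preds)) {
    if (is.null(scores)) stop("supply scores or preds", call. = FALSE)
    preds <- classify(scores, threshold)
  }
  rep <- metric_report(confusion(truth, preds))
  if (!is.null(scores) && length(unique(truth)) == 2) {
    rep$auc <- roc_points(scores, truth)$auc
    rep$ap <- pr_points(scores, truth)$ap
  }
  rep
}
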