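# Metric ledger, ROC/PR curves, overlays, consensus selection.

random_labels <- function(n, p = 0.4) {
  ifelse(runif(n) < p, "gland", "stroma")
}

test_that("confusion counts partition the input and match a per-item tally", {
  t1 <- rep("gland", 5)
  expect_equal(unclass(confusion(t1, t1))[c("FP", "FN")], list(FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  c2 <- confusion(rep("gland", 7), rep("stroma", 7))
  expect_equal(c2$TP, 0); expect_equal(c2$FN, 7)
  set.seed(10)
  truth <- random_labels(200); preds <- random_labels(200)
  cc <- confusion(truth, preds)
  tally <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:200) {
    key <- if (truth[i] == "gland" && preds[i] == "gland") "TP"
      else if (truth[i] == "stroma" && preds[i] == "gland") "FP"
      else if (truth[i] == "stroma" && preds[i] == "stroma") "TN"
      else "FN"
    tally[key] <- tally[key] + 1
  }
  expect_equal(unlist(unclass(cc)), tally)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 200)
  expect_error(confusion(truth, preds[-1]), "aligned")
})

# independently coded formula set (kept deliberately separate from metric_report)
report_oracle <- function(TP, FP, TN, FN) {
  pct <- function(x) 100 * x
  sn <- TP / (TP + FN); sp <- TN / (TN + FP)
  ppv <- TP / (TP + FP); npv <- TN / (TN + FN)
  c(accuracy = pct((TP + TN) / (TP + FP + TN + FN)),
    sensitivity = pct(sn), specificity = pct(sp),
    ppv = pct(ppv), npv = pct(npv),
    fnr = pct(FN / (TP + FN)), fpr = pct(FP / (TN + FP)),
    f1 = pct(2 * ppv * sn / (ppv + sn)))
}

test_that("metric formulas match a dual implementation on random tables", {
  set.seed(11)
  max_diff <- 0
  for (i in seq_len(2000)) {
    counts <- as.list(rpois(4, lambda = 20) + 1)
    names(counts) <- c("TP", "FP", "TN", "FN")
    rep <- metric_report(counts)
    oracle <- report_oracle(counts$TP, counts$FP, counts$TN, counts$FN)
    max_diff <- max(max_diff, abs(unlist(rep[names(oracle)]) - oracle))
  }
  expect_lt(max_diff, 1e-9)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(12)
  worst <- 0
  all_nonneg <- TRUE
  for (i in seq_len(10000)) {
    counts <- list(TP = rpois(1, 30) + 1, FP = rpois(1, 10) + 1,
                   TN = rpois(1, 40) + 1, FN = rpois(1, 8) + 1)
    r <- metric_report(counts)
    worst <- max(worst,
                 abs(r$fnr - (100 - r$sensitivity)),
                 abs(r$fpr - (100 - r$specificity)),
                 abs(r$f1 - 2 * r$ppv * r$sensitivity / (r$ppv + r$sensitivity)))
    all_nonneg <- all_nonneg &&
      all(unlist(r[c("accuracy", "sensitivity", "specificity",
                     "ppv", "npv", "fnr", "fpr", "f1")]) >= 0)
  }
  expect_lt(worst, 1e-9)
  expect_true(all_nonneg)
})

test_that("perfect predictions give 100% everywhere; zero denominators give NA", {
  r <- metric_report(list(TP = 50, FP = 0, TN = 50, FN = 0))
  for (k in c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1"))
    expect_equal(r[[k]], 100)
  expect_equal(r$fnr, 0); expect_equal(r$fpr, 0)
  # no positives in truth: SN, FNR undefined -- NA, never 0
  r2 <- metric_report(list(TP = 0, FP = 3, TN = 7, FN = 0))
  expect_true(is.na(r2$sensitivity))
  expect_true(is.na(r2$fnr))
  expect_false(is.na(r2$specificity))
  expect_error(metric_report(list(TP = 0, FP = 0, TN = 0, FN = 0)), "zero")
})

# O(n^2) pairwise-concordance oracle with half ties (Mann-Whitney)
auc_oracle <- function(scores, truth) {
  pos <- which(truth == "gland"); neg <- which(truth == "stroma")
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(pos) * length(neg))
}

test_that("trapezoidal AUC equals pairwise concordance with midrank ties", {
  hand_scores <- c(0.9, 0.8, 0.8, 0.7, 0.6, 0.55, 0.5, 0.5, 0.4, 0.3, 0.2, 0.1)
  hand_truth <- c("gland", "gland", "stroma", "gland", "stroma", "gland",
                  "stroma", "gland", "stroma", "stroma", "gland", "stroma")
  expect_equal(roc_points(hand_scores, hand_truth)$auc,
               auc_oracle(hand_scores, hand_truth))
  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    truth <- random_labels(n)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # include heavy ties
    expect_equal(roc_points(scores, truth)$auc, auc_oracle(scores, truth),
                 tolerance = 1e-12)
  }
  # degenerate and extreme cases
  sep_scores <- c(rep(0.9, 5), rep(0.1, 5))
  sep_truth <- rep(c("gland", "stroma"), each = 5)
  expect_equal(roc_points(sep_scores, sep_truth)$auc, 1)
  set.seed(14)
  null_scores <- runif(4000)
  null_truth <- random_labels(4000)
  expect_equal(roc_points(null_scores, null_truth)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_points(runif(5), rep("gland", 5)), "both classes")
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  truth <- random_labels(300)
  scores <- pmin(runif(300) + 0.3 * (truth == "gland"), 1)
  got <- roc_points(scores, truth)$auc
  want <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truth, levels = c("stroma", "gland")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

# exhaustive step-sum oracle for average precision
ap_oracle <- function(scores, truth) {
  ths <- sort(unique(scores), decreasing = TRUE)
  np <- sum(truth == "gland")
  prev_r <- 0; ap <- 0
  for (t in ths) {
    sel <- scores >= t
    tp <- sum(sel & truth == "gland")
    r <- tp / np; p <- tp / sum(sel)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

test_that("average precision matches the step-sum oracle and closed forms", {
  hand_scores <- c(0.9, 0.8, 0.8, 0.7, 0.6, 0.55, 0.5, 0.5, 0.4, 0.3, 0.2, 0.1)
  hand_truth <- c("gland", "gland", "stroma", "gland", "stroma", "gland",
                  "stroma", "gland", "stroma", "stroma", "gland", "stroma")
  expect_equal(pr_points(hand_scores, hand_truth)$ap,
               ap_oracle(hand_scores, hand_truth))
  # perfect ranking
  expect_equal(pr_points(c(0.9, 0.8, 0.2, 0.1),
                         c("gland", "gland", "stroma", "stroma"))$ap, 1)
  # all scores tied: single operating point, AP = prevalence
  truth <- rep(c("gland", "stroma"), c(30, 70))
  expect_equal(pr_points(rep(0.5, 100), truth)$ap, 0.3)
  set.seed(16)
  for (i in 1:20) {
    n <- sample(10:150, 1)
    truth <- random_labels(n)
    if (!any(truth == "gland")) next
    scores <- round(runif(n), 2)
    expect_equal(pr_points(scores, truth)$ap, ap_oracle(scores, truth),
                 tolerance = 1e-12)
  }
  expect_error(pr_points(runif(4), rep("stroma", 4)), "positive")
})

test_that("overlays color nuclei by outcome and count them exactly", {
  sc <- tiny_scene(seed = 17)
  ct <- scene_container(sc)
  truth <- sc$labels
  # all-correct: only red (TP) and blue (TN)
  ov <- render_overlay(ct, truth, truth)
  counts <- attr(ov, "color_counts")
  expect_equal(unname(counts["FN"] + counts["FP"]), 0L)
  expect_equal(sum(counts), length(ct$records))
  expect_equal(unname(counts["TP"]), sum(truth == "gland"))
  # flipping one gland prediction turns exactly one nucleus red -> green
  preds <- truth
  flip <- which(truth == "gland")[1]
  preds[flip] <- "stroma"
  ov2 <- render_overlay(ct, truth, preds)
  counts2 <- attr(ov2, "color_counts")
  expect_equal(unname(counts2["TP"]), unname(counts["TP"]) - 1L)
  expect_equal(unname(counts2["FN"]), 1L)
  # the recolored pixels are exactly the flipped nucleus's fill
  diffpx <- which(ov != ov2, arr.ind = TRUE)
  rec <- ct$records[[flip]]
  poly <- sweep(rec$boundary, 2, rec$slide_offset, "+")
  fill <- rasterize_fill(poly, dim(sc$image))
  expect_setequal(unique(paste(diffpx[, 1], diffpx[, 2])),
                  paste(fill[, 1] + 1, fill[, 2] + 1))
  # confusion counts match the color ledger
  cc <- confusion(truth, preds)
  expect_equal(unname(counts2), c(cc$TP, cc$TN, cc$FN, cc$FP),
               ignore_attr = TRUE)
})

test_that("consensus selection intersects observer lists", {
  r1 <- observer_ranking("o1", best = c("a", "b", "c", "d", "e"),
                         worst = c("u", "v", "w", "x", "y"))
  r2 <- observer_ranking("o2", best = c("c", "a", "z", "b", "q"),
                         worst = c("x", "u", "w", "m", "n"))
  r3 <- observer_ranking("o3", best = c("b", "c", "a", "r", "s"),
                         worst = c("w", "x", "u", "t", "p"))
  sel <- consensus_select(list(r1, r2, r3), k = 5)
  expect_setequal(sel$best, c("a", "b", "c"))
  expect_setequal(sel$worst, c("u", "w", "x"))
  # identical rankings intersect to themselves
  sel2 <- consensus_select(list(r1, r1, r1), k = 5)
  expect_setequal(sel2$best, r1$best)
  # disjoint rankings give empty sets with a warning
  r4 <- observer_ranking("o4", best = c("m", "n"), worst = c("o", "p"))
  r5 <- observer_ranking("o5", best = c("q", "r"), worst = c("s", "t"))
  expect_warning(sel3 <- consensus_select(list(r4, r5), k = 2), "no consensus")
  expect_length(sel3$best, 0)
  expect_error(consensus_select(list(r1), k = 5), "at least 2")
  expect_error(observer_ranking("o", c("a", "b"), c("b", "c")), "disjoint")
})

test_that("evaluate_predictions attaches AUC and AP to the ledger", {
  set.seed(18)
  truth <- random_labels(120)
  scores <- pmin(pmax(runif(120) + 0.4 * (truth == "gland"), 0), 1)
  r <- evaluate_predictions(truth, scores = scores)
  expect_false(is.na(r$auc))
  expect_false(is.na(r$ap))
  expect_gt(r$auc, 0.5)
  expect_equal(r$counts$TP + r$counts$FP + r$counts$TN + r$counts$FN, 120)
})
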