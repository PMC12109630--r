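# Two-round false-positive-relabeling semi-supervised training.
#
# Round 1 trains on the human annotations. Validation nuclei whose annotated
# label is stroma but whose round-1 prediction is gland (false positives
# against the annotation) are harvested and added to the training set as
# positives, compensating for one-sided annotation misses (true gland nuclei
# annotated stroma). Round 2 retrains from scratch on the augmented set.

#' Harvest annotation-relative false positives
#'
#' Returns exactly the ids whose annotated label is stroma and whose
#' prediction is gland.
#'
#' @param labels Character annotation labels.
#' @param preds Character predicted labels, aligned with `labels`.
#' @param ids Identifiers aligned with `labels` (default positional indices).
#' @return Subset of `ids`.
#' @export
harvest_false_positives <- function(labels, preds, ids = seq_along(labels)) {
  n_ids <- if (is.data.frame(ids)) nrow(ids) else length(ids)
  if (length(labels) != length(preds) || n_ids != length(labels))
    stop("labels, preds and ids must be aligned", call. = FALSE)
  assert_label(labels)
  assert_label(preds, allow_unknown = FALSE)
  if (is.data.frame(ids)) ids[labels == "stroma" & preds == "gland", , drop = FALSE]
  else ids[labels == "stroma" & preds == "gland"]
}

#' Relabel the training set with harvested pseudo-positives
#'
#' In the default `"add-val-fps-to-train"` mode the harvested validation
#' nuclei are appended to the training label table with label gland and
#' provenance `"round-1-pseudo"`; the original human labels are kept
#' immutably in the `human_label` column. In `"relabel-in-place"` mode
#' harvested ids must already exist in the table and have their label flipped
#' to gland (provenance updated, human label retained).
#'
#' @param train_labels Data frame with columns `biopsy_id`, `nucleus_id`,
#'   `label`, and optionally `human_label`, `provenance`.
#' @param harvested Data frame with columns `biopsy_id`, `nucleus_id` and,
#'   for the default mode, `human_label` (the annotation of the harvested
#'   nucleus).
#' @param mode `"add-val-fps-to-train"` (default) or `"relabel-in-place"`.
#' @return The augmented label table.
#' @export
relabel_training <- function(train_labels, harvested,
                             mode = c("add-val-fps-to-train", "relabel-in-place")) {
  mode <- match.arg(mode)
  if (is.null(train_labels$human_label)) train_labels$human_label <- train_labels$label
  if (is.null(train_labels$provenance)) train_labels$provenance <- "human"
  if (nrow(harvested) == 0) return(train_labels)
  key <- function(d) paste(d$biopsy_id, d$nucleus_id)
  if (anyDuplicated(key(harvested)))
    stop("harvested set contains duplicate ids", call. = FALSE)
  if (mode == "add-val-fps-to-train") {
    if (any(key(harvested) %in% key(train_labels)))
      stop("harvested ids collide with existing training nuclei", call. = FALSE)
    add <- data.frame(biopsy_id = harvested$biopsy_id,
                      nucleus_id = harvested$nucleus_id,
                      label = "gland",
                      human_label = harvested$human_label %||% "stroma",
                      provenance = "round-1-pseudo")
    rbind(train_labels[c("biopsy_id", "nucleus_id", "label",
                         "human_label", "provenance")], add)
  } else {
    hit <- match(key(harvested), key(train_labels))
    if (anyNA(hit))
      stop("relabel-in-place: harvested ids not found in training table",
           call. = FALSE)
    train_labels$label[hit] <- "gland"
    train_labels$provenance[hit] <- "round-1-pseudo"
    train_labels
  }
}

containers_label_table <- function(containers) {
  do.call(rbind, lapply(containers, function(ct) {
    data.frame(biopsy_id = ct$biopsy_id,
               nucleus_id = vapply(ct$records, function(r) r$nucleus_id, integer(1)),
               label = vapply(ct$records, function(r) r$label, character(1)))
  }))
}

#' Run the two-round semi-supervised training procedure
#'
#' Round 1 trains on the human annotations in the training containers. The
#' round-1 model predicts every validation nucleus; predictions are
#' thresholded at `harvest_threshold` and annotation-relative false positives
#' are harvested and appended to the training set as gland (hard pseudo-labels
#' by default). Round 2 trains a freshly initialized model (same
#' initialization scheme and seed; set `warm_start = TRUE` to continue from
#' the round-1 weights) on the augmented set. Both rounds keep the
#' final-epoch weights unless the config says otherwise.
#'
#' @param train,val Lists of labeled [biopsy_container()]s; cohorts must be
#'   disjoint at the biopsy level.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param harvest_threshold Threshold for harvesting (defaults to the
#'   config's decision threshold, 0.5).
#' @param warm_start Initialize round 2 from the round-1 weights instead of
#'   retraining from scratch.
#' @param soft_labels Weight each harvested pseudo-positive by its round-1
#'   predicted gland probability instead of weight 1.
#' @param rounds Number of rounds (default 2, the reference procedure; more
#'   rounds generalize the loop).
#' @param track_validation Record per-epoch validation metrics in the
#'   training history (slower).
#' @return List of class `semisup_fit`: `model` (the final-round fit),
#'   `models` (per round), `ledgers` (one `round_ledger` per round; see
#'   Details), and `val_ids` (biopsy/nucleus id table of the validation
#'   cohort, aligned with the per-round stored probabilities).
#'
#' @details Each ledger records: `round_index`, `train_positive_count`,
#' `train_negative_count`, `harvested_fp_ids` (ids harvested *from* this
#' round's validation predictions), `metrics` (validation [metric_report()]
#' against the annotations), `val_probs` (per-nucleus gland probabilities),
#' and the provenance table of the training labels used in the round.
#' @export
run_two_rounds <- function(train, val, spec = model_spec(),
                           config = train_config(),
                           harvest_threshold = NULL,
                           warm_start = FALSE,
                           soft_labels = FALSE,
                           rounds = 2L,
                           track_validation = FALSE) {
  if (inherits(train, "biopsy_container")) train <- list(train)
  if (inherits(val, "biopsy_container")) val <- list(val)
  train_biopsies <- vapply(train, function(ct) ct$biopsy_id, character(1))
  val_biopsies <- vapply(val, function(ct) ct$biopsy_id, character(1))
  if (length(intersect(train_biopsies, val_biopsies)) > 0)
    stop("training and validation cohorts must be disjoint at the biopsy level",
         call. = FALSE)
  tau <- harvest_threshold %||% config$decision_threshold

  tr_dat <- as_patch_array(train)
  va_dat <- as_patch_array(val)
  label_table <- containers_label_table(train)
  label_table$human_label <- label_table$label
  label_table$provenance <- "human"

  x <- tr_dat$x
  labels <- label_table$label
  sample_w <- rep(1, length(labels))

  ledgers <- list()
  models <- list()
  model <- NULL
  for (round in seq_len(rounds)) {
    # quality gate, mirroring the observer review between rounds: the round's
    # validation predictions must beat a constant predictor against the
    # annotations (balanced accuracy >= 0.6); a near-constant collapsed fit
    # sits at 0.5 and is retried from a fresh seeded initialization
    for (attempt in 0:3) {
      cfg_a <- config
      cfg_a$seed <- config$seed + 7919L * attempt
      fit <- glandnet(x, labels, spec = spec, config = cfg_a,
                      validation = if (track_validation) va_dat$x else NULL,
                      validation_labels = if (track_validation) va_dat$labels else NULL,
                      model = if (warm_start && !is.null(model)) model else NULL,
                      sample_weights = if (any(sample_w != 1)) sample_w else NULL)
      val_probs <- predict(fit, va_dat$x, type = "prob")
      val_preds <- classify(val_probs, tau)
      cc <- confusion(va_dat$labels, val_preds)
      sn <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA
      sp <- if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else NA
      bal <- mean(c(sn, sp), na.rm = TRUE)
      if (is.na(bal) || bal >= 0.6) break
      if (attempt < 3)
        warning(sprintf("round %d: validation balanced accuracy %.2f vs annotations (collapsed fit); restarting (attempt %d)",
                        round, bal, attempt + 1L), call. = FALSE)
    }
    model <- fit
    models[[round]] <- fit
    metrics <- evaluate_predictions(va_dat$labels, scores = val_probs,
                                    preds = val_preds)

    harvested <- harvest_false_positives(va_dat$labels, val_preds, va_dat$ids)
    harvested$human_label <- rep("stroma", nrow(harvested))
    harvested$prob <- val_probs[va_dat$labels == "stroma" & val_preds == "gland"]

    ledgers[[round]] <- structure(list(
      round_index = round,
      train_positive_count = sum(labels == "gland"),
      train_negative_count = sum(labels == "stroma"),
      harvested_fp_ids = harvested[c("biopsy_id", "nucleus_id")],
      metrics = metrics,
      val_probs = val_probs,
      provenance = label_table
    ), class = "round_ledger")

    if (round == rounds) break

    if (nrow(harvested) == 0) {
      warning(sprintf("round %d harvested no false positives; next round degenerates to retraining",
                      round))
    } else {
      label_table <- relabel_training(label_table, harvested)
      # append the harvested validation patches to the training tensor
      sel <- which(paste(va_dat$ids$biopsy_id, va_dat$ids$nucleus_id) %in%
                     paste(harvested$biopsy_id, harvested$nucleus_id))
      x2 <- array(0, dim = dim(x) + c(0, 0, length(sel)))
      x2[, , seq_len(dim(x)[3])] <- x
      x2[, , dim(x)[3] + seq_along(sel)] <- va_dat$x[, , sel, drop = FALSE]
      x <- x2
      labels <- label_table$label
      sample_w <- c(sample_w,
                    if (soft_labels) harvested$prob else rep(1, length(sel)))
    }
  }

  structure(list(model = model, models = models, ledgers = ledgers,
                 val_ids = va_dat$ids, harvest_threshold = tau),
            class = "semisup_fit")
}

#' @export
print.semisup_fit <- function(x, ...) {
  cat(sprintf("Two-round semi-supervised fit (%d rounds)\n", length(x$ledgers)))
  for (led in x$ledgers) {
    m <- led$metrics
    cat(sprintf("  round %d: train +%d/-%d, harvested %d, val FNR %.1f%%, FPR %.1f%%\n",
                led$round_index, led$train_positive_count,
                led$train_negative_count, nrow(led$harvested_fp_ids),
                m$fnr, m$fpr))
  }
  invisible(x)
}

#' Persist a round ledger
#'
#' Writes the ledger as JSON (counts, harvested ids) plus a per-nucleus CSV
#' audit table of training-label provenance.
#'
#' @param ledger A `round_ledger` from [run_two_rounds()].
#' @param path Output path without extension; `.json` and `.csv` are added.
#' @return The JSON path, invisibly.
#' @export
write_round_ledger <- function(ledger, path) {
  out <- list(round_index = ledger$round_index,
              train_positive_count = ledger$train_positive_count,
              train_negative_count = ledger$train_negative_count,
              harvested_fp_ids = ledger$harvested_fp_ids,
              metrics = as.data.frame(ledger$metrics))
  jsonlite::write_json(out, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(ledger$provenance, paste0(path, ".csv"), row.names = FALSE)
  invisible(paste0(path, ".json"))
}
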