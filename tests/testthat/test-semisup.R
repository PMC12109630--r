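# False-positive harvesting, relabeling bookkeeping, and the two-round loop.

test_that("harvesting returns exactly the annotation-relative false positives", {
  labels <- c("stroma", "gland", "stroma", "stroma", "gland",
              "stroma", "stroma", "gland", "stroma", "stroma")
  preds <- c("gland", "gland", "stroma", "gland", "stroma",
             "stroma", "gland", "gland", "stroma", "stroma")
  # exhaustive enumeration oracle
  want <- which(labels == "stroma" & preds == "gland")
  expect_equal(harvest_false_positives(labels, preds), want)
  expect_equal(want, c(1L, 4L, 7L))
  # vacuous cases
  expect_length(harvest_false_positives(rep("gland", 10), preds), 0)
  expect_length(harvest_false_positives(labels, rep("stroma", 10)), 0)
  expect_error(harvest_false_positives(labels, preds[-1]), "aligned")
  # data-frame ids subset by row
  ids <- data.frame(biopsy_id = "b", nucleus_id = 1:10)
  got <- harvest_false_positives(labels, preds, ids)
  expect_equal(got$nucleus_id, want)
})

test_that("relabeling appends pseudo-positives with immutable provenance", {
  train <- data.frame(biopsy_id = "t1", nucleus_id = 1:10,
                      label = rep(c("gland", "stroma"), 5))
  harvested0 <- data.frame(biopsy_id = character(0), nucleus_id = integer(0))
  expect_equal(nrow(relabel_training(train, harvested0)), 10)

  harvested <- data.frame(biopsy_id = "v1", nucleus_id = 1:50,
                          human_label = "stroma")
  out <- relabel_training(train, harvested)
  expect_equal(nrow(out), 60)
  expect_equal(sum(out$label == "gland"), sum(train$label == "gland") + 50)
  # provenance round-trip: pseudo-label recorded, human label retrievable
  added <- out[out$provenance == "round-1-pseudo", ]
  expect_equal(nrow(added), 50)
  expect_true(all(added$label == "gland"))
  expect_true(all(added$human_label == "stroma"))
  expect_true(all(out$provenance[1:10] == "human"))
  # collisions are rejected
  clash <- data.frame(biopsy_id = "t1", nucleus_id = 2, human_label = "stroma")
  expect_error(relabel_training(train, clash), "collide")
  # in-place mode flips labels without adding rows
  inplace <- relabel_training(train,
                              data.frame(biopsy_id = "t1", nucleus_id = c(2, 4)),
                              mode = "relabel-in-place")
  expect_equal(nrow(inplace), 10)
  expect_equal(inplace$label[c(2, 4)], c("gland", "gland"))
  expect_equal(inplace$human_label[c(2, 4)], c("stroma", "stroma"))
})

test_that("two rounds conserve the training set and relabel one-sidedly", {
  tr <- corrupted_scene_container(301, q = 0.3, biopsy_id = "train-1")
  va <- corrupted_scene_container(302, q = 0.3, biopsy_id = "val-1")
  ss <- suppressWarnings(
    run_two_rounds(tr$ct, va$ct, spec = desk_spec(),
                   config = desk_config(seed = 2, epochs = 6L)))
  expect_length(ss$ledgers, 2)
  l1 <- ss$ledgers[[1]]; l2 <- ss$ledgers[[2]]
  h <- nrow(l1$harvested_fp_ids)
  # conservation: round-2 set = round-1 set plus the harvest, nothing deleted
  expect_equal(l2$train_positive_count, l1$train_positive_count + h)
  expect_equal(l2$train_negative_count, l1$train_negative_count)
  # one-sidedness: relabeling only creates positives
  prov <- l2$provenance
  pseudo <- prov[prov$provenance == "round-1-pseudo", ]
  expect_equal(nrow(pseudo), h)
  expect_true(all(pseudo$label == "gland"))
  expect_true(all(pseudo$human_label == "stroma"))
  expect_true(all(prov$label[prov$provenance == "human"] ==
                  prov$human_label[prov$provenance == "human"]))
  # harvested ids are unique and drawn from the validation biopsy
  expect_false(anyDuplicated(paste(l1$harvested_fp_ids$biopsy_id,
                                   l1$harvested_fp_ids$nucleus_id)) > 0)
  if (h > 0) expect_true(all(l1$harvested_fp_ids$biopsy_id == "val-1"))
  # per-round validation probabilities are aligned with the id table
  expect_length(l1$val_probs, nrow(ss$val_ids))
  expect_length(l2$val_probs, nrow(ss$val_ids))
})

test_that("cohort overlap is rejected", {
  tr <- corrupted_scene_container(303, q = 0.1, biopsy_id = "same")
  expect_error(run_two_rounds(tr$ct, tr$ct, spec = desk_spec(),
                              config = desk_config(seed = 1, epochs = 1L)),
               "disjoint")
})

test_that("round ledgers persist as JSON plus a CSV audit table", {
  tr <- corrupted_scene_container(304, q = 0.2, biopsy_id = "train-1")
  va <- corrupted_scene_container(305, q = 0.2, biopsy_id = "val-1")
  ss <- suppressWarnings(
    run_two_rounds(tr$ct, va$ct, spec = desk_spec(),
                   config = desk_config(seed = 3, epochs = 5L)))
  dir <- withr::local_tempdir()
  path <- write_round_ledger(ss$ledgers[[1]], file.path(dir, "round-1"))
  expect_true(file.exists(path))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$round_index, 1)
  expect_equal(back$train_positive_count, ss$ledgers[[1]]$train_positive_count)
  audit <- read.csv(file.path(dir, "round-1.csv"))
  expect_equal(nrow(audit), length(tr$ct$records))
})
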