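# End-to-end orchestration: synthetic demo, prepare, train, predict, evaluate.
#
# Workdir layout (fixed):
#   scenes/<biopsy>/         rendered scene interchange files + truth
#   containers/<biopsy>.cmg  per-biopsy containers (annotation labels)
#   model/                   checkpoint (RDS) + topology JSON + history CSV
#   ledgers/                 per-round JSON/CSV ledgers + round diff
#   reports/                 per-biopsy and pooled metric reports (CSV/JSON)
#   overlays/                PNG prediction overlays
#   manifest.json            config echo, seeds, versions

#' Demo/pipeline run configuration
#'
#' @param n_train,n_val,n_test Number of synthetic biopsies per cohort.
#' @param scene A [scene_spec()] used as the per-biopsy template (each biopsy
#'   re-seeds it deterministically from `seed`).
#' @param miss_fraction One-sided annotation-miss rate q applied to the
#'   train/validation annotations (test biopsies keep true labels, standing
#'   in for the hand-annotated evaluation set).
#' @param patch_size Patch edge length (must be divisible by 32).
#' @param spec A [model_spec()] (desk-scale default: width 1/8, 64-px input).
#' @param config A [train_config()] (desk-scale default: faster learning rate
#'   and fewer epochs than the full-size recipe).
#' @param seed Master seed; all per-biopsy and training seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_train = 2L, n_val = 1L, n_test = 1L,
                       scene = scene_spec(),
                       miss_fraction = 0.3,
                       patch_size = 64L,
                       spec = NULL,
                       config = NULL,
                       seed = 1L) {
  if (patch_size %% 32L != 0L)
    stop("patch_size must be divisible by 32", call. = FALSE)
  spec <- spec %||% model_spec(input_size = patch_size, width_scale = 1 / 8,
                               noise_sigma = 0.15, allow_any_input = TRUE)
  config <- config %||% train_config(learning_rate = 3e-4, batch_size = 8L,
                                     epochs = 12L, lr_schedule = "step",
                                     seed = seed,
                                     augment_policy = augment_policy(
                                       rotation_degrees = 0,
                                       zoom_fraction = 0,
                                       width_shift_fraction = 0,
                                       height_shift_fraction = 0))
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), scene = scene,
                 miss_fraction = miss_fraction,
                 patch_size = as.integer(patch_size),
                 spec = spec, config = config, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; `scene`, `spec` and
#' `config` keys hold nested argument lists for [scene_spec()],
#' [model_spec()] and [train_config()].
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("n_train", "n_val", "n_test",
                                  "miss_fraction", "patch_size", "seed"))]
  if (!is.null(y$scene)) args$scene <- do.call(scene_spec, y$scene)
  if (!is.null(y$spec)) {
    y$spec$allow_any_input <- y$spec$allow_any_input %||% TRUE
    args$spec <- do.call(model_spec, y$spec)
  }
  if (!is.null(y$config)) args$config <- do.call(train_config, y$config)
  do.call(run_config, args)
}

demo_biopsy_ids <- function(rc) {
  n <- rc$n_train + rc$n_val + rc$n_test
  sprintf("synthetic-%02d", seq_len(n))
}

demo_cohorts <- function(rc) {
  ids <- demo_biopsy_ids(rc)
  list(train = ids[seq_len(rc$n_train)],
       val = ids[rc$n_train + seq_len(rc$n_val)],
       test = ids[rc$n_train + rc$n_val + seq_len(rc$n_test)])
}

#' Save / load a GlandNet checkpoint
#'
#' The weights and fit metadata are serialized (RDS) alongside a JSON topology
#' descriptor and the training history as CSV.
#'
#' @param model A `glandnet` object.
#' @param dir Checkpoint directory (created).
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(input_size = model$spec$input_size,
         width_scale = model$spec$width_scale,
         conv_widths = model$spec$conv_widths,
         head_widths = model$spec$head_widths,
         noise_sigma = model$spec$noise_sigma,
         layers = glandnet_layers(model$spec)),
    file.path(dir, "topology.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (!is.null(model$history))
    utils::write.csv(model$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) readRDS(file.path(dir, "model.rds"))

stage_error <- function(stage, what) {
  stop(sprintf("stage '%s': missing upstream artifact: %s", stage, what),
       call. = FALSE)
}

#' Run one pipeline stage
#'
#' Stages are composable over a shared `workdir`:
#' `prepare` renders the synthetic biopsies and writes one container per
#' biopsy; `train` runs the two-round procedure on the prepared train/val
#' containers; `predict` applies the checkpoint to the test containers;
#' `evaluate` writes metric reports and overlays for the predictions.
#'
#' @param stage One of `"prepare"`, `"train"`, `"predict"`, `"evaluate"`.
#' @param config A [run_config()].
#' @param workdir Working directory.
#' @return Stage-specific artifact summary, invisibly.
#' @export
run_stage <- function(stage = c("prepare", "train", "predict", "evaluate"),
                      config = run_config(), workdir) {
  stage <- match.arg(stage)
  rc <- config
  cohorts <- demo_cohorts(rc)
  cdir <- file.path(workdir, "containers")
  switch(stage,
    prepare = {
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      ids <- demo_biopsy_ids(rc)
      truth <- list()
      for (b in seq_along(ids)) {
        sc_spec <- rc$scene
        sc_spec$seed <- rc$seed * 1000L + b
        scene <- render_scene(sc_spec)
        sdir <- file.path(workdir, "scenes", ids[b])
        write_scene(scene, sdir)
        labels <- scene$labels
        flipped <- integer(0)
        if (ids[b] %in% c(cohorts$train, cohorts$val) && rc$miss_fraction > 0) {
          noisy <- inject_annotation_misses(labels, rc$miss_fraction,
                                            seed = sc_spec$seed + 500L)
          labels <- noisy$labels
          flipped <- noisy$flipped
        }
        utils::write.csv(
          data.frame(nucleus_id = vapply(scene$nuclei, function(n) n$nucleus_id,
                                         integer(1)),
                     true_label = scene$labels, annotation = labels,
                     flipped = seq_along(labels) %in% flipped),
          file.path(sdir, "truth.csv"), row.names = FALSE)
        ct <- build_biopsy_container(scene$image, scene$nuclei, scene$glands,
                                     rc$patch_size, biopsy_id = ids[b],
                                     labels = labels)
        write_container(ct, file.path(cdir, paste0(ids[b], ".cmg")))
      }
      message(sprintf("prepare: %d containers under %s", length(ids), cdir))
      invisible(cdir)
    },
    train = {
      paths <- file.path(cdir, paste0(c(cohorts$train, cohorts$val), ".cmg"))
      missing <- paths[!file.exists(paths)]
      if (length(missing)) stage_error("train", paste(missing, collapse = ", "))
      train_ct <- lapply(file.path(cdir, paste0(cohorts$train, ".cmg")),
                         read_container)
      val_ct <- lapply(file.path(cdir, paste0(cohorts$val, ".cmg")),
                       read_container)
      ss <- run_two_rounds(train_ct, val_ct, spec = rc$spec, config = rc$config)
      write_model(ss$model, file.path(workdir, "model"))
      ldir <- file.path(workdir, "ledgers")
      dir.create(ldir, recursive = TRUE, showWarnings = FALSE)
      for (led in ss$ledgers)
        write_round_ledger(led, file.path(ldir, sprintf("round-%d", led$round_index)))
      diff <- do.call(rbind, lapply(ss$ledgers, function(l)
        cbind(round = l$round_index, as.data.frame(l$metrics),
              harvested = nrow(l$harvested_fp_ids))))
      utils::write.csv(diff, file.path(ldir, "round_diff.csv"), row.names = FALSE)
      saveRDS(ss, file.path(workdir, "model", "semisup.rds"))
      message(sprintf("train: %d rounds, final harvest %d",
                      length(ss$ledgers),
                      nrow(ss$ledgers[[length(ss$ledgers)]]$harvested_fp_ids)))
      invisible(ss)
    },
    predict = {
      mdir <- file.path(workdir, "model", "model.rds")
      if (!file.exists(mdir)) stage_error("predict", mdir)
      model <- read_model(file.path(workdir, "model"))
      out <- list()
      for (id in cohorts$test) {
        p <- file.path(cdir, paste0(id, ".cmg"))
        if (!file.exists(p)) stage_error("predict", p)
        ct <- read_container(p)
        if (ct$patch_size != model$spec$input_size)
          stop(sprintf("predict: container '%s' has patch size %d but the model expects %d",
                       id, ct$patch_size, model$spec$input_size), call. = FALSE)
        ct <- predict_proba(model, ct)
        write_container(ct, p)
        write_nucleus_table(ct, file.path(cdir, paste0(id, "_predictions.csv")))
        out[[id]] <- ct
      }
      message(sprintf("predict: %d test containers scored", length(out)))
      invisible(out)
    },
    evaluate = {
      rdir <- file.path(workdir, "reports")
      odir <- file.path(workdir, "overlays")
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      dir.create(odir, recursive = TRUE, showWarnings = FALSE)
      tau <- rc$config$decision_threshold
      rows <- list()
      for (id in cohorts$test) {
        p <- file.path(cdir, paste0(id, ".cmg"))
        if (!file.exists(p)) stage_error("evaluate", p)
        ct <- read_container(p)
        probs <- vapply(ct$records, function(r) r$prediction, numeric(1))
        if (anyNA(probs)) stage_error("evaluate", paste0("predictions in ", p))
        truth <- vapply(ct$records, function(r) r$label, character(1))
        rep <- evaluate_predictions(truth, scores = probs, threshold = tau)
        rows[[id]] <- cbind(biopsy_id = id, as.data.frame(rep))
        ov <- render_overlay(ct, truth, classify(probs, tau))
        write_raster(ov, file.path(odir, paste0(id, "_overlay.png")))
        roc <- roc_points(probs, truth)
        utils::write.csv(roc$points, file.path(rdir, paste0(id, "_roc.csv")),
                         row.names = FALSE)
        pr <- pr_points(probs, truth)
        utils::write.csv(pr$points, file.path(rdir, paste0(id, "_pr.csv")),
                         row.names = FALSE)
      }
      per_biopsy <- do.call(rbind, rows)
      utils::write.csv(per_biopsy, file.path(rdir, "per_biopsy.csv"),
                       row.names = FALSE)
      jsonlite::write_json(per_biopsy, file.path(rdir, "per_biopsy.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      message(sprintf("evaluate: %d biopsies reported", nrow(per_biopsy)))
      invisible(per_biopsy)
    })
}

#' Run the full synthetic demo pipeline
#'
#' Renders synthetic biopsies, corrupts the train/validation annotations with
#' one-sided misses, builds containers, runs the two-round semi-supervised
#' training, predicts and evaluates the test cohort, and writes all artifacts
#' plus a reproducibility manifest under `workdir`. Deterministic under
#' `config$seed`.
#'
#' @param config A [run_config()].
#' @param workdir Output directory (created).
#' @return The per-biopsy test report data frame, invisibly.
#' @export
run_demo <- function(config = run_config(), workdir) {
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  run_stage("prepare", config, workdir)
  run_stage("train", config, workdir)
  run_stage("predict", config, workdir)
  report <- run_stage("evaluate", config, workdir)
  deep_unclass <- function(x) {
    x <- unclass(x)
    if (is.list(x)) lapply(x, deep_unclass) else x
  }
  cfg_plain <- deep_unclass(config)
  tmp <- tempfile()
  saveRDS(cfg_plain, tmp)
  manifest <- list(package = "glandcell",
                   version = as.character(utils::packageVersion("glandcell")),
                   r_version = R.version.string,
                   seed = config$seed,
                   config_hash = unname(tools::md5sum(tmp)),
                   config = cfg_plain)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(workdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Side-by-side patch-size comparison
#'
#' Runs the full pipeline once per patch size on the same scenes and seeds
#' and emits a side-by-side test report, the harness used to compare
#' patch-size context effects.
#'
#' @param config A [run_config()]; its `patch_size` is overridden.
#' @param workdir Output directory; one subdirectory per size.
#' @param sizes Patch sizes to compare.
#' @return Data frame with one report row per biopsy and size.
#' @export
compare_patch_sizes <- function(config = run_config(), workdir,
                                sizes = c(128L, 256L)) {
  out <- list()
  for (s in sizes) {
    rc <- config
    rc$patch_size <- as.integer(s)
    rc$spec <- model_spec(input_size = as.integer(s),
                          width_scale = rc$spec$width_scale,
                          noise_sigma = rc$spec$noise_sigma,
                          allow_any_input = TRUE)
    sub <- file.path(workdir, sprintf("patch-%d", s))
    rep <- run_demo(rc, sub)
    out[[as.character(s)]] <- cbind(patch_size = s, rep)
  }
  res <- do.call(rbind, out)
  utils::write.csv(res, file.path(workdir, "patch_size_comparison.csv"),
                   row.names = FALSE)
  res
}
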