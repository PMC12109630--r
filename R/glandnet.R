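#' Numerically stable softmax
#'
#' Maps a finite real vector of logits to a probability vector:
#' `exp(y_i) / sum_j exp(y_j)`, computed after subtracting the maximum logit
#' so that large magnitudes cannot overflow.
#'
#' @param logits Numeric vector of finite values (length >= 1).
#' @return Probability vector of the same length, summing to 1.
#' @export
softmax <- function(logits) {
  if (length(logits) == 0) stop("logits must be non-empty", call. = FALSE)
  if (!all(is.finite(logits))) stop("logits must be finite", call. = FALSE)
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Weighted categorical cross-entropy
#'
#' `-sum_i w_i * y_i * log(p_i)` for a one-hot truth vector `y`, predicted
#' probabilities `p` and positive per-class weights `w`. Probabilities are
#' clipped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param true_onehot One-hot numeric vector (exactly one 1, rest 0).
#' @param probs Probability vector of the same length.
#' @param class_weights Positive weights of the same length (default all 1).
#' @param eps Clipping constant.
#' @return Non-negative loss scalar; 0 iff the true class has probability 1.
#' @export
weighted_ce <- function(true_onehot, probs,
                        class_weights = rep(1, length(probs)), eps = 1e-12) {
  n <- length(probs)
  if (length(true_onehot) != n || length(class_weights) != n)
    stop("true_onehot, probs and class_weights must have equal length",
         call. = FALSE)
  if (any(class_weights <= 0)) stop("class_weights must be > 0", call. = FALSE)
  if (!isTRUE(all.equal(sort(unique(true_onehot)), c(0, 1))) ||
      sum(true_onehot) != 1)
    stop("true_onehot must be a one-hot vector", call. = FALSE)
  p <- pmin(pmax(probs, eps), 1 - eps)
  -sum(class_weights * true_onehot * log(p))
}

#' Threshold a gland probability into a class label
#'
#' A nucleus is called `"gland"` when its predicted gland probability strictly
#' exceeds the threshold tau, and `"stroma"` otherwise (a probability exactly
#' equal to tau is stroma).
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @param threshold Decision threshold tau in (0, 1); default 0.5.
#' @return Character vector of `"gland"` / `"stroma"`.
#' @export
classify <- function(p, threshold = 0.5) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]", call. = FALSE)
  ifelse(p > threshold, "gland", "stroma")
}

#' Apply the augmentation policy to one patch
#'
#' Deterministic under `seed`; the transform chain is flip, rotate, zoom,
#' shift, resampled bilinearly with mirror fill.
#'
#' @param patch Square numeric matrix.
#' @param policy An [augment_policy()].
#' @param seed Integer seed.
#' @return Augmented patch of the same shape.
#' @export
augment <- function(patch, policy = augment_policy(), seed = 1L) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch))
    stop("patch must be a square matrix", call. = FALSE)
  .gn_augment(patch, unclass(policy), as.integer(seed))
}

#' Initialize an untrained GlandNet model
#'
#' Creates the model object with He-initialized weights (seeded, random
#' initialization; transfer-learned initial weights are not bundled).
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `glandnet` (untrained).
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "glandnet_spec"))
  w <- .gn_init_weights(engine_spec(spec), as.integer(seed))
  structure(list(spec = spec, weights = w, trained = FALSE,
                 history = NULL, config = NULL, input_stats = NULL,
                 init_seed = as.integer(seed)),
            class = "glandnet")
}

# Pull a (size, size, n) array + label vector out of containers / arrays.
# `x` may be a biopsy_container, a list of them, or a 3-D array.
as_patch_array <- function(x, labels = NULL) {
  if (inherits(x, "biopsy_container")) x <- list(x)
  if (is.list(x) && length(x) > 0 && all(vapply(x, inherits, TRUE, "biopsy_container"))) {
    sizes <- vapply(x, function(ct) ct$patch_size, integer(1))
    if (length(unique(sizes)) != 1)
      stop("containers have mixed patch sizes", call. = FALSE)
    size <- sizes[1]
    n <- sum(vapply(x, function(ct) length(ct$records), integer(1)))
    arr <- array(0, dim = c(size, size, n))
    lab <- character(n)
    ids <- data.frame(biopsy_id = character(n), nucleus_id = integer(n))
    i <- 0L
    for (ct in x) for (rec in ct$records) {
      i <- i + 1L
      px <- rec$pixels
      if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)  # collapse channels
      arr[, , i] <- px
      lab[i] <- rec$label
      ids$biopsy_id[i] <- ct$biopsy_id
      ids$nucleus_id[i] <- rec$nucleus_id
    }
    return(list(x = arr, labels = lab, ids = ids))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    if (is.null(labels)) return(list(x = x, labels = NULL, ids = NULL))
    assert_label(labels)
    if (length(labels) != dim(x)[3])
      stop("labels length must match number of patches", call. = FALSE)
    return(list(x = x, labels = as.character(labels), ids = NULL))
  }
  stop("x must be a biopsy_container, a list of containers, or a 3-D array",
       call. = FALSE)
}

#' Fit a GlandNet classifier
#'
#' Trains the gland-vs-stroma patch classifier with Adam on the weighted
#' categorical cross-entropy, with seeded shuffling, augmentation and
#' Gaussian-noise regularization. Input patches are standardized by the
#' training-set mean and standard deviation; the statistics are stored in the
#' fitted model and re-applied at prediction time.
#'
#' @param x Training data: a [biopsy_container()], a list of containers
#'   (labels are taken from the records), or a `(size, size, n)` array with
#'   `labels` supplied separately.
#' @param labels Character vector of `"gland"`/`"stroma"` per patch when `x`
#'   is an array; ignored otherwise.
#' @param spec A [model_spec()]; its `input_size` must equal the patch size.
#' @param config A [train_config()].
#' @param validation Optional validation data in the same forms as `x`
#'   (with `validation_labels` when an array); per-epoch validation loss and
#'   accuracy are then tracked in the history.
#' @param validation_labels See `validation`.
#' @param model Optional untrained or previously fitted `glandnet` whose
#'   weights are the starting point (warm start); by default a fresh
#'   He-initialized model seeded by `config$seed` is used.
#' @param sample_weights Optional per-patch positive multipliers on the loss
#'   (used, e.g., for soft pseudo-labels); default all 1.
#' @param max_restarts Deep narrow networks occasionally converge to a
#'   degenerate constant predictor (every training patch classified into one
#'   class). Such fits are detected after training and retried from a fresh
#'   seeded initialization, up to `max_restarts` times, keeping the last fit
#'   (with a warning) if all attempts degenerate.
#' @return A fitted object of class `glandnet` with a `history` data frame
#'   (epoch, loss, accuracy, val_loss, val_accuracy).
#' @seealso [predict.glandnet()], [run_two_rounds()]
#' @export
glandnet <- function(x, labels = NULL, spec = model_spec(),
                     config = train_config(), validation = NULL,
                     validation_labels = NULL, model = NULL,
                     sample_weights = NULL, max_restarts = 3L) {
  stopifnot(inherits(spec, "glandnet_spec"), inherits(config, "glandnet_config"))
  dat <- as_patch_array(x, labels)
  if (is.null(dat$labels)) stop("training labels are required", call. = FALSE)
  keep <- dat$labels != "unknown"
  xs <- dat$x[, , keep, drop = FALSE]
  ys <- dat$labels[keep]
  if (length(unique(ys)) < 2)
    stop("training data must contain both classes (gland and stroma)",
         call. = FALSE)
  if (dim(xs)[1] != spec$input_size)
    stop(sprintf("patch size %d does not match model input size %d",
                 dim(xs)[1], spec$input_size), call. = FALSE)
  y <- .label_codes[ys]

  # standardize by training statistics
  mu <- mean(xs); sdv <- stats::sd(as.vector(xs))
  if (sdv == 0) sdv <- 1
  xs <- (xs - mu) / sdv

  cw <- config$class_weights
  if (is.null(cw)) {
    freq <- c(stroma = mean(y == 0L), gland = mean(y == 1L))
    cw <- (1 / freq) / mean(1 / freq)   # inverse frequency, mean-1 normalized
  }
  cls_w <- unname(cw[c("stroma", "gland")])

  vx <- NULL; vy <- NULL
  if (!is.null(validation)) {
    vdat <- as_patch_array(validation, validation_labels)
    if (is.null(vdat$labels)) stop("validation labels are required", call. = FALSE)
    vkeep <- vdat$labels != "unknown"
    vx <- (vdat$x[, , vkeep, drop = FALSE] - mu) / sdv
    vy <- .label_codes[vdat$labels[vkeep]]
  }

  if (!is.null(sample_weights)) {
    sample_weights <- sample_weights[keep]
    if (any(sample_weights <= 0)) stop("sample_weights must be > 0", call. = FALSE)
  }
  sw <- if (is.null(sample_weights)) NULL else as.numeric(sample_weights)

  lr_epochs <- rep(config$learning_rate, config$epochs)
  if (identical(config$lr_schedule, "step")) {
    cut <- ceiling(2 * config$epochs / 3)
    if (cut < config$epochs)
      lr_epochs[(cut + 1):config$epochs] <- config$learning_rate / 10
  }
  eng_cfg <- list(learning_rate = lr_epochs,
                  beta1 = config$beta1, beta2 = config$beta2,
                  epochs = config$epochs,
                  batch_size = config$batch_size,
                  class_weights = cls_w,
                  seed = config$seed,
                  augment = config$augment,
                  augment_policy = unclass(config$augment_policy))

  for (attempt in 0:max_restarts) {
    seed_a <- config$seed + 7919L * attempt
    eng_cfg$seed <- seed_a
    start <- if (attempt == 0L && !is.null(model)) model
             else build_model(spec, seed = seed_a)
    stopifnot(inherits(start, "glandnet"))
    res <- .gn_train(start$weights, xs, as.integer(unname(y)),
                     engine_spec(spec), eng_cfg,
                     if (is.null(vx)) NULL else vx,
                     if (is.null(vy)) NULL else as.integer(unname(vy)),
                     sw)
    # degenerate-fit check: a healthy fit separates the training classes at
    # the decision threshold; a constant predictor is retried
    p_train <- .gn_predict(res$weights, xs, engine_spec(spec), 64L)
    cls <- classify(p_train[, .label_codes["gland"] + 1L],
                    config$decision_threshold)
    if (length(unique(cls)) > 1L) break
    if (attempt < max_restarts)
      warning(sprintf("degenerate fit (all training patches classified '%s'); restarting (attempt %d)",
                      cls[1], attempt + 1L), call. = FALSE)
    else
      warning("all training restarts produced a degenerate constant fit",
              call. = FALSE)
  }

  history <- data.frame(epoch = seq_len(config$epochs),
                        loss = res$loss, accuracy = res$accuracy,
                        val_loss = res$val_loss, val_accuracy = res$val_accuracy)
  weights <- res$weights
  if (config$checkpoint == "best_validation" && !all(is.na(history$val_accuracy))) {
    # weights snapshot only kept for final epoch; best-validation selection
    # re-runs training up to the best epoch
    best <- which.max(history$val_accuracy)
    if (best < config$epochs) {
      cfg2 <- eng_cfg; cfg2$epochs <- best
      model2 <- build_model(spec, seed = eng_cfg$seed)
      weights <- .gn_train(model2$weights, xs, as.integer(unname(y)),
                           engine_spec(spec), cfg2, NULL, NULL, sw)$weights
    }
  }
  structure(list(spec = spec, weights = weights, trained = TRUE,
                 history = history, config = config,
                 input_stats = c(mean = mu, sd = sdv),
                 class_weights = cls_w,
                 n_train = length(ys),
                 train_class_counts = table(factor(ys, levels = c("stroma", "gland"))),
                 init_seed = config$seed),
            class = "glandnet")
}

#' Predict gland probabilities
#'
#' @param object A fitted `glandnet` model.
#' @param newdata A [biopsy_container()], list of containers, or
#'   `(size, size, n)` array.
#' @param type `"prob"` for gland probabilities, `"class"` for thresholded
#'   labels.
#' @param threshold Decision threshold for `type = "class"`; defaults to the
#'   fitted configuration's threshold (0.5).
#' @param batch_size Prediction mini-batch size.
#' @param ... Unused.
#' @return Numeric vector of gland probabilities (or character labels),
#'   ordered as the input records.
#' @export
predict.glandnet <- function(object, newdata, type = c("prob", "class"),
                             threshold = NULL, batch_size = 64L, ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained))
    warning("predicting from an untrained model")
  dat <- as_patch_array(newdata)
  if (dim(dat$x)[1] != object$spec$input_size)
    stop(sprintf("patch size %d does not match model input size %d",
                 dim(dat$x)[1], object$spec$input_size), call. = FALSE)
  xs <- dat$x
  if (!is.null(object$input_stats))
    xs <- (xs - object$input_stats["mean"]) / object$input_stats["sd"]
  probs <- .gn_predict(object$weights, xs, engine_spec(object$spec),
                       as.integer(batch_size))
  p_gland <- probs[, .label_codes["gland"] + 1L]
  if (type == "prob") return(p_gland)
  threshold <- threshold %||% object$config$decision_threshold %||% 0.5
  classify(p_gland, threshold)
}

#' Predict and store per-nucleus gland probabilities in a container
#'
#' Runs the model over every record of the container and returns the container
#' with each record's `prediction` field set to the gland probability, ordered
#' as the records.
#'
#' @param model A fitted `glandnet`.
#' @param container A [biopsy_container()] whose `patch_size` matches the
#'   model input size.
#' @return The container with predictions filled in.
#' @export
predict_proba <- function(model, container) {
  stopifnot(inherits(container, "biopsy_container"))
  p <- predict(model, container, type = "prob")
  for (i in seq_along(container$records))
    container$records[[i]]$prediction <- p[i]
  container
}

#' @export
print.glandnet <- function(x, ...) {
  cat("GlandNet", if (isTRUE(x$trained)) "(fitted)" else "(untrained)", "\n")
  print(x$spec)
  if (isTRUE(x$trained)) {
    h <- x$history
    last <- h[nrow(h), ]
    cat(sprintf("  trained on %d patches (%s) for %d epochs\n",
                x$n_train,
                paste(sprintf("%s=%d", names(x$train_class_counts),
                              as.integer(x$train_class_counts)), collapse = ", "),
                nrow(h)))
    cat(sprintf("  final loss %.4f, accuracy %.3f", last$loss, last$accuracy))
    if (!is.na(last$val_accuracy))
      cat(sprintf(", val accuracy %.3f", last$val_accuracy))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.glandnet <- function(object, ...) {
  print(object)
  cat("\nLayer sequence:\n")
  print(glandnet_layers(object$spec))
  invisible(object)
}

#' @export
coef.glandnet <- function(object, ...) object$weights

#' Plot training history
#'
#' Loss and accuracy per epoch for training (and validation when tracked).
#'
#' @param x A fitted `glandnet`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.glandnet <- function(x, ...) {
  if (!isTRUE(x$trained)) stop("model is not trained", call. = FALSE)
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss", ...)
  if (!all(is.na(h$val_loss))) graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::plot(h$epoch, h$accuracy, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", ...)
  if (!all(is.na(h$val_accuracy))) graphics::lines(h$epoch, h$val_accuracy, lty = 2)
  invisible(x)
}
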