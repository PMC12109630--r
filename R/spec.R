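#' GlandNet architecture specification
#'
#' Describes a member of the GlandNet family: a VGG-lineage convolutional
#' network with 13 convolution layers in five blocks (each block followed by
#' 2x2 max pooling), a global-average-pooling head, and three dense layers
#' interleaved with two Gaussian-noise regularization layers, ending in a
#' 2-unit softmax (gland vs stroma). At `width_scale = 1` the network has 16
#' weight layers (13 convolutional + 3 dense) and a 24-layer sequence.
#'
#' `width_scale` shrinks every convolutional and dense width proportionally,
#' producing desk-scale variants that train in minutes on a CPU while keeping
#' the layer sequence identical.
#'
#' @param input_size Patch edge length in pixels; 128 or 256 unless
#'   `allow_any_input = TRUE` (used for scaled-down experiments, e.g. 64).
#' @param width_scale Multiplier in (0, 1] applied to all layer widths.
#' @param conv_widths Base output widths of the 13 convolution layers
#'   (default follows the canonical 64/128/256/512/512 block progression).
#' @param head_widths Base widths of the two hidden dense layers.
#' @param noise_sigma Standard deviation of the Gaussian-noise layers
#'   (active during training only).
#' @param noise_on_input If `TRUE`, apply the Gaussian noise to the input
#'   patch instead of the dense-head activations (alternative placement).
#' @param channels Number of image channels (1 = optical density).
#' @param allow_any_input Permit even input sizes other than 128/256.
#' @return An object of class `glandnet_spec`.
#' @export
model_spec <- function(input_size = 256L,
                       width_scale = 1,
                       conv_widths = c(64, 64, 128, 128, 256, 256, 256,
                                       512, 512, 512, 512, 512, 512),
                       head_widths = c(256, 64),
                       noise_sigma = 1,
                       noise_on_input = FALSE,
                       channels = 1L,
                       allow_any_input = FALSE) {
  input_size <- as.integer(input_size)
  if (!allow_any_input && !input_size %in% c(128L, 256L))
    stop("input_size must be 128 or 256 (use allow_any_input = TRUE to override)",
         call. = FALSE)
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32 (five 2x2 poolings)", call. = FALSE)
  if (length(conv_widths) != 13L)
    stop("conv_widths must have exactly 13 entries", call. = FALSE)
  if (length(head_widths) != 2L)
    stop("head_widths must have exactly 2 entries", call. = FALSE)
  if (!is.numeric(width_scale) || width_scale <= 0 || width_scale > 1)
    stop("width_scale must be in (0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  scaled_conv <- pmax(1L, as.integer(round(conv_widths * width_scale)))
  # the dense head keeps a minimum width of 16 units at small scales: narrower
  # heads are prone to whole-layer ReLU death, which freezes training
  scaled_head <- pmax(pmin(16L, as.integer(head_widths)),
                      as.integer(round(head_widths * width_scale)))
  structure(list(
    input_size = input_size,
    width_scale = width_scale,
    base_conv_widths = as.integer(conv_widths),
    base_head_widths = as.integer(head_widths),
    conv_widths = scaled_conv,
    head_widths = scaled_head,
    # 2x2 max pooling after conv layers 2, 4, 7, 10, 13 (1-based)
    pool_after = c(2L, 4L, 7L, 10L, 13L),
    noise_sigma = noise_sigma,
    noise_on_input = isTRUE(noise_on_input),
    channels = as.integer(channels),
    n_class = 2L
  ), class = "glandnet_spec")
}

# Internal: list layout consumed by the C++ engine (0-based pool indices).
engine_spec <- function(spec) {
  list(conv_widths = spec$conv_widths,
       pool_after = spec$pool_after - 1L,
       d1 = spec$head_widths[1], d2 = spec$head_widths[2],
       n_class = spec$n_class,
       input_size = spec$input_size, channels = spec$channels,
       noise_sigma = spec$noise_sigma,
       noise_on_input = spec$noise_on_input)
}

#' Enumerate the layer sequence of a GlandNet specification
#'
#' Returns one row per layer in forward order: 13 convolutions, 5 max-pooling
#' layers, 1 global average pooling, 3 dense layers and 2 Gaussian-noise
#' layers (24 in total). The `weight_layer` column marks the 16 layers that
#' carry learnable parameters; `n_params` counts weights plus biases.
#' Activation functions are not counted as layers.
#'
#' @param spec A [model_spec()] object.
#' @return A data frame with columns `index`, `type`, `output_width`,
#'   `weight_layer`, `n_params`.
#' @export
glandnet_layers <- function(spec) {
  stopifnot(inherits(spec, "glandnet_spec"))
  rows <- list()
  cin <- spec$channels
  for (l in seq_along(spec$conv_widths)) {
    cout <- spec$conv_widths[l]
    rows[[length(rows) + 1L]] <- data.frame(
      type = "conv3x3", output_width = cout,
      weight_layer = TRUE, n_params = 9L * cin * cout + cout)
    cin <- cout
    if (l %in% spec$pool_after)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "maxpool2x2", output_width = cin,
        weight_layer = FALSE, n_params = 0L)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    type = "global_average_pool", output_width = cin,
    weight_layer = FALSE, n_params = 0L)
  d1 <- spec$head_widths[1]; d2 <- spec$head_widths[2]
  rows[[length(rows) + 1L]] <- data.frame(
    type = "dense", output_width = d1, weight_layer = TRUE,
    n_params = cin * d1 + d1)
  rows[[length(rows) + 1L]] <- data.frame(
    type = "gaussian_noise", output_width = d1, weight_layer = FALSE, n_params = 0L)
  rows[[length(rows) + 1L]] <- data.frame(
    type = "dense", output_width = d2, weight_layer = TRUE,
    n_params = d1 * d2 + d2)
  rows[[length(rows) + 1L]] <- data.frame(
    type = "gaussian_noise", output_width = d2, weight_layer = FALSE, n_params = 0L)
  rows[[length(rows) + 1L]] <- data.frame(
    type = "dense", output_width = spec$n_class, weight_layer = TRUE,
    n_params = d2 * spec$n_class + spec$n_class)
  out <- do.call(rbind, rows)
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' @export
print.glandnet_spec <- function(x, ...) {
  layers <- glandnet_layers(x)
  cat("GlandNet specification\n")
  cat(sprintf("  input: %dx%dx%d, width scale %s\n",
              x$input_size, x$input_size, x$channels, format(x$width_scale)))
  cat(sprintf("  layers: %d total, %d weight layers (%d conv + 3 dense)\n",
              nrow(layers), sum(layers$weight_layer),
              sum(layers$type == "conv3x3")))
  cat(sprintf("  parameters: %s\n", format(sum(layers$n_params), big.mark = ",")))
  cat(sprintf("  noise sigma: %s (%s)\n", format(x$noise_sigma),
              if (x$noise_on_input) "on input" else "head noise layers"))
  invisible(x)
}

#' Training configuration for GlandNet
#'
#' Defaults follow the reference training recipe for the full-size network:
#' Adam with beta1 = 0.9, beta2 = 0.999 and a very low initial learning rate
#' of 1e-5, batch size 128, 100 epochs, Gaussian-noise sigma 1, and a 0.5
#' decision threshold. Scaled-down experiments typically override
#' `learning_rate`, `epochs` and `batch_size`.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of training epochs (>= 1).
#' @param beta1,beta2 Adam moment decay rates.
#' @param class_weights Named per-class loss weights
#'   (`c(stroma = , gland = )`), or `NULL` to use inverse class frequency
#'   computed on the training data.
#' @param decision_threshold Probability threshold tau used by [classify()];
#'   a nucleus is called gland when its gland probability strictly exceeds tau.
#' @param lr_schedule `"constant"` keeps the learning rate fixed; `"step"`
#'   divides it by 10 for the final third of the epochs, which settles the
#'   calibration of the output probabilities in short desk-scale runs.
#' @param seed Integer seed driving initialization, shuffling, augmentation
#'   and the noise layers.
#' @param augment Apply the augmentation policy during training.
#' @param augment_policy An [augment_policy()] object.
#' @param checkpoint Which epoch's weights the fitted model keeps:
#'   `"final"` (default) or `"best_validation"` (highest validation accuracy).
#' @return An object of class `glandnet_config`.
#' @export
train_config <- function(learning_rate = 1e-5,
                         batch_size = 128L,
                         epochs = 100L,
                         lr_schedule = c("constant", "step"),
                         beta1 = 0.9,
                         beta2 = 0.999,
                         class_weights = NULL,
                         decision_threshold = 0.5,
                         seed = 1L,
                         augment = TRUE,
                         augment_policy = glandcell::augment_policy(),
                         checkpoint = c("final", "best_validation")) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stop("decision_threshold must be in (0, 1)", call. = FALSE)
  if (!is.null(class_weights)) {
    if (any(class_weights <= 0)) stop("class_weights must be > 0", call. = FALSE)
    if (is.null(names(class_weights)) ||
        !setequal(names(class_weights), c("stroma", "gland")))
      stop("class_weights must be named c(stroma = , gland = )", call. = FALSE)
  }
  structure(list(
    learning_rate = learning_rate,
    lr_schedule = match.arg(lr_schedule),
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    beta1 = beta1, beta2 = beta2,
    class_weights = class_weights,
    decision_threshold = decision_threshold,
    seed = as.integer(seed),
    augment = isTRUE(augment),
    augment_policy = augment_policy,
    checkpoint = match.arg(checkpoint)
  ), class = "glandnet_config")
}

#' Patch augmentation policy
#'
#' Random horizontal/vertical flips, rotation, zoom and translation applied to
#' training patches, with mirror fill for pixels exposed by the transform.
#' The composition order is fixed: flip, rotate, zoom, shift. Rotation angles
#' are drawn uniformly from `[0, rotation_degrees]` with a random sign; zoom
#' factors from `1 +/- zoom_fraction`; shifts uniformly within the stated
#' fraction of the patch edge.
#'
#' @param hflip_prob,vflip_prob Flip probabilities in \[0, 1\].
#' @param rotation_degrees Maximum rotation magnitude in degrees.
#' @param zoom_fraction,width_shift_fraction,height_shift_fraction
#'   Fractions in \[0, 1).
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(hflip_prob = 0.5,
                           vflip_prob = 0.5,
                           rotation_degrees = 45,
                           zoom_fraction = 0.2,
                           width_shift_fraction = 0.2,
                           height_shift_fraction = 0.2) {
  probs <- c(hflip_prob, vflip_prob)
  fracs <- c(zoom_fraction, width_shift_fraction, height_shift_fraction)
  if (any(probs < 0 | probs > 1)) stop("flip probabilities must be in [0, 1]",
                                       call. = FALSE)
  if (any(fracs < 0 | fracs >= 1)) stop("fractions must be in [0, 1)", call. = FALSE)
  if (rotation_degrees < 0) stop("rotation_degrees must be >= 0", call. = FALSE)
  structure(list(hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 rotation_degrees = rotation_degrees,
                 zoom_fraction = zoom_fraction,
                 width_shift_fraction = width_shift_fraction,
                 height_shift_fraction = height_shift_fraction,
                 fill = "mirror"),
            class = "augment_policy")
}

# Identity policy: useful in tests and as an explicit "no augmentation" value.
#' @rdname augment_policy
#' @export
identity_policy <- function() {
  augment_policy(hflip_prob = 0, vflip_prob = 0, rotation_degrees = 0,
                 zoom_fraction = 0, width_shift_fraction = 0,
                 height_shift_fraction = 0)
}
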