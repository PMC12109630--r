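# Classifier family: softmax/loss primitives, topology, augmentation,
# training and prediction.

test_that("softmax matches closed forms and is overflow-safe", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  big <- softmax(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  expect_error(softmax(numeric(0)), "non-empty")
  expect_error(softmax(c(1, Inf)), "finite")
  # normalization property over random logit vectors
  set.seed(8)
  for (i in 1:50) {
    z <- softmax(rnorm(sample(2:6, 1), sd = 10))
    expect_equal(sum(z), 1, tolerance = 1e-12)
    expect_true(all(z > 0 & z < 1))
  }
})

test_that("weighted cross-entropy matches closed forms and scales in weights", {
  expect_equal(weighted_ce(c(1, 0), c(1, 0)), 0)
  expect_equal(weighted_ce(c(1, 0), c(0.5, 0.5)), log(2))
  base <- weighted_ce(c(1, 0), c(0.3, 0.7), c(1, 1))
  expect_equal(weighted_ce(c(1, 0), c(0.3, 0.7), c(2, 1)), 2 * base)
  expect_gte(weighted_ce(c(0, 1), c(0.99, 0.01)), 0)
  expect_error(weighted_ce(c(1, 0, 0), c(0.5, 0.5)), "equal length")
  expect_error(weighted_ce(c(1, 1), c(0.5, 0.5)), "one-hot")
  # moving probability mass toward the true class lowers the loss
  ps <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(ps, function(p) weighted_ce(c(1, 0), c(p, 1 - p)), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("classify applies a strict threshold with gland above", {
  expect_equal(classify(0.51, 0.5), "gland")
  expect_equal(classify(0.5, 0.5), "stroma")      # ties go to stroma
  expect_equal(classify(c(0, 1), 0.5), c("stroma", "gland"))
  # sweeping tau flips each decision exactly once
  p <- runif(20)
  taus <- seq(0, 1, by = 0.01)
  for (pi in p) {
    dec <- vapply(taus, function(t) classify(pi, t), character(1))
    expect_lte(sum(dec[-1] != dec[-length(dec)]), 1)
  }
  expect_error(classify(1.2), "\\[0, 1\\]")
})

test_that("full-size topology has 16 weight layers in a 24-layer sequence", {
  spec <- model_spec(input_size = 256L, width_scale = 1)
  layers <- glandnet_layers(spec)
  expect_equal(nrow(layers), 24)
  expect_equal(sum(layers$weight_layer), 16)
  expect_equal(sum(layers$type == "conv3x3"), 13)
  expect_equal(sum(layers$type == "dense"), 3)
  expect_equal(sum(layers$type == "maxpool2x2"), 5)
  expect_equal(sum(layers$type == "global_average_pool"), 1)
  expect_equal(sum(layers$type == "gaussian_noise"), 2)
  # output layer has exactly 2 units
  expect_equal(layers$output_width[nrow(layers)], 2)
  # weights materialize with matching parameter counts
  m <- build_model(spec, seed = 1)
  n_params <- sum(vapply(m$weights$convW, length, numeric(1))) +
    sum(vapply(m$weights$convB, length, numeric(1))) +
    length(m$weights$W1) + length(m$weights$b1) +
    length(m$weights$W2) + length(m$weights$b2) +
    length(m$weights$W3) + length(m$weights$b3)
  expect_equal(n_params, sum(layers$n_params))
})

test_that("width scaling shrinks conv parameters quadratically", {
  full <- glandnet_layers(model_spec(256L, width_scale = 1))
  eighth <- glandnet_layers(model_spec(64L, width_scale = 1 / 8,
                                       allow_any_input = TRUE))
  expect_equal(eighth$type, full$type)   # same 24-layer sequence
  conv_full <- sum(full$n_params[full$type == "conv3x3"])
  conv_eighth <- sum(eighth$n_params[eighth$type == "conv3x3"])
  # ~1/64 of the conv parameters (boundary effects from the 1-channel input)
  expect_lt(conv_eighth / conv_full, 1 / 50)
  expect_error(model_spec(96L), "input_size must be 128 or 256")
  expect_silent(model_spec(96L, allow_any_input = TRUE))
})

test_that("the engine forward pass matches a direct-convolution reference", {
  ref_forward <- function(w, spec, img) {
    conv <- function(A, W9, b) {
      H <- dim(A)[1]; W <- dim(A)[2]; Cin <- dim(A)[3]; Cout <- nrow(W9)
      Y <- array(0, c(H, W, Cout))
      Ap <- array(0, c(H + 2, W + 2, Cin)); Ap[2:(H + 1), 2:(W + 1), ] <- A
      for (co in seq_len(Cout)) {
        acc <- matrix(b[co], H, W)
        for (dc in -1:1) for (dr in -1:1) {
          k <- (dc + 1) * 3 + (dr + 1)
          for (ci in seq_len(Cin))
            acc <- acc + W9[co, k * Cin + ci] *
              Ap[2:(H + 1) + dr, 2:(W + 1) + dc, ci]
        }
        Y[, , co] <- pmax(acc, 0)
      }
      Y
    }
    pool <- function(A) {
      H <- dim(A)[1] / 2; W <- dim(A)[2] / 2
      Y <- array(0, c(H, W, dim(A)[3]))
      for (r in 1:H) for (cc in 1:W)
        Y[r, cc, ] <- apply(A[(2 * r - 1):(2 * r), (2 * cc - 1):(2 * cc), ,
                              drop = FALSE], 3, max)
      Y
    }
    es <- engine_spec(spec)
    A <- array(img, c(dim(img), 1))
    for (l in seq_along(es$conv_widths)) {
      A <- conv(A, w$convW[[l]], w$convB[[l]])
      if ((l - 1) %in% es$pool_after) A <- pool(A)
    }
    gap <- apply(A, 3, mean)
    h1 <- pmax(as.vector(w$W1 %*% gap + w$b1), 0)
    h2 <- pmax(as.vector(w$W2 %*% h1 + w$b2), 0)
    softmax(as.vector(w$W3 %*% h2 + w$b3))
  }
  spec <- model_spec(64L, width_scale = 1 / 16, allow_any_input = TRUE)
  m <- build_model(spec, seed = 5)
  set.seed(1)
  img <- matrix(rnorm(64 * 64), 64, 64)
  p_ref <- ref_forward(m$weights, spec, img)
  p_eng <- suppressWarnings(predict(m, array(img, c(64, 64, 1)), type = "prob"))
  expect_equal(unname(p_ref[2]), unname(p_eng), tolerance = 1e-12)
})

test_that("augmentation is seeded, shape-preserving, and involutive for flips", {
  set.seed(2)
  patch <- matrix(runif(64 * 64), 64, 64)
  ident <- augment(patch, identity_policy(), seed = 3)
  expect_equal(ident, patch)
  hflip_pol <- augment_policy(hflip_prob = 1, vflip_prob = 0,
                              rotation_degrees = 0, zoom_fraction = 0,
                              width_shift_fraction = 0,
                              height_shift_fraction = 0)
  once <- augment(patch, hflip_pol, seed = 3)
  expect_false(identical(once, patch))
  expect_equal(augment(once, hflip_pol, seed = 99), patch)  # involution
  full <- augment_policy()
  a <- augment(patch, full, seed = 7)
  b <- augment(patch, full, seed = 7)
  expect_identical(a, b)                                    # seeded
  expect_equal(dim(a), dim(patch))
  expect_false(identical(augment(patch, full, seed = 8), a))
})

test_that("training separates toy classes and is reproducible", {
  toy <- toy_patches(n = 96, seed = 1)
  spec <- desk_spec(noise_sigma = 0)
  cfg <- desk_config(seed = 2, epochs = 6L, augment = FALSE)
  fit <- glandnet(toy$x, toy$labels, spec = spec, config = cfg)
  expect_s3_class(fit, "glandnet")
  expect_equal(nrow(fit$history), 6)
  # training accuracy on separable data reaches the sanity floor
  p <- predict(fit, toy$x)
  acc <- mean(classify(p, 0.5) == toy$labels)
  expect_gte(acc, 0.95)
  # identical seeds reproduce the history exactly
  fit2 <- glandnet(toy$x, toy$labels, spec = spec, config = cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$weights, fit2$weights)
  # single-class data is rejected
  expect_error(glandnet(toy$x, rep("gland", 96), spec = spec, config = cfg),
               "both classes")
})

test_that("prediction is pure, ordered, in range, and size-checked", {
  toy <- toy_patches(n = 40, seed = 3)
  fit <- glandnet(toy$x, toy$labels, spec = desk_spec(0),
                  config = desk_config(seed = 1, epochs = 3L, augment = FALSE))
  sc <- tiny_scene(seed = 2)
  ct <- scene_container(sc)
  ct <- predict_proba(fit, ct)
  probs <- vapply(ct$records, function(r) r$prediction, numeric(1))
  expect_length(probs, length(ct$records))
  expect_true(all(probs >= 0 & probs <= 1))
  # functional purity: a duplicated record gets an identical probability
  dup <- ct$records[[1]]; dup$nucleus_id <- 99999L
  ct2 <- biopsy_container("dup", ct$slide_shape, ct$patch_size,
                          c(ct$records[1], list(dup)))
  p2 <- predict(fit, ct2)
  expect_equal(p2[1], p2[2])
  expect_equal(unname(p2[1]), unname(probs[1]))
  # eval-mode determinism: noise layers are inactive at prediction
  expect_identical(predict(fit, ct), predict(fit, ct))
  # patch size mismatch is an error
  big <- scene_container(sc, size = 96L, biopsy_id = "b96")
  expect_error(predict(fit, big), "does not match model input size")
})

test_that("training histories track validation when supplied", {
  toy <- toy_patches(n = 48, seed = 4)
  val <- toy_patches(n = 24, seed = 5)
  fit <- glandnet(toy$x, toy$labels, spec = desk_spec(0),
                  config = desk_config(seed = 1, epochs = 3L, augment = FALSE),
                  validation = val$x, validation_labels = val$labels)
  expect_false(anyNA(fit$history$val_accuracy))
  expect_false(anyNA(fit$history$val_loss))
})
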