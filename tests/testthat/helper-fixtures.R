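# Shared fixtures: small synthetic scenes, desk-scale model/config, and the
# independent geometry oracle used against the packaged point-in-polygon.

flips_only_policy <- function() {
  augment_policy(rotation_degrees = 0, zoom_fraction = 0,
                 width_shift_fraction = 0, height_shift_fraction = 0)
}

desk_spec <- function(noise_sigma = 0.15) {
  model_spec(input_size = 64L, width_scale = 1 / 8, noise_sigma = noise_sigma,
             allow_any_input = TRUE)
}

desk_config <- function(seed = 1L, epochs = 12L, ...) {
  train_config(learning_rate = 3e-4, batch_size = 8L, epochs = epochs,
               lr_schedule = "step", seed = seed,
               augment_policy = flips_only_policy(), ...)
}

# a small but full-featured scene (three glands, modest stroma)
tiny_scene <- function(seed = 1L, ...) {
  render_scene(scene_spec(canvas_shape = c(256L, 256L), n_glands = 2L,
                          gland_radius_range = c(20, 26),
                          nuclei_per_gland_ring = c(8L, 10L),
                          n_stroma = 30L, seed = seed, ...))
}

scene_container <- function(scene, size = 64L, biopsy_id = "b1", labels = NULL) {
  build_biopsy_container(scene$image, scene$nuclei, scene$glands, size,
                         biopsy_id = biopsy_id, labels = labels)
}

# default-sized labeled scene triple used by the semi-supervised tests
corrupted_scene_container <- function(seed, q, biopsy_id, size = 64L) {
  sc <- render_scene(scene_spec(seed = seed))
  ns <- inject_annotation_misses(sc$labels, q, seed = seed + 500L)
  ct <- build_biopsy_container(sc$image, sc$nuclei, sc$glands, size,
                               biopsy_id = biopsy_id, labels = ns$labels)
  list(ct = ct, truth = sc$labels, flipped = ns$flipped)
}

# independent point-in-polygon oracle: classic ray casting along +col with a
# separate boundary test, written without reference to the packaged code
pip_oracle <- function(point, poly) {
  n <- nrow(poly)
  px <- point[1]; py <- point[2]
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check via projection
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    if (len2 > 0) {
      t <- ((px - xi) * dx + (py - yi) * dy) / len2
      t <- min(max(t, 0), 1)
      if ((px - (xi + t * dx))^2 + (py - (yi + t * dy))^2 < 1e-16) return(TRUE)
    } else if ((px - xi)^2 + (py - yi)^2 < 1e-16) return(TRUE)
    if ((xi > px) != (xj > px)) {
      yint <- yi + (px - xi) / (xj - xi) * (yj - yi)
      if (yint > py) inside <- !inside
    }
    j <- i
  }
  inside
}

# random simple (star-shaped) polygon around a center
random_polygon <- function(center, rmin, rmax, k = 8L) {
  t <- sort(stats::runif(k, 0, 2 * pi))
  r <- stats::runif(k, rmin, rmax)
  cbind(center[1] + r * cos(t), center[2] + r * sin(t))
}

# separable toy patches: bright square for one class
toy_patches <- function(n = 96L, size = 64L, seed = 1L) {
  set.seed(seed)
  x <- array(rnorm(size * size * n, 0.5, 0.2), dim = c(size, size, n))
  y <- rep(c("stroma", "gland"), length.out = n)
  sq <- (size %/% 2 - 8):(size %/% 2 + 8)
  for (i in seq_len(n)) if (y[i] == "gland")
    x[sq, sq, i] <- x[sq, sq, i] + 1
  list(x = x, labels = y)
}
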