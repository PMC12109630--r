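# Patch extraction, labeling and cohort splitting.

test_that("extract_patch centers the nucleus at floor(size/2)", {
  set.seed(1)
  img <- matrix(runif(1000 * 1000), 1000, 1000)
  res <- extract_patch(img, c(300, 300), 128L)
  expect_equal(res$slide_offset, c(236L, 236L))
  # 0-based patch index (64, 64) is 1-based [65, 65]
  expect_equal(res$pixels[65, 65], img[301, 301])
  expect_equal(dim(res$pixels), c(128L, 128L))
  # interior patch equals a plain crop
  expect_equal(res$pixels, img[237:364, 237:364])
})

# explicit pad-then-crop oracle: mirror-pad the full image, then crop
pad_crop_oracle <- function(img, center, size) {
  h <- nrow(img); w <- ncol(img)
  pad <- size                      # generous pad
  ridx <- reflect_index((-pad):(h + pad - 1L), h) + 1L
  cidx <- reflect_index((-pad):(w + pad - 1L), w) + 1L
  big <- img[ridx, cidx]
  off <- center - size %/% 2
  big[(off[1] + pad + 1):(off[1] + pad + size),
      (off[2] + pad + 1):(off[2] + pad + size)]
}

test_that("border patches match a pad-then-crop mirror oracle", {
  set.seed(2)
  img <- matrix(runif(300 * 280), 300, 280)
  for (center in list(c(10, 10), c(0, 0), c(299, 279), c(5, 270))) {
    res <- extract_patch(img, center, 256L)
    expect_equal(res$slide_offset, as.integer(center) - 128L)
    expect_equal(res$pixels, pad_crop_oracle(img, center, 256L))
  }
  # in-bounds pixels are untouched source pixels
  res <- extract_patch(img, c(10, 10), 256L)
  off <- res$slide_offset   # (-118, -118)
  expect_equal(res$pixels[(1 - off[1]):(256), (1 - off[2]):(256)],
               img[1:(256 + off[1]), 1:(256 + off[2])])
})

test_that("extract_patch validates its inputs", {
  img <- matrix(0, 100, 100)
  expect_error(extract_patch(img, c(100, 50), 64L), "outside image bounds")
  expect_error(extract_patch(img, c(-1, 50), 64L), "outside image bounds")
  expect_error(extract_patch(img, c(50, 50), 63L), "even")
})

test_that("label_nucleus uses inclusive point-in-polygon with even-odd rule", {
  square <- cbind(c(10, 10, 20, 20), c(10, 20, 20, 10))
  expect_equal(label_nucleus(c(15, 15), list(square)), "gland")
  expect_equal(label_nucleus(c(5, 15), list(square)), "stroma")
  expect_equal(label_nucleus(c(10, 15), list(square)), "gland")  # on boundary
  expect_equal(label_nucleus(c(15, 15), list()), "stroma")       # empty set
  expect_error(label_nucleus(c(1, 1), list(square[1:2, ])), "V >= 3")
})

test_that("labeling matches an independent ray-casting oracle on random data", {
  set.seed(33)
  polys <- lapply(1:3, function(i)
    random_polygon(runif(2, 30, 170), 10, 28))
  centers <- matrix(runif(1000, 0, 200), ncol = 2)
  got <- label_nuclei(centers, polys)
  want <- vapply(seq_len(nrow(centers)), function(i)
    any(vapply(polys, function(p) pip_oracle(centers[i, ], p), logical(1))),
    logical(1))
  expect_equal(got == "gland", want)
})

test_that("build_biopsy_container labels and transforms records correctly", {
  sc <- tiny_scene(seed = 9)
  ct <- scene_container(sc, size = 64L)
  expect_length(ct$records, length(sc$nuclei))
  labs <- vapply(ct$records, function(r) r$label, character(1))
  expect_equal(labs, sc$labels)   # geometric labels equal generator truth
  # boundary stored in patch frame: slide = offset + patch vertices
  r1 <- ct$records[[1]]
  expect_equal(sweep(r1$boundary, 2, r1$slide_offset, "+"),
               sc$nuclei[[1]]$boundary, tolerance = 1e-12,
               ignore_attr = TRUE)
  # same scene at two sizes: identical labels, offsets differ by 16 per axis
  ct96 <- scene_container(sc, size = 96L)
  expect_equal(vapply(ct96$records, function(r) r$label, character(1)), labs)
  d <- t(vapply(seq_along(ct$records), function(i)
    ct$records[[i]]$slide_offset - ct96$records[[i]]$slide_offset,
    integer(2)))
  expect_true(all(d == 16L))
})

test_that("boundaries straddling the patch edge are clipped and flagged", {
  img <- matrix(0.5, 200, 200)
  # nucleus near center but with an exaggerated boundary sticking out
  big_boundary <- ellipse_polygon(c(100, 100), 40, 38, 0)
  nuc <- nucleus_record(1L, c(100, 100), big_boundary)
  ct <- build_biopsy_container(img, list(nuc), list(), 64L)
  rec <- ct$records[[1]]
  expect_true(isTRUE(attr(rec$boundary, "clipped")))
  expect_true(all(rec$boundary >= 0 & rec$boundary < 64))
  expect_length(ct$records, 1)
})

test_that("cohort split honors fractions with largest-remainder rounding", {
  ids <- sprintf("b%03d", 1:110)
  sp <- split_by_biopsy(ids, c(0.6, 0.2, 0.2), seed = 5)
  expect_length(sp$train_ids, 66)
  expect_length(sp$val_ids, 22)
  expect_length(sp$test_ids, 22)
  expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), ids)

  sp2 <- split_by_biopsy(ids, c(0.6, 0.2, 0.2), seed = 5)
  expect_identical(sp, sp2)   # deterministic under seed

  small <- split_by_biopsy(as.character(1:10), c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(lengths(unclass(small)), c(train_ids = 6L, val_ids = 2L,
                                          test_ids = 2L))
  expect_length(intersect(small$train_ids, small$val_ids), 0)
  expect_length(intersect(small$train_ids, small$test_ids), 0)
  expect_setequal(unlist(unclass(small)), as.character(1:10))

  expect_error(split_by_biopsy(ids, c(0.8, 0.2, 0)), "positive")
  expect_error(split_by_biopsy(ids, c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(split_by_biopsy(c("a", "b"), c(0.6, 0.2, 0.2)), "at least 3")
})
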