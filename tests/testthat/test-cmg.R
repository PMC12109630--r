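# Container format: round trips, appendability, reconstruction, corruption.

make_records <- function(n, size = 64L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    patch_record(
      nucleus_id = i,
      pixels = matrix(runif(size * size), size, size),
      boundary = ellipse_polygon(c(size / 2, size / 2), 6, 4, runif(1, 0, pi)),
      slide_offset = c(sample(seq(-size %/% 2, 100), 1), sample(0:100, 1)),
      label = sample(c("gland", "stroma", "unknown"), 1),
      prediction = if (i %% 2 == 0) runif(1) else NA_real_)
  })
}

test_that("containers round-trip losslessly through the binary format", {
  for (size in c(64L, 128L)) {
    ct <- biopsy_container("biopsy-A", c(400L, 380L), size,
                           make_records(3, size), pixel_spacing_um = 0.329)
    path <- withr::local_tempfile(fileext = ".cmg")
    write_container(ct, path)
    back <- read_container(path)
    expect_equal(back, ct)
    # write -> read -> write is byte-identical
    path2 <- withr::local_tempfile(fileext = ".cmg")
    write_container(back, path2)
    expect_identical(readBin(path, "raw", file.size(path)),
                     readBin(path2, "raw", file.size(path2)))
  }
})

test_that("an empty container is valid and round-trips", {
  ct <- biopsy_container("empty", c(100L, 100L), 64L)
  path <- withr::local_tempfile(fileext = ".cmg")
  write_container(ct, path)
  back <- read_container(path)
  expect_length(back$records, 0)
  expect_equal(back$biopsy_id, "empty")
})

test_that("appending preserves earlier records, order, and counts", {
  size <- 64L
  recs <- make_records(60, size, seed = 2)
  ct <- biopsy_container("grow", c(600L, 600L), size, recs[1:50])
  path <- withr::local_tempfile(fileext = ".cmg")
  write_container(ct, path)
  size_before <- file.size(path)
  append_records(path, recs[51:60])
  back <- read_container(path)
  expect_length(back$records, 60)
  expect_equal(vapply(back$records, function(r) r$nucleus_id, integer(1)), 1:60)
  expect_equal(back$records[[7]], recs[[7]])
  expect_equal(back$records[[55]], recs[[55]])
  # file grows linearly: append of 10 adds exactly 10 fixed-stride records
  per_record <- (file.size(path) - size_before) / 10
  ct1 <- biopsy_container("one", c(600L, 600L), size, recs[1])
  p1 <- withr::local_tempfile(fileext = ".cmg")
  write_container(ct1, p1)
  ct0 <- biopsy_container("one", c(600L, 600L), size)
  p0 <- withr::local_tempfile(fileext = ".cmg")
  write_container(ct0, p0)
  expect_equal(per_record,
               (file.size(p1) - file.size(p0)))
  # id collisions on append are rejected
  expect_error(append_records(path, recs[5]), "collide")
})

test_that("corrupt or truncated files raise format errors with byte offsets", {
  ct <- biopsy_container("bad", c(200L, 200L), 64L, make_records(2))
  path <- withr::local_tempfile(fileext = ".cmg")
  write_container(ct, path)
  raw <- readBin(path, "raw", file.size(path))
  raw[1:4] <- as.raw(c(0x58, 0x58, 0x58, 0x58))
  writeBin(raw, path)
  expect_error(read_container(path), "magic")

  write_container(ct, path)
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:(length(raw) - 100)], path)
  expect_error(read_container(path), "byte offset")

  # version bump is reported explicitly
  write_container(ct, path)
  raw <- readBin(path, "raw", file.size(path))
  raw[5] <- as.raw(9)
  writeBin(raw, path)
  expect_error(read_container(path), "version")
})

test_that("records violating invariants are rejected by name", {
  expect_error(patch_record(7, matrix(0, 4, 5), diag(3), c(0, 0)),
               "record 7.*square")
  expect_error(patch_record(8, matrix(0, 4, 4),
                            matrix(c(0, 0, 1, 5, 2, 1), 3, 2, byrow = TRUE),
                            c(0, 0)),
               "record 8.*within")
  tri <- matrix(c(0, 1, 2, 0, 2, 1), 3, 2)
  expect_error(patch_record(9, matrix(0, 4, 4), tri, c(0, 0),
                            prediction = 1.4),
               "record 9.*prediction")
  rec <- patch_record(1, matrix(0, 64, 64),
                      ellipse_polygon(c(32, 32), 5, 4, 0), c(0, 0))
  expect_error(biopsy_container("x", c(100, 100), 64, list(rec, rec)),
               "unique")
  far <- patch_record(2, matrix(0, 64, 64),
                      ellipse_polygon(c(32, 32), 5, 4, 0), c(90, 0))
  expect_error(biopsy_container("x", c(100, 100), 64, list(far)),
               "outside the mirror-padded")
})

test_that("reconstruction places patches exactly and handles empty containers", {
  rec <- patch_record(1, matrix(seq_len(64^2) / 64^2, 64, 64),
                      ellipse_polygon(c(32, 32), 5, 4, 0), c(0L, 0L))
  ct <- biopsy_container("one", c(100L, 120L), 64L, list(rec))
  canvas <- reconstruct_image(ct, background = 0)
  expect_equal(canvas[1:64, 1:64], rec$pixels)
  expect_true(all(canvas[65:100, ] == 0))

  empty <- biopsy_container("none", c(50L, 50L), 64L)
  blank <- reconstruct_image(empty, background = 0.7)
  expect_equal(blank, matrix(0.7, 50, 50))
})

test_that("reconstruction restores every covered pixel of a real scene", {
  sc <- tiny_scene(seed = 4)
  ct <- scene_container(sc)
  canvas <- reconstruct_image(ct, background = -1)
  covered <- canvas != -1
  expect_gt(mean(covered), 0.5)
  expect_equal(canvas[covered], sc$image[covered])
  # boundary drawing marks pixels without moving patches
  with_b <- reconstruct_image(ct, draw_boundaries = TRUE, background = -1,
                              boundary_value = 2)
  expect_gt(sum(with_b == 2), length(ct$records) * 8)
})
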