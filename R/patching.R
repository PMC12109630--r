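# Cell-centric patch extraction, gland/stroma labeling and cohort splitting.
#
# All public coordinates are 0-based (row, col) with half-open patch extents:
# a patch of size s at offset (r, c) covers slide rows r .. r+s-1. The nucleus
# center sits at patch index floor(s/2) on each axis, so for even sizes the
# offset is simply center - s/2 per axis and the convention is self-consistent
# between the 128 and 256 patch sizes.

#' Create a nucleus record
#'
#' One segmented nucleus: its center and boundary polygon in slide-frame
#' (0-based) coordinates.
#'
#' @param nucleus_id Integer id.
#' @param center Numeric `(row, col)` center, inside or on the boundary.
#' @param boundary `V x 2` matrix of slide-frame vertices, `V >= 3`, simple.
#' @return An object of class `nucleus_record`.
#' @export
nucleus_record <- function(nucleus_id, center, boundary) {
  if (!is.matrix(boundary) || ncol(boundary) != 2 || nrow(boundary) < 3)
    stop("boundary must be a V x 2 matrix with V >= 3", call. = FALSE)
  if (length(center) != 2) stop("center must be (row, col)", call. = FALSE)
  if (.pip_test(matrix(center, 1, 2), boundary) != 1L)
    stop(sprintf("nucleus %d: center must lie inside or on its boundary",
                 nucleus_id), call. = FALSE)
  structure(list(nucleus_id = as.integer(nucleus_id),
                 center = as.numeric(center),
                 boundary = boundary),
            class = "nucleus_record")
}

#' Extract a cell-centric patch
#'
#' Cuts a `size x size` tile whose designated center pixel
#' `(floor(size/2), floor(size/2))` is the nucleus center. Pixels falling
#' outside the image are filled by symmetric mirror reflection of the slide
#' (edge pixel included), so border nuclei yield full-size patches without
#' constant-color bands.
#'
#' @param image Numeric matrix (slide raster), or `(h, w, channels)` array.
#' @param center Integer-valued `(row, col)`, 0-based, within the image.
#' @param size Even patch edge length.
#' @return A list with `pixels` (the patch) and `slide_offset`
#'   (`center - size/2`, 0-based, possibly negative).
#' @export
extract_patch <- function(image, center, size) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (size %% 2L != 0L) stop("size must be even", call. = FALSE)
  if (length(center) != 2 || center[1] < 0 || center[1] >= h ||
      center[2] < 0 || center[2] >= w)
    stop(sprintf("center (%s) outside image bounds %d x %d",
                 paste(center, collapse = ", "), h, w), call. = FALSE)
  half <- as.integer(size / 2)
  offset <- as.integer(round(center)) - half
  rows <- reflect_index(offset[1]:(offset[1] + size - 1L), h) + 1L
  cols <- reflect_index(offset[2]:(offset[2] + size - 1L), w) + 1L
  pixels <- if (length(d) == 2L) image[rows, cols]
            else image[rows, cols, , drop = FALSE]
  list(pixels = pixels, slide_offset = offset)
}

#' Label a nucleus center as gland or stroma
#'
#' A nucleus is glandular iff its center lies inside any annotated gland
#' polygon under the even-odd rule; centers exactly on a polygon boundary are
#' counted as gland (inclusive convention). An empty annotation set labels
#' everything stroma.
#'
#' @param center Numeric `(row, col)`, 0-based slide frame.
#' @param glands List of gland polygons (`V x 2` matrices), possibly empty.
#' @return `"gland"` or `"stroma"`.
#' @export
label_nucleus <- function(center, glands) {
  label_nuclei(matrix(center, 1, 2), glands)
}

#' @rdname label_nucleus
#' @param centers `n x 2` matrix of centers.
#' @export
label_nuclei <- function(centers, glands) {
  centers <- as.matrix(centers)
  for (poly in glands) {
    if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3)
      stop("each gland polygon must be a V x 2 matrix with V >= 3",
           call. = FALSE)
  }
  inside <- rep(FALSE, nrow(centers))
  for (poly in glands)
    inside <- inside | (.pip_test(centers, poly) == 1L)
  ifelse(inside, "gland", "stroma")
}

#' Build a per-biopsy container from an image, nuclei and gland annotations
#'
#' One [patch_record()] per nucleus, in nucleus order: the patch is extracted
#' with [extract_patch()], the label assigned with [label_nucleus()] (or taken
#' from `labels` when supplied, e.g. corrupted annotations), and the nuclear
#' boundary translated into the patch frame. Boundary vertices that stick out
#' of the patch are clamped to its edge and the boundary flagged as clipped;
#' the record is retained.
#'
#' @param image Slide raster (matrix or `(h, w, c)` array).
#' @param nuclei List of [nucleus_record()]s.
#' @param glands List of gland polygons (may be empty).
#' @param size Patch edge length.
#' @param biopsy_id Container id.
#' @param labels Optional character vector overriding the geometric labels
#'   (one per nucleus, e.g. annotations with known misses).
#' @param pixel_spacing_um Micrometres per pixel.
#' @return A [biopsy_container()].
#' @export
build_biopsy_container <- function(image, nuclei, glands, size,
                                   biopsy_id = "biopsy",
                                   labels = NULL,
                                   pixel_spacing_um = 0.329) {
  d <- dim(image)
  if (!is.null(labels)) {
    assert_label(labels)
    if (length(labels) != length(nuclei))
      stop("labels must have one entry per nucleus", call. = FALSE)
  }
  records <- vector("list", length(nuclei))
  for (i in seq_along(nuclei)) {
    nuc <- nuclei[[i]]
    res <- tryCatch(extract_patch(image, nuc$center, size),
                    error = function(e)
                      stop(sprintf("nucleus %d: %s", nuc$nucleus_id,
                                   conditionMessage(e)), call. = FALSE))
    label <- if (is.null(labels)) label_nucleus(nuc$center, glands)
             else labels[i]
    bnd <- sweep(nuc$boundary, 2, res$slide_offset, "-")
    out_of_patch <- bnd < 0 | bnd > size - 1e-9
    if (any(out_of_patch)) {
      bnd <- pmin(pmax(bnd, 0), size - 1e-9)
      dim(bnd) <- c(nrow(nuc$boundary), 2L)
      attr(bnd, "clipped") <- TRUE
    }
    colnames(bnd) <- c("row", "col")
    records[[i]] <- patch_record(nuc$nucleus_id, res$pixels, bnd,
                                 res$slide_offset, label)
  }
  biopsy_container(biopsy_id, d[1:2], size, records, pixel_spacing_um,
                   channels = if (length(d) == 3L) d[3] else 1L)
}

#' Split biopsies into train/validation/test cohorts
#'
#' The split is by biopsy (case level), never by cell: all nuclei of one
#' biopsy land in the same cohort. Cohort sizes follow the fractions with
#' largest-remainder rounding, so they always sum to the number of biopsies;
#' the assignment is a seeded random permutation.
#'
#' @param biopsy_ids Character or integer vector of ids (>= 3, unique).
#' @param fractions Numeric `(train, val, test)`, each > 0, summing to 1.
#' @param seed Integer seed.
#' @return An object of class `cohort_split`: list with `train_ids`,
#'   `val_ids`, `test_ids`.
#' @export
split_by_biopsy <- function(biopsy_ids, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (anyDuplicated(biopsy_ids)) stop("biopsy_ids must be unique", call. = FALSE)
  if (length(biopsy_ids) < 3) stop("need at least 3 biopsies", call. = FALSE)
  if (length(fractions) != 3 || any(fractions <= 0))
    stop("fractions must be three positive values", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1", call. = FALSE)
  n <- length(biopsy_ids)
  exact <- fractions * n
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_rem <- order(exact - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(rem)]] <- sizes[order_rem[seq_len(rem)]] + 1
  }
  perm <- with_seed(seed, sample(biopsy_ids))
  structure(list(train_ids = perm[seq_len(sizes[1])],
                 val_ids = perm[sizes[1] + seq_len(sizes[2])],
                 test_ids = perm[sizes[1] + sizes[2] + seq_len(sizes[3])]),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("Cohort split: train %d / val %d / test %d biopsies\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids)))
  invisible(x)
}
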