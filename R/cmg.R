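# Per-biopsy cell-centric container ("CMG-style") binary format, version 1.
#
# All multi-byte values little-endian. Layout:
#
#   offset  size  field
#   0       4     magic "CMG1"
#   4       4     int32  format version (1)
#   8       4     int32  patch_size
#   12      4     int32  channels
#   16      4     int32  slide height (pixels)
#   20      4     int32  slide width (pixels)
#   24      8     float64 pixel spacing (micrometres per pixel)
#   32      4     int32  record count
#   36      4     int32  biopsy-id byte length L
#   40      L     UTF-8  biopsy id
#
# followed by `record count` records, each:
#
#   int32   nucleus_id
#   int32   slide offset row (0-based, may be negative: mirror-padded frame)
#   int32   slide offset col
#   int8    label code (0 = stroma, 1 = gland, 2 = unknown)
#   int8    has_prediction (0/1)
#   float64 prediction (0 when absent)
#   int8    boundary_clipped (0/1)
#   int32   boundary vertex count V
#   float64 x 2V  boundary vertices, patch frame, (row, col) interleaved
#   float64 x patch_size^2 x channels  pixels, column-major, channel planes last
#
# Records are fixed-layout given their own vertex count, and the file is
# append-only: adding records rewrites only the record-count field.

CMG_MAGIC <- charToRaw("CMG1")
CMG_VERSION <- 1L
CMG_COUNT_OFFSET <- 32L

#' Create a patch record
#'
#' One cell-centric patch: the image tile centered on a segmented nucleus, the
#' nuclear boundary polygon in patch-frame coordinates, and the patch's
#' placement in the slide frame. All coordinates are 0-based `(row, col)`.
#'
#' @param nucleus_id Integer id, unique within a container.
#' @param pixels `size x size` numeric matrix (or `size x size x channels`
#'   array) of intensities.
#' @param boundary Closed polygon, `V x 2` matrix of patch-frame vertices in
#'   `[0, size)`.
#' @param slide_offset Integer `(row, col)` of the patch's top-left corner in
#'   the slide frame (negative values lie in the mirror-padded border).
#' @param label `"gland"`, `"stroma"` or `"unknown"`.
#' @param prediction Optional gland probability in \[0, 1\] (`NA` if absent).
#' @return An object of class `patch_record`.
#' @export
patch_record <- function(nucleus_id, pixels, boundary, slide_offset,
                         label = "unknown", prediction = NA_real_) {
  rec <- structure(list(nucleus_id = as.integer(nucleus_id),
                        pixels = pixels,
                        boundary = boundary,
                        slide_offset = as.integer(slide_offset),
                        label = as.character(label),
                        prediction = as.numeric(prediction)),
                   class = "patch_record")
  validate_patch_record(rec)
  rec
}

validate_patch_record <- function(rec, patch_size = NULL) {
  d <- dim(rec$pixels)
  if (is.null(d) || length(d) < 2 || d[1] != d[2])
    stop(sprintf("record %d: pixels must be a square matrix or array",
                 rec$nucleus_id), call. = FALSE)
  size <- d[1]
  if (!is.null(patch_size) && size != patch_size)
    stop(sprintf("record %d: pixels are %dx%d but container patch_size is %d",
                 rec$nucleus_id, d[1], d[2], patch_size), call. = FALSE)
  if (!is.matrix(rec$boundary) || ncol(rec$boundary) != 2 || nrow(rec$boundary) < 3)
    stop(sprintf("record %d: boundary must be a V x 2 matrix with V >= 3",
                 rec$nucleus_id), call. = FALSE)
  if (any(rec$boundary < 0) || any(rec$boundary >= size))
    stop(sprintf("record %d: boundary vertices must lie within [0, %d)",
                 rec$nucleus_id, size), call. = FALSE)
  if (length(rec$slide_offset) != 2)
    stop(sprintf("record %d: slide_offset must have length 2", rec$nucleus_id),
         call. = FALSE)
  assert_label(rec$label)
  if (!is.na(rec$prediction) && (rec$prediction < 0 || rec$prediction > 1))
    stop(sprintf("record %d: prediction must be in [0, 1]", rec$nucleus_id),
         call. = FALSE)
  invisible(rec)
}

#' Create a per-biopsy container of cell-centric patches
#'
#' The container holds every nucleus of one biopsy as a [patch_record()],
#' together with slide metadata, and can be persisted with [write_container()]
#' and reassembled into the biopsy image with [reconstruct_image()].
#'
#' @param biopsy_id Character id of the biopsy.
#' @param slide_shape Integer `(height, width)` of the source image in pixels.
#' @param patch_size Patch edge length (the study used 128 or 256; any even
#'   size is accepted for scaled experiments).
#' @param records List of [patch_record()]s, ordered.
#' @param pixel_spacing_um Micrometres per pixel (0.329 for the reference
#'   scanner).
#' @param channels Number of image channels (1 = optical density raster).
#' @return An object of class `biopsy_container`.
#' @export
biopsy_container <- function(biopsy_id, slide_shape, patch_size,
                             records = list(), pixel_spacing_um = 0.329,
                             channels = 1L) {
  ct <- structure(list(biopsy_id = as.character(biopsy_id),
                       slide_shape = as.integer(slide_shape),
                       pixel_spacing_um = as.numeric(pixel_spacing_um),
                       patch_size = as.integer(patch_size),
                       channels = as.integer(channels),
                       records = records),
                  class = "biopsy_container")
  validate_container(ct)
  ct
}

validate_container <- function(ct) {
  if (ct$patch_size %% 2L != 0L)
    stop("patch_size must be even", call. = FALSE)
  if (length(ct$slide_shape) != 2 || any(ct$slide_shape <= 0))
    stop("slide_shape must be positive (height, width)", call. = FALSE)
  ids <- vapply(ct$records, function(r) r$nucleus_id, integer(1))
  if (anyDuplicated(ids))
    stop("nucleus_id values must be unique within a container (duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), ")", call. = FALSE)
  half <- ct$patch_size %/% 2L
  for (rec in ct$records) {
    validate_patch_record(rec, ct$patch_size)
    off <- rec$slide_offset
    if (off[1] < -half || off[2] < -half ||
        off[1] + ct$patch_size > ct$slide_shape[1] + half ||
        off[2] + ct$patch_size > ct$slide_shape[2] + half)
      stop(sprintf("record %d: slide_offset (%d, %d) places the patch outside the mirror-padded slide frame",
                   rec$nucleus_id, off[1], off[2]), call. = FALSE)
  }
  invisible(ct)
}

#' @export
print.biopsy_container <- function(x, ...) {
  labs <- vapply(x$records, function(r) r$label, character(1))
  cat(sprintf("Biopsy container '%s': %d records (patch %dx%d, slide %dx%d, %.3f um/px)\n",
              x$biopsy_id, length(x$records), x$patch_size, x$patch_size,
              x$slide_shape[1], x$slide_shape[2], x$pixel_spacing_um))
  if (length(labs))
    cat("  labels:", paste(sprintf("%s=%d", names(table(labs)), table(labs)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Convert a container's records to a per-nucleus data frame
#'
#' @param x A [biopsy_container()].
#' @param ... Unused.
#' @return Data frame with columns `nucleus_id`, `offset_row`, `offset_col`,
#'   `center_row`, `center_col`, `label`, `prediction`.
#' @export
as.data.frame.biopsy_container <- function(x, ...) {
  half <- x$patch_size %/% 2L
  do.call(rbind, lapply(x$records, function(r) data.frame(
    nucleus_id = r$nucleus_id,
    offset_row = r$slide_offset[1], offset_col = r$slide_offset[2],
    center_row = r$slide_offset[1] + half, center_col = r$slide_offset[2] + half,
    label = r$label, prediction = r$prediction)))
}

write_one_record <- function(con, rec, size, channels) {
  writeBin(rec$nucleus_id, con, size = 4, endian = "little")
  writeBin(as.integer(rec$slide_offset), con, size = 4, endian = "little")
  writeBin(.label_codes[[rec$label]], con, size = 1)
  writeBin(as.integer(!is.na(rec$prediction)), con, size = 1)
  writeBin(ifelse(is.na(rec$prediction), 0, rec$prediction), con,
           size = 8, endian = "little")
  writeBin(as.integer(isTRUE(attr(rec$boundary, "clipped"))), con, size = 1)
  writeBin(nrow(rec$boundary), con, size = 4, endian = "little")
  writeBin(as.numeric(t(rec$boundary)), con, size = 8, endian = "little")
  writeBin(as.numeric(rec$pixels), con, size = 8, endian = "little")
}

#' Write a biopsy container to disk
#'
#' Persists the container in the package's documented chunked binary layout
#' (see the format comment at the top of `R/cmg.R` and the methods vignette).
#' The layout is append-only: [append_records()] adds records without
#' rewriting existing ones.
#'
#' @param container A valid [biopsy_container()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(container, path) {
  validate_container(container)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CMG_MAGIC, con)
  writeBin(CMG_VERSION, con, size = 4, endian = "little")
  writeBin(container$patch_size, con, size = 4, endian = "little")
  writeBin(container$channels, con, size = 4, endian = "little")
  writeBin(container$slide_shape, con, size = 4, endian = "little")
  writeBin(container$pixel_spacing_um, con, size = 8, endian = "little")
  writeBin(length(container$records), con, size = 4, endian = "little")
  id_raw <- charToRaw(enc2utf8(container$biopsy_id))
  writeBin(length(id_raw), con, size = 4, endian = "little")
  writeBin(id_raw, con)
  for (rec in container$records)
    write_one_record(con, rec, container$patch_size, container$channels)
  invisible(path)
}

#' Append records to an existing container file
#'
#' Records are written after the existing ones and the header record count is
#' updated in place; earlier records are not rewritten.
#'
#' @param path Path to a file written by [write_container()].
#' @param records List of [patch_record()]s to append.
#' @return `path`, invisibly.
#' @export
append_records <- function(path, records) {
  hdr <- read_container_header(path)
  existing <- read_container(path)
  ids <- vapply(existing$records, function(r) r$nucleus_id, integer(1))
  new_ids <- vapply(records, function(r) r$nucleus_id, integer(1))
  if (any(new_ids %in% ids) || anyDuplicated(new_ids))
    stop("appended nucleus_id values collide with existing records",
         call. = FALSE)
  for (rec in records) validate_patch_record(rec, hdr$patch_size)
  con <- file(path, "r+b")
  on.exit(close(con))
  seek(con, 0, origin = "end", rw = "write")
  for (rec in records) write_one_record(con, rec, hdr$patch_size, hdr$channels)
  seek(con, CMG_COUNT_OFFSET, rw = "write")
  writeBin(hdr$record_count + length(records), con, size = 4, endian = "little")
  invisible(path)
}

cmg_format_error <- function(path, offset, what) {
  stop(sprintf("CMG format error in '%s' at byte offset %d: %s",
               path, offset, what), call. = FALSE)
}

read_exact <- function(con, path, what, n, size, type = "double") {
  off <- seek(con, NA)
  x <- readBin(con, what = type, n = n, size = size, endian = "little",
               signed = !(type == "integer" && size == 1))
  if (length(x) != n)
    cmg_format_error(path, off, sprintf("truncated while reading %s", what))
  x
}

read_container_header <- function(path, con = NULL) {
  owned <- is.null(con)
  if (owned) { con <- file(path, "rb"); on.exit(close(con)) }
  magic <- readBin(con, "raw", n = 4)
  if (length(magic) < 4 || !identical(magic, CMG_MAGIC))
    cmg_format_error(path, 0, "bad magic bytes (not a CMG container)")
  version <- read_exact(con, path, "version", 1, 4, "integer")
  if (version != CMG_VERSION)
    stop(sprintf("CMG version mismatch in '%s': file is version %d, reader supports %d",
                 path, version, CMG_VERSION), call. = FALSE)
  patch_size <- read_exact(con, path, "patch_size", 1, 4, "integer")
  channels <- read_exact(con, path, "channels", 1, 4, "integer")
  slide_shape <- read_exact(con, path, "slide_shape", 2, 4, "integer")
  spacing <- read_exact(con, path, "pixel_spacing", 1, 8)
  record_count <- read_exact(con, path, "record_count", 1, 4, "integer")
  id_len <- read_exact(con, path, "id length", 1, 4, "integer")
  id_raw <- readBin(con, "raw", n = id_len)
  if (length(id_raw) != id_len)
    cmg_format_error(path, seek(con, NA), "truncated biopsy id")
  list(patch_size = patch_size, channels = channels, slide_shape = slide_shape,
       pixel_spacing_um = spacing, record_count = record_count,
       biopsy_id = rawToChar(id_raw))
}

#' Read a biopsy container from disk
#'
#' @param path Path to a file written by [write_container()].
#' @return A [biopsy_container()], equal field-by-field to the written one.
#' @export
read_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_container_header(path, con)
  size <- hdr$patch_size
  npix <- size * size * hdr$channels
  records <- vector("list", hdr$record_count)
  for (i in seq_len(hdr$record_count)) {
    nucleus_id <- read_exact(con, path, "nucleus_id", 1, 4, "integer")
    offset <- read_exact(con, path, "slide_offset", 2, 4, "integer")
    label_code <- read_exact(con, path, "label", 1, 1, "integer")
    if (!label_code %in% .label_codes)
      cmg_format_error(path, seek(con, NA), sprintf("invalid label code %d", label_code))
    has_pred <- read_exact(con, path, "has_prediction", 1, 1, "integer")
    pred <- read_exact(con, path, "prediction", 1, 8)
    clipped <- read_exact(con, path, "boundary_clipped", 1, 1, "integer")
    nv <- read_exact(con, path, "vertex count", 1, 4, "integer")
    bnd <- matrix(read_exact(con, path, "boundary", 2 * nv, 8),
                  ncol = 2, byrow = TRUE)
    colnames(bnd) <- c("row", "col")
    if (clipped == 1L) attr(bnd, "clipped") <- TRUE
    px <- read_exact(con, path, "pixels", npix, 8)
    px <- if (hdr$channels == 1L) matrix(px, size, size)
          else array(px, dim = c(size, size, hdr$channels))
    records[[i]] <- structure(list(
      nucleus_id = nucleus_id, pixels = px, boundary = bnd,
      slide_offset = offset,
      label = names(.label_codes)[match(label_code, .label_codes)],
      prediction = if (has_pred == 1L) pred else NA_real_),
      class = "patch_record")
  }
  biopsy_container(hdr$biopsy_id, hdr$slide_shape, hdr$patch_size,
                   records, hdr$pixel_spacing_um, hdr$channels)
}

#' Reconstruct the biopsy image from a container
#'
#' Places each record's pixels at its slide offset on a canvas of the slide
#' shape; parts of a patch that fall in the mirror-padded border are clipped.
#' Overlapping patches (expected, since neighboring nuclei share pixels) are
#' resolved last-writer-wins in record order. With `draw_boundaries = TRUE`
#' each nuclear boundary polygon is burned into the canvas at
#' `slide_offset + patch-frame vertices`.
#'
#' @param container A [biopsy_container()].
#' @param draw_boundaries Draw the segmentation outlines.
#' @param background Canvas fill value for pixels covered by no patch.
#' @param boundary_value Intensity used for drawn boundary pixels.
#' @return A `slide_shape` numeric matrix (single channel) or array.
#' @export
reconstruct_image <- function(container, draw_boundaries = FALSE,
                              background = 1, boundary_value = 0) {
  validate_container(container)
  h <- container$slide_shape[1]; w <- container$slide_shape[2]
  nc <- container$channels
  canvas <- if (nc == 1L) matrix(background, h, w)
            else array(background, dim = c(h, w, nc))
  size <- container$patch_size
  for (rec in container$records) {
    off <- rec$slide_offset
    rr <- (off[1]):(off[1] + size - 1L)   # 0-based slide rows of the patch
    cc <- (off[2]):(off[2] + size - 1L)
    rkeep <- which(rr >= 0L & rr < h)
    ckeep <- which(cc >= 0L & cc < w)
    if (length(rkeep) == 0 || length(ckeep) == 0) next
    if (nc == 1L) {
      canvas[rr[rkeep] + 1L, cc[ckeep] + 1L] <- rec$pixels[rkeep, ckeep]
    } else {
      canvas[rr[rkeep] + 1L, cc[ckeep] + 1L, ] <- rec$pixels[rkeep, ckeep, , drop = FALSE]
    }
  }
  if (draw_boundaries) {
    for (rec in container$records) {
      poly <- sweep(rec$boundary, 2, rec$slide_offset, "+")
      px <- rasterize_outline(poly, c(h, w))
      if (nrow(px)) {
        if (nc == 1L) canvas[px + 1L] <- boundary_value
        else for (k in seq_len(nc)) canvas[cbind(px + 1L, k)] <- boundary_value
      }
    }
  }
  canvas
}
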