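# Import/export of the standard interchange formats around the container:
# PNG/TIFF rasters, CSV per-nucleus tables, JSON polygon sets.

#' Write / read a grayscale or RGB raster
#'
#' PNG via the png package; TIFF via the tiff package when installed.
#'
#' @param image Numeric matrix or `(h, w, 3)` array in \[0, 1\].
#' @param path Output path; format chosen by extension (.png/.tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(image, 0), 1)
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required for TIFF output", call. = FALSE)
    tiff::writeTIFF(img, path)
  } else stop("unsupported raster format: ", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required for TIFF input", call. = FALSE)
    return(tiff::readTIFF(path))
  }
  stop("unsupported raster format: ", ext, call. = FALSE)
}

#' Write / read a polygon set as JSON
#'
#' GeoJSON-flavored: a list of objects with `id` and `vertices`
#' (`[[row, col], ...]`, 0-based slide frame).
#'
#' @param polygons List of `V x 2` matrices (optionally named).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polygons, path) {
  ids <- names(polygons) %||% as.character(seq_along(polygons))
  obj <- lapply(seq_along(polygons), function(i)
    list(id = ids[i], vertices = unname(apply(polygons[[i]], 1, c, simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons
#' @export
read_polygons <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- lapply(obj, function(o) {
    m <- do.call(rbind, lapply(o$vertices, function(v) as.numeric(unlist(v))))
    colnames(m) <- c("row", "col")
    m
  })
  names(polys) <- vapply(obj, function(o) as.character(o$id), character(1))
  polys
}

#' Export a per-nucleus table
#'
#' CSV with one row per nucleus: id, center coordinates, label and prediction.
#'
#' @param container A [biopsy_container()].
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_nucleus_table <- function(container, path) {
  utils::write.csv(as.data.frame(container), path, row.names = FALSE)
  invisible(path)
}

#' Persist a synthetic scene as interchange files
#'
#' Writes `image.png`, `nuclei.csv` (id, row, col, label),
#' `nucleus_boundaries.json`, `glands.json` and `truth.csv` under `dir`.
#'
#' @param scene A [render_scene()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(scene$image, file.path(dir, "image.png"))
  df <- data.frame(
    nucleus_id = vapply(scene$nuclei, function(n) n$nucleus_id, integer(1)),
    row = vapply(scene$nuclei, function(n) n$center[1], numeric(1)),
    col = vapply(scene$nuclei, function(n) n$center[2], numeric(1)),
    label = scene$labels)
  utils::write.csv(df, file.path(dir, "nuclei.csv"), row.names = FALSE)
  bnds <- lapply(scene$nuclei, function(n) n$boundary)
  names(bnds) <- df$nucleus_id
  write_polygons(bnds, file.path(dir, "nucleus_boundaries.json"))
  write_polygons(scene$glands, file.path(dir, "glands.json"))
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  image <- read_raster(file.path(dir, "image.png"))
  if (length(dim(image)) == 3) image <- image[, , 1]
  df <- read_csv_plain(file.path(dir, "nuclei.csv"))
  bnds <- read_polygons(file.path(dir, "nucleus_boundaries.json"))
  glands <- unname(read_polygons(file.path(dir, "glands.json")))
  nuclei <- lapply(seq_len(nrow(df)), function(i)
    nucleus_record(df$nucleus_id[i], c(df$row[i], df$col[i]),
                   bnds[[as.character(df$nucleus_id[i])]]))
  structure(list(image = image, nuclei = nuclei, glands = glands,
                 labels = df$label, spec = NULL),
            class = "synthetic_scene")
}

#' Reference performance tables of the original GlandNet study
#'
#' Per-biopsy metric rows (accuracy, SN, SP, PPV, NPV, F1, percent) for the
#' patch-128 random test splits and the consensus best-3 / worst-3 test
#' biopsies, plus the `Average` rows (unweighted row means). Used by the
#' test suite to check the internal consistency of the metric definitions
#' (e.g. recomputing F1 from each SN/PPV pair).
#'
#' @return Data frame with columns `cohort`, `row`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `f1`.
#' @export
published_performance <- function() {
  read_csv_plain(system.file("extdata", "published_performance.csv",
                             package = "glandcell"))
}

#' Reference cohort counts of the original GlandNet study
#'
#' Biopsy, nucleus and gland-nucleus counts of the train/validation/test
#' cohorts and their totals.
#'
#' @return Data frame with columns `cohort`, `biopsies`, `nuclei`,
#'   `gland_nuclei`.
#' @export
published_counts <- function() {
  read_csv_plain(system.file("extdata", "published_counts.csv",
                             package = "glandcell"))
}
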