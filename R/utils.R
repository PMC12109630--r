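`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib glandcell, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Valid nucleus labels; "gland" is the positive class everywhere in the package.
.labels <- c("stroma", "gland", "unknown")
.label_codes <- c(stroma = 0L, gland = 1L, unknown = 2L)

assert_label <- function(x, allow_unknown = TRUE) {
  ok <- if (allow_unknown) .labels else .labels[1:2]
  bad <- setdiff(unique(as.character(x)), ok)
  if (length(bad) > 0)
    stop("invalid label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(ok, collapse = "/"), ")", call. = FALSE)
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Symmetric (edge-included) mirror fold of 0-based indices into [0, n).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  period <- 2L * n
  k <- i %% period
  ifelse(k < n, k, period - 1L - k)
}

# Vertices of an ellipse polygon, 0-based (row, col) coordinates.
ellipse_polygon <- function(center, major, minor, angle, n_vertices = 16L) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  x <- major * cos(t)
  y <- minor * sin(t)
  r <- center[1] + x * cos(angle) - y * sin(angle)
  c <- center[2] + x * sin(angle) + y * cos(angle)
  cbind(row = r, col = c)
}

# Dense-sample the outline of a closed polygon at sub-pixel steps and return
# unique integer pixel coordinates (0-based), clipped to the canvas.
rasterize_outline <- function(poly, shape) {
  m <- nrow(poly)
  pts <- lapply(seq_len(m), function(j) {
    k <- if (j == m) 1L else j + 1L
    d <- sqrt(sum((poly[k, ] - poly[j, ])^2))
    n <- max(2L, ceiling(d * 2))
    t <- seq(0, 1, length.out = n)
    cbind(poly[j, 1] + t * (poly[k, 1] - poly[j, 1]),
          poly[j, 2] + t * (poly[k, 2] - poly[j, 2]))
  })
  pts <- round(do.call(rbind, pts))
  keep <- pts[, 1] >= 0 & pts[, 1] < shape[1] & pts[, 2] >= 0 & pts[, 2] < shape[2]
  unique(pts[keep, , drop = FALSE])
}

# Integer pixel centers (0-based) inside-or-on a polygon, clipped to the canvas.
rasterize_fill <- function(poly, shape) {
  r0 <- max(0L, floor(min(poly[, 1]))); r1 <- min(shape[1] - 1L, ceiling(max(poly[, 1])))
  c0 <- max(0L, floor(min(poly[, 2]))); c1 <- min(shape[2] - 1L, ceiling(max(poly[, 2])))
  if (r1 < r0 || c1 < c0) return(matrix(numeric(0), 0, 2))
  grid <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  inside <- .pip_test(grid, poly) == 1L
  grid[inside, , drop = FALSE]
}

read_csv_plain <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
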