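#' Fan-beam acquisition geometry
#'
#' Describes a circular full-scan fan-beam acquisition: an X-ray source on a
#' circle of radius `source_radius` around the rotation axis and a flat,
#' equispatial virtual detector array that passes through the origin,
#' perpendicular to the source-origin direction. For view angle `theta` the
#' source sits at `(-R sin theta, R cos theta)` and the detector axis runs
#' along `(cos theta, sin theta)`; view `v` (1-based) uses
#' `theta = 2 pi (v - 1) / n_views`, equiangular over the full scan.
#'
#' @param n_views number of projections over `[0, 2*pi)`.
#' @param n_detectors number of detector elements (default 128).
#' @param source_radius source-to-rotation-axis distance in cm (default 57).
#' @param detector_length physical detector length in cm (default 20).
#' @return A `fan_geometry` object (list with the fields above plus
#'   `view_angles` in radians).
#' @export
fan_geometry <- function(n_views, n_detectors = 128L, source_radius = 57,
                         detector_length = 20) {
  if (n_views < 1 || n_detectors < 1) {
    stop("`n_views` and `n_detectors` must be >= 1", call. = FALSE)
  }
  if (source_radius <= 0 || detector_length <= 0) {
    stop("`source_radius` and `detector_length` must be positive", call. = FALSE)
  }
  structure(
    list(n_views = as.integer(n_views),
         n_detectors = as.integer(n_detectors),
         source_radius = source_radius,
         detector_length = detector_length,
         view_angles = 2 * pi * (seq_len(n_views) - 1) / n_views),
    class = "fan_geometry")
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat(sprintf(paste0("<fan_geometry> %d views x %d detectors, source radius ",
                     "%.4g cm, detector length %.4g cm\n"),
              x$n_views, x$n_detectors, x$source_radius, x$detector_length))
  invisible(x)
}

#' Build the area-weighted fan-beam system matrix
#'
#' For each measurement `m` (view `v`, detector element `d`, with
#' `m = (v - 1) * n_detectors + d`), the beam is the strip bounded by the two
#' rays joining the source point to the endpoints of detector element `d`.
#' The matrix entry `a[m, n]` is the exact area (cm^2) of the intersection of
#' that strip with pixel `n`'s square, computed by convex polygon clipping;
#' entries below `drop_tol` are dropped. Row sums `a_{m+}`, column sums
#' `a_{+n}` and the SART weighting diagonals `1/a_{m+}`, `1/a_{+n}` are
#' precomputed. Measurements whose beam misses the grid (`a_{m+} = 0`) and
#' pixels never intersected (`a_{+n} = 0`) carry a zero weight, which excludes
#' them from the SART update.
#'
#' Pixels are indexed column-major over the [ct_image] matrix
#' (`n = (c - 1) * nside + r`), matching `as.vector()` on the image.
#'
#' @param geom a [fan_geometry].
#' @param n image grid side length (pixels).
#' @param fov image field-of-view side length in cm (default 20).
#' @param drop_tol smallest retained intersection area in cm^2.
#' @return A `ct_system` object: list with sparse `A` (a
#'   `Matrix::dgCMatrix`), `row_sums`, `col_sums`, `lam_row`, `lam_col`,
#'   `geom`, `n`, `fov`, `pixel_size`.
#' @export
build_system_matrix <- function(geom, n, fov = 20, drop_tol = 1e-12) {
  stopifnot(inherits(geom, "fan_geometry"))
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer", call. = FALSE)
  if (geom$source_radius <= fov * sqrt(2) / 2) {
    stop("degenerate geometry: source inside the image square", call. = FALSE)
  }
  tr <- cpp_fan_system(geom$source_radius, geom$detector_length,
                       geom$n_detectors, geom$view_angles,
                       as.integer(n), fov, drop_tol)
  A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(tr$M, tr$N))
  A <- methods::as(A, "CsparseMatrix")
  new_ct_system(A, geom = geom, n = as.integer(n), fov = fov)
}

#' Wrap an arbitrary measurement matrix as a reconstruction system
#'
#' Builds the same container as [build_system_matrix] around a caller-supplied
#' nonnegative measurement matrix, e.g. a random compressed-sensing matrix.
#' The SART weighting diagonals are computed from its row and column sums.
#'
#' @param A an `M x N` matrix or `Matrix` sparse matrix with `N = n^2`.
#' @param n image grid side length (pixels).
#' @param fov field-of-view side length in cm.
#' @return A `ct_system`.
#' @export
as_ct_system <- function(A, n, fov = 20) {
  A <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  if (ncol(A) != n * n) stop("`A` must have n^2 columns", call. = FALSE)
  new_ct_system(A, geom = NULL, n = as.integer(n), fov = fov)
}

new_ct_system <- function(A, geom, n, fov) {
  row_sums <- Matrix::rowSums(A)
  col_sums <- Matrix::colSums(A)
  lam_row <- ifelse(row_sums > 0, 1 / row_sums, 0)
  lam_col <- ifelse(col_sums > 0, 1 / col_sums, 0)
  structure(
    list(A = A, row_sums = row_sums, col_sums = col_sums,
         lam_row = lam_row, lam_col = lam_col,
         geom = geom, n = n, fov = fov, pixel_size = fov / n),
    class = "ct_system")
}

#' @export
print.ct_system <- function(x, ...) {
  cat(sprintf("<ct_system> %d measurements x %d pixels (%d x %d grid), %d nonzeros\n",
              nrow(x$A), ncol(x$A), x$n, x$n, Matrix::nnzero(x$A)))
  if (!is.null(x$geom)) print(x$geom)
  invisible(x)
}

image_vec <- function(f, sys) {
  v <- if (is.matrix(f)) as.vector(as.matrix(f)) else as.numeric(f)
  if (length(v) != ncol(sys$A)) {
    stop("image size does not match the system matrix", call. = FALSE)
  }
  v
}

#' Forward projection
#'
#' Computes the sinogram `g = A f` by sparse matrix-vector product: each
#' measurement is the area-weighted sum of attenuation over the pixels the
#' beam strip intersects (cm^2 x attenuation).
#'
#' @param sys a `ct_system`.
#' @param f a [ct_image], matrix or length-`N` vector.
#' @return A `sinogram`: numeric vector of length
#'   `n_views * n_detectors`, measurement `m = (v - 1) * n_detectors + d`.
#' @export
forward_project <- function(sys, f) {
  stopifnot(inherits(sys, "ct_system"))
  g <- as.numeric(sys$A %*% image_vec(f, sys))
  new_sinogram(g, sys$geom)
}

#' Back projection
#'
#' Applies the transpose system matrix: `back_project(sys, r) = A' r`,
#' smearing a sinogram-shaped vector over the beam footprints.
#'
#' @param sys a `ct_system`.
#' @param r a sinogram or numeric vector of length `M`.
#' @return An `n x n` numeric matrix (image-shaped).
#' @export
back_project <- function(sys, r) {
  stopifnot(inherits(sys, "ct_system"))
  r <- as.numeric(r)
  if (length(r) != nrow(sys$A)) {
    stop("sinogram length does not match the system matrix", call. = FALSE)
  }
  matrix(as.numeric(Matrix::crossprod(sys$A, r)), sys$n, sys$n)
}

new_sinogram <- function(values, geom) {
  structure(as.numeric(values),
            n_views = if (is.null(geom)) NA_integer_ else geom$n_views,
            n_detectors = if (is.null(geom)) NA_integer_ else geom$n_detectors,
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d detectors, range [%.4g, %.4g]\n",
              attr(x, "n_views"), attr(x, "n_detectors"), min(x), max(x)))
  invisible(x)
}

#' @export
as.matrix.sinogram <- function(x, ...) {
  matrix(as.numeric(x), nrow = attr(x, "n_views"),
         ncol = attr(x, "n_detectors"), byrow = TRUE)
}

#' Add Gaussian measurement noise to a sinogram
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation
#' `level * max(g)` — a "0.1 percent" noise level means
#' `sd = 0.001 * max(g)`. Deterministic for a fixed `seed`.
#'
#' @param g a sinogram or numeric vector.
#' @param level noise level as a fraction of the maximum measurement
#'   (`>= 0`).
#' @param seed integer RNG seed; `NULL` uses (and advances) the session RNG.
#' @return The noisy sinogram, same shape as `g`.
#' @export
add_noise <- function(g, level, seed = NULL) {
  if (length(level) != 1L || !is.finite(level) || level < 0) {
    stop("`level` must be a single nonnegative number", call. = FALSE)
  }
  if (level == 0) return(g)
  e <- local_rng(seed, stats::rnorm(length(g), 0, level * max(as.numeric(g))))
  out <- as.numeric(g) + e
  attributes(out) <- attributes(g)
  out
}

# evaluate `expr` under a private RNG state when seed is given
local_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read and write sinograms as CSV
#'
#' The on-disk layout is one row per view and one column per detector
#' element, plain uncompressed CSV without row names.
#'
#' @param g a sinogram.
#' @param path file path.
#' @param geom the [fan_geometry] the file was produced under.
#' @return `write_sinogram` returns `path` invisibly; `read_sinogram` a
#'   `sinogram`.
#' @export
write_sinogram <- function(g, path) {
  utils::write.csv(as.matrix(g), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path, geom) {
  m <- as.matrix(utils::read.csv(path, header = TRUE))
  if (nrow(m) != geom$n_views || ncol(m) != geom$n_detectors) {
    stop("sinogram file shape does not match the geometry", call. = FALSE)
  }
  new_sinogram(as.vector(t(m)), geom)
}

#' Read and write geometry configuration blocks
#'
#' A small `key: value` text format carrying `source_radius_cm`,
#' `detector_length_cm`, `n_detectors` and `n_views`.
#'
#' @param geom a [fan_geometry].
#' @param path file path.
#' @export
write_geometry <- function(geom, path) {
  writeLines(c(
    sprintf("source_radius_cm: %.10g", geom$source_radius),
    sprintf("detector_length_cm: %.10g", geom$detector_length),
    sprintf("n_detectors: %d", geom$n_detectors),
    sprintf("n_views: %d", geom$n_views)), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  kv <- read.dcf(textConnection(gsub(": ", ": ", readLines(path))))
  get1 <- function(k) as.numeric(kv[1, k])
  fan_geometry(n_views = get1("n_views"), n_detectors = get1("n_detectors"),
               source_radius = get1("source_radius_cm"),
               detector_length = get1("detector_length_cm"))
}
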