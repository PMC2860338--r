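#' Orthonormal 2D Haar wavelet transform
#'
#' Full-depth (maximal dyadic level) separable 2D Haar decomposition with
#' orthonormal (unit-norm) filters, so Parseval holds exactly:
#' `sum(coeffs^2) == sum(f^2)`. At each level the row then column pairs of
#' the current approximation block are mapped to `(a + b)/sqrt(2)` and
#' `(a - b)/sqrt(2)`; the recursion continues on the approximation down to a
#' single scaling coefficient. The grid side must be a power of two.
#'
#' @param f a [ct_image] or square numeric matrix with dyadic side length.
#' @return A `haar_coeffs` vector of length `n^2` (column-major standard
#'   layout over the coefficient matrix), with attribute `n`.
#' @export
haar2 <- function(f) {
  m <- as.matrix(f)
  n <- nrow(m)
  if (ncol(m) != n) stop("image must be square", call. = FALSE)
  if (n > 1 && bitwAnd(n, n - 1L) != 0) {
    stop("grid side must be a power of two for the full-depth Haar transform",
         call. = FALSE)
  }
  out <- cpp_haar2_forward(as.numeric(m), as.integer(n))
  structure(out, n = n, class = "haar_coeffs")
}

#' Inverse orthonormal 2D Haar transform
#'
#' Exact inverse of [haar2]: `ihaar2(haar2(f))` reproduces `f` to machine
#' precision.
#'
#' @param c a `haar_coeffs` vector, or a numeric vector of length `n^2` with
#'   `n` supplied.
#' @param n grid side length (taken from the attribute when missing).
#' @param fov field-of-view side length of the reconstructed image, in cm.
#' @return A [ct_image].
#' @export
ihaar2 <- function(c, n = attr(c, "n"), fov = 20) {
  if (is.null(n)) stop("`n` is required when `c` carries no size attribute",
                       call. = FALSE)
  v <- as.numeric(c)
  if (length(v) != n * n) stop("coefficient length must equal n^2", call. = FALSE)
  out <- cpp_haar2_inverse(v, as.integer(n))
  ct_image(matrix(out, n, n), fov = fov)
}

#' Export transform coefficients as a flat CSV
#'
#' Writes one row per coefficient with columns `index` (1-based, column-major
#' standard layout) and `value`, for external inspection.
#'
#' @param c a coefficient vector.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_coeffs <- function(c, path) {
  utils::write.csv(
    data.frame(index = seq_along(c), value = as.numeric(c)),
    path, row.names = FALSE)
  invisible(path)
}

#' Count significant transform coefficients
#'
#' @param c a coefficient vector.
#' @param tol absolute magnitude threshold (`>= 0`); coefficients with
#'   `abs(c) > tol` are counted.
#' @return Integer count.
#' @examples
#' count_nonzero(haar2(shepp_logan(64)))
#' @export
count_nonzero <- function(c, tol = 1e-8) {
  if (tol < 0) stop("`tol` must be nonnegative", call. = FALSE)
  sum(abs(as.numeric(c)) > tol)
}
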