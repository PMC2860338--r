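#' The shrinkage companion map F and its inverse S
#'
#' `shrink_F()` evaluates `F_{w,p}(x) = x + w * p * sign(x) * |x|^(p-1)`,
#' a strictly increasing odd bijection of the real line for `p > 1`.
#' `shrink_S()` evaluates its inverse, the generalized soft-threshold
#' `S_{w,p} = F_{w,p}^{-1}`: for `p = 1` the classical soft-threshold
#' (`y - w` for `y >= w`, `0` for `|y| < w`, `y + w` for `y <= -w`), for
#' `p = 3/2` and `p = 2` closed forms, and for other `p` in `(1, 2)` a
#' safeguarded Newton/bisection inversion accurate to
#' `|F(S(y)) - y| <= 1e-10 * max(1, |y|)`.
#'
#' @param x,y numeric vectors.
#' @param p shrinkage exponent; `shrink_F` requires `p` in `(1, 2]`,
#'   `shrink_S` accepts `[1, 2]`.
#' @param w nonnegative threshold weight.
#' @return Numeric vector of the same length.
#' @export
shrink_F <- function(x, p, w) {
  check_pw(p, w, p_min_open = TRUE)
  x + w * p * sign(x) * abs(x)^(p - 1)
}

#' @rdname shrink_F
#' @export
shrink_S <- function(y, p, w) {
  check_pw(p, w)
  cpp_shrink(as.numeric(y), p, w)
}

check_pw <- function(p, w, p_min_open = FALSE) {
  lo_ok <- if (p_min_open) p > 1 else p >= 1
  if (length(p) != 1L || !is.finite(p) || !lo_ok || p > 2) {
    stop(sprintf("`p` must be a single value in %s",
                 if (p_min_open) "(1, 2]" else "[1, 2]"), call. = FALSE)
  }
  if (length(w) != 1L || !is.finite(w) || w < 0) {
    stop("`w` must be a single nonnegative number", call. = FALSE)
  }
  invisible(TRUE)
}

#' Componentwise shrinkage of a coefficient vector
#'
#' Applies [shrink_S] to every transform coefficient, i.e. the operator
#' that soft-thresholds an image in the sparse domain.
#'
#' @param c coefficient vector (attributes are preserved).
#' @inheritParams shrink_F
#' @return Shrunk coefficient vector.
#' @export
shrink_coeffs <- function(c, p, w) {
  out <- shrink_S(as.numeric(c), p, w)
  attributes(out) <- attributes(c)
  out
}

#' lp radius of a coefficient vector
#'
#' `(sum(|c|^p))^(1/p)`, the radius of the vector in the sparse domain; for
#' `p = 1` the l1 norm, for `p = 2` the Euclidean norm.
#'
#' @param c coefficient vector.
#' @param p exponent in `[1, 2]`.
#' @return A single number.
#' @export
lp_radius <- function(c, p = 1) {
  check_pw(p, 0)
  v <- abs(as.numeric(c))
  if (p == 1) sum(v) else if (p == 2) sqrt(sum(v^2)) else sum(v^p)^(1 / p)
}

#' Project a coefficient vector onto an lp ball
#'
#' If the vector already lies inside the ball (`lp_radius(c, p) <= radius`)
#' it is returned unchanged with threshold `mu = 0`. Otherwise the adaptive
#' threshold `mu > 0` is found by dichotomy (bisection) so that the shrunk
#' vector's lp radius equals `radius` within `tol * max(1, radius)`; the
#' shrunk radius is continuous and nonincreasing in `mu`, so the search is
#' globally convergent. The bracket starts at `[0, max(|c|)]` and is doubled
#' upward if needed (for `p > 1` shrinkage never reaches radius zero at a
#' finite threshold).
#'
#' @param c coefficient vector.
#' @param radius target lp radius (`>= 0`).
#' @param p exponent in `[1, 2]`.
#' @param tol relative radius tolerance of the dichotomy search.
#' @param max_steps bisection step cap.
#' @return A list with `coeffs` (projected vector, attributes preserved) and
#'   `mu` (the adapted threshold).
#' @export
project_lp_ball <- function(c, radius, p = 1, tol = 1e-8, max_steps = 200L) {
  check_pw(p, 0)
  if (length(radius) != 1L || !is.finite(radius) || radius < 0) {
    stop("`radius` must be a single nonnegative number", call. = FALSE)
  }
  res <- cpp_project_ball(as.numeric(c), radius, p, tol, as.integer(max_steps))
  attributes(res$coeffs) <- attributes(c)
  res
}
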