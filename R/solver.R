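#' SART-weighted residual backprojection
#'
#' Computes `rt = LamC A' LamR (g - A f)` where `LamR = diag(1/a_{m+})` and
#' `LamC = diag(1/a_{+n})` are the SART weighting diagonals (zero for beams
#' that miss the grid and pixels never intersected, which excludes them from
#' the update). With `weighted = FALSE` both diagonals are the identity and
#' the result is the plain backprojected residual `A'(g - A f)` of the
#' direct projected-gradient method.
#'
#' @param sys a `ct_system`.
#' @param g sinogram (numeric vector of length `M`).
#' @param f current image estimate ([ct_image], matrix or vector).
#' @param weighted apply the SART diagonals (default `TRUE`).
#' @return An `n x n` image-shaped matrix.
#' @export
sart_residual <- function(sys, g, f, weighted = TRUE) {
  stopifnot(inherits(sys, "ct_system"))
  res <- as.numeric(g) - as.numeric(sys$A %*% image_vec(f, sys))
  if (weighted) {
    rt <- sys$lam_col * as.numeric(Matrix::crossprod(sys$A, sys$lam_row * res))
  } else {
    rt <- as.numeric(Matrix::crossprod(sys$A, res))
  }
  matrix(rt, sys$n, sys$n)
}

#' One classical SART iteration
#'
#' `f <- f + lambda * rt` with `rt` the SART-weighted residual
#' backprojection, i.e. the simultaneous algebraic reconstruction technique
#' update with relaxation parameter `0 < lambda < 2`.
#'
#' @inheritParams sart_residual
#' @param lambda relaxation parameter in `(0, 2)`.
#' @return The updated image as an `n x n` matrix.
#' @export
sart_step <- function(f, sys, g, lambda = 1) {
  if (lambda < 0 || lambda >= 2) {
    stop("`lambda` must lie in [0, 2)", call. = FALSE)
  }
  matrix(image_vec(f, sys), sys$n, sys$n) + lambda * sart_residual(sys, g, f)
}

#' Scale constant relating SART weighting to the unweighted gradient
#'
#' Estimates `alpha = alpha0 * sqrt(max_n((A'A 1)_n) /
#' max_n((LamC A' LamR LamR A LamC 1)_n))`, the operator-norm bound ratio
#' between the unweighted and the SART-weighted normal operators, evaluated
#' with a few sparse matrix-vector products on the all-ones vector. `alpha0`
#' is a safety constant (2.0 by default); reduce it if the iteration
#' diverges.
#'
#' @param sys a `ct_system`.
#' @param alpha0 positive scale constant.
#' @return A single positive number.
#' @export
estimate_alpha <- function(sys, alpha0 = 2) {
  if (alpha0 <= 0) stop("`alpha0` must be positive", call. = FALSE)
  A <- sys$A
  num <- max(as.numeric(Matrix::crossprod(A, A %*% rep(1, ncol(A)))))
  t1 <- as.numeric(A %*% sys$lam_col)
  den <- max(sys$lam_col * as.numeric(Matrix::crossprod(A, sys$lam_row^2 * t1)))
  if (den <= 0 || num <= 0) {
    stop("cannot estimate alpha for an empty system matrix", call. = FALSE)
  }
  alpha0 * sqrt(num / den)
}

#' Steepest-descent step length
#'
#' `beta = ||r||^2 / ||A r||^2` for an image-shaped search direction `r`.
#'
#' @param sys a `ct_system`.
#' @param r image-shaped direction (matrix or vector), nonzero.
#' @return A single positive number; errors if `A r = 0` while `r != 0`
#'   (stagnation).
#' @export
step_size_beta <- function(sys, r) {
  v <- image_vec(r, sys)
  num <- sum(v^2)
  if (num == 0) stop("`r` must be nonzero", call. = FALSE)
  den <- sum(as.numeric(sys$A %*% v)^2)
  if (den == 0) stop("A r = 0 for nonzero r: iteration stagnated", call. = FALSE)
  num / den
}

#' Growing radius schedule of the interior scheme
#'
#' `R^k = (0.4 + 0.6 * (k / max_iter)^0.05) * R_star`: the target lp radius
#' starts at about 77 percent of `R_star` at `k = 1` (for the default
#' 20000-iteration budget) and reaches exactly `R_star` at `k = max_iter`,
#' slowly growing the feasible ball to stabilize severely ill-posed cases.
#'
#' @param k iteration index (`1 <= k <= max_iter`).
#' @param max_iter iteration budget.
#' @param R_star final target radius.
#' @return The radius target for iteration `k`.
#' @export
interior_radius <- function(k, max_iter, R_star) {
  (0.4 + 0.6 * (k / max_iter)^0.05) * R_star
}

#' One iteration of the reference iterative soft-thresholding algorithm
#'
#' `f <- S_{w,p}(f + A'(g - A f))` with the shrinkage applied to the Haar
#' coefficients of the Landweber update. Requires the caller to have
#' renormalized `A` so that `||A'A|| < 1`. With `w = 0` this is a plain
#' Landweber step. Reference implementation for cross-checks; the production
#' solver is [reconstruct].
#'
#' @inheritParams sart_residual
#' @param p shrinkage exponent in `[1, 2]`.
#' @param w threshold weight (`>= 0`).
#' @return The updated image as an `n x n` matrix.
#' @export
ista_step <- function(f, sys, g, p = 1, w = 0) {
  check_pw(p, w)
  f1 <- matrix(image_vec(f, sys), sys$n, sys$n) +
    sart_residual(sys, g, f, weighted = FALSE)
  if (w == 0) return(f1)
  as.matrix(ihaar2(shrink_coeffs(haar2(f1), p, w), fov = sys$fov))
}

#' Relative reconstruction error in percent
#'
#' `100 * ||f - f_ref||_2 / ||f_ref||_2`, the convergence and quality metric
#' logged by the solver.
#'
#' @param f image estimate (matrix or vector).
#' @param f_ref nonzero reference image (the ground truth in simulations).
#' @return A single nonnegative number (percent).
#' @export
rre <- function(f, f_ref) {
  f <- as.numeric(as.matrix(f)); f_ref <- as.numeric(as.matrix(f_ref))
  nref <- sqrt(sum(f_ref^2))
  if (nref == 0) stop("`f_ref` must be nonzero", call. = FALSE)
  100 * sqrt(sum((f - f_ref)^2)) / nref
}

#' Sparsity-constrained SART-type reconstruction
#'
#' Runs one of the iterative reconstruction schemes from a zero initial
#' image:
#'
#' * `"A"` — SART-weighted projected gradient: `f <- P_R(f + alpha * beta * rt)`
#'   with `rt` the SART-weighted residual backprojection, `beta` the
#'   steepest-descent step, `alpha` from [estimate_alpha], and `P_R` the
#'   projection onto the lp ball of radius `R_star` in the Haar domain.
#' * `"B"` — the same step without the sparsity projection.
#' * `"C"` — Scheme A with the growing radius schedule [interior_radius]
#'   (the "interior" variant).
#' * `"AD"`, `"BD"`, `"CD"` — direct counterparts: `alpha = 1` and identity
#'   weighting diagonals, so the step uses the plain backprojected residual
#'   `A'(g - A f)`.
#' * `"SART"` — classical SART: `f <- f + lambda * rt`, no `beta`, no
#'   projection.
#'
#' Iterations stop when the RRE against `f_true` drops below `rre_stop`
#' (percent) or after `max_iter` iterations. If the RRE (or, without ground
#' truth, the discrepancy) exceeds `div_factor` times its initial value or
#' becomes non-finite, the run aborts with a diagnostic suggesting a smaller
#' `alpha0`.
#'
#' @param sys a `ct_system` built by [build_system_matrix] or
#'   [as_ct_system].
#' @param g measured sinogram.
#' @param scheme one of `"A"`, `"B"`, `"C"`, `"AD"`, `"BD"`, `"CD"`,
#'   `"SART"`.
#' @param f_true ground-truth image for RRE logging and the default
#'   `R_star`; `NULL` disables both.
#' @param p sparsity exponent in `[1, 2]` (default 1, the compressed-sensing
#'   choice).
#' @param alpha0 scale constant passed to [estimate_alpha] (default 2.0).
#' @param R_star target lp radius of the solution's Haar coefficients;
#'   defaults to `lp_radius(haar2(f_true), p)`.
#' @param max_iter iteration cap (default 20000).
#' @param rre_stop stopping RRE in percent (default 0.1).
#' @param lambda relaxation parameter for `scheme = "SART"`.
#' @param div_factor divergence threshold as a multiple of the initial
#'   error.
#' @param mu_tol,mu_max_steps dichotomy tolerance and step cap of the ball
#'   projection.
#' @param f_init initial image (default: zeros, which makes the initial RRE
#'   100 percent and runs reproducible).
#' @return A `ct_recon` object: final `image` ([ct_image]), per-iteration
#'   `log` (tibble with `iteration`, `rre`, `beta`, `mu`, `discrepancy`),
#'   `scheme`, `alpha`, `R_star`, `iterations`, `status` (`"converged"`,
#'   `"max_iter"` or `"stagnated"`) and `final_rre`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
reconstruct <- function(sys, g, scheme = c("A", "B", "C", "AD", "BD", "CD", "SART"),
                        f_true = NULL, p = 1, alpha0 = 2, R_star = NULL,
                        max_iter = 20000L, rre_stop = 0.1, lambda = 1,
                        div_factor = 10, mu_tol = 1e-8, mu_max_steps = 200L,
                        f_init = NULL) {
  stopifnot(inherits(sys, "ct_system"))
  scheme <- match.arg(scheme)
  check_pw(p, 0)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  n <- sys$n
  N <- ncol(sys$A)
  g <- as.numeric(g)
  if (length(g) != nrow(sys$A)) {
    stop("sinogram length does not match the system matrix", call. = FALSE)
  }

  classical <- scheme == "SART"
  direct <- !classical && nchar(scheme) == 2L
  base <- substr(scheme, 1, 1)
  project <- !classical && base %in% c("A", "C")
  interior <- base == "C"
  if (project && (n < 1 || (n > 1 && bitwAnd(n, n - 1L) != 0))) {
    stop("schemes with the sparsity projection need a dyadic grid side",
         call. = FALSE)
  }

  has_truth <- !is.null(f_true)
  ft <- if (has_truth) image_vec(f_true, sys) else numeric(N)
  if (project) {
    if (is.null(R_star)) {
      if (!has_truth) {
        stop("`R_star` is required when no ground truth is supplied",
             call. = FALSE)
      }
      R_star <- lp_radius(haar2(matrix(ft, n, n)), p)
    }
  } else {
    R_star <- NA_real_
  }

  if (classical) {
    lam_row <- sys$lam_row; lam_col <- sys$lam_col
    alpha <- lambda; use_beta <- FALSE
  } else if (direct) {
    lam_row <- rep(1, nrow(sys$A)); lam_col <- rep(1, N)
    alpha <- 1; use_beta <- TRUE
  } else {
    lam_row <- sys$lam_row; lam_col <- sys$lam_col
    alpha <- estimate_alpha(sys, alpha0); use_beta <- TRUE
  }

  f0 <- if (is.null(f_init)) numeric(N) else image_vec(f_init, sys)
  res <- cpp_run_scheme(sys$A, g, lam_row, lam_col,
                        f0, ft, has_truth,
                        alpha, use_beta, project, interior,
                        p, if (is.na(R_star)) 0 else R_star, n,
                        as.integer(max_iter), rre_stop,
                        mu_tol, as.integer(mu_max_steps), div_factor,
                        0.4, 0.6, 0.05)

  if (res$status == 2L) {
    stop(sprintf(paste0("reconstruction diverged at iteration %d ",
                        "(error grew beyond %g times its initial value); ",
                        "try a smaller `alpha0`"),
                 res$iterations, div_factor), call. = FALSE)
  }

  k <- res$iterations
  log <- tibble::tibble(
    iteration = seq_len(k),
    rre = res$rre[seq_len(k)],
    beta = res$beta[seq_len(k)],
    mu = res$mu[seq_len(k)],
    discrepancy = res$discrepancy[seq_len(k)])

  structure(
    list(image = ct_image(matrix(res$f, n, n), fov = sys$fov),
         log = log, scheme = scheme, p = p, alpha = alpha,
         R_star = R_star, iterations = k,
         status = c("converged", "max_iter", "diverged", "stagnated")[res$status + 1L],
         final_rre = if (k > 0 && has_truth) res$rre[k] else NA_real_,
         config = list(alpha0 = alpha0, max_iter = max_iter,
                       rre_stop = rre_stop, lambda = lambda)),
    class = "ct_recon")
}

#' @export
print.ct_recon <- function(x, ...) {
  cat(sprintf("<ct_recon> scheme %s (p = %g), %d iterations, status: %s\n",
              x$scheme, x$p, x$iterations, x$status))
  if (!is.na(x$final_rre)) {
    cat(sprintf("  final RRE %.4f%% (alpha = %.4g)\n", x$final_rre, x$alpha))
  }
  invisible(x)
}

#' Tidy a reconstruction's convergence log
#'
#' @param x a `ct_recon`.
#' @param ... unused.
#' @return The per-iteration log tibble with columns `iteration`, `rre`
#'   (percent), `beta`, `mu`, `discrepancy`.
#' @export
tidy.ct_recon <- function(x, ...) x$log

#' One-row summary of a reconstruction
#'
#' @param x a `ct_recon`.
#' @param ... unused.
#' @return A one-row tibble with `scheme`, `p`, `alpha`, `R_star`,
#'   `iterations`, `final_rre`, `status`.
#' @export
glance.ct_recon <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, p = x$p, alpha = x$alpha,
                 R_star = x$R_star, iterations = x$iterations,
                 final_rre = x$final_rre, status = x$status)
}

#' Convergence curve of a reconstruction
#'
#' Plots the relative reconstruction error (log10 scale) against the
#' iteration index.
#'
#' @param object a `ct_recon`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ct_recon <- function(object, ...) {
  df <- object$log[!is.na(object$log$rre), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$rre)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration k", y = "RRE (%)",
                  title = sprintf("Scheme %s", object$scheme))
}
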