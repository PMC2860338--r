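#' Pixel images on a centred square field of view
#'
#' A `ct_image` is an `n x n` numeric matrix with a physical field of view
#' attached. Row 1 is the top of the image, column 1 the left; the pixel at
#' row `r`, column `c` has its centre at
#' `x = -fov/2 + (c - 1/2) * pixel_size`, `y = fov/2 - (r - 1/2) * pixel_size`
#' (cm), so the grid is centred on the rotation axis. Attenuation values are
#' dimensionless.
#'
#' @param values numeric `n x n` matrix of attenuation values.
#' @param fov field-of-view side length in cm (default 20).
#' @return A `ct_image` object (a matrix with `fov` and `pixel_size`
#'   attributes).
#' @export
ct_image <- function(values, fov = 20) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 1L || ncol(values) != n) {
    stop("`values` must be a square matrix with n >= 1", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("image values must be finite", call. = FALSE)
  if (fov <= 0) stop("`fov` must be positive", call. = FALSE)
  structure(values, fov = fov, pixel_size = fov / n,
            class = c("ct_image", class(values)))
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %d x %d pixels, %.4g cm field of view (%.4g cm/pixel)\n",
              nrow(x), ncol(x), attr(x, "fov"), attr(x, "pixel_size")))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @export
as.matrix.ct_image <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Ellipse table of the modified Shepp-Logan phantom
#'
#' The canonical ten-ellipse description of the modified (high-contrast)
#' Shepp-Logan head phantom on the unit disc: intensity (additive), semi-axes
#' `a`, `b`, centre `(x0, y0)` and tilt `phi` in degrees (counter-clockwise).
#'
#' @return A tibble with one row per ellipse and columns
#'   `intensity`, `a`, `b`, `x0`, `y0`, `phi`.
#' @export
shepp_logan_ellipses <- function() {
  tibble::tribble(
    ~intensity,     ~a,     ~b,    ~x0,     ~y0, ~phi,
           1.0,    .69,    .92,     0,       0,    0,
           -.8,  .6624,  .8740,     0,  -.0184,    0,
           -.2,  .1100,  .3100,   .22,       0,  -18,
           -.2,  .1600,  .4100,  -.22,       0,   18,
            .1,  .2100,  .2500,     0,     .35,    0,
            .1,  .0460,  .0460,     0,      .1,    0,
            .1,  .0460,  .0460,     0,     -.1,    0,
            .1,  .0460,  .0230,  -.08,   -.605,    0,
            .1,  .0230,  .0230,     0,   -.605,    0,
            .1,  .0230,  .0460,   .06,   -.605,    0
  )
}

#' Modified Shepp-Logan phantom
#'
#' Rasterizes the ten-ellipse modified Shepp-Logan head phantom at pixel
#' centres on the square `[-fov/2, fov/2]^2`. The unit-disc ellipse
#' coordinates are scaled to the compact support radius `fov/2` (10 cm by
#' default). A pixel's value is the sum of the intensities of every ellipse
#' whose (inclusive) membership inequality its centre satisfies; pixels
#' outside all ellipses are exactly zero. Point sampling, no anti-aliasing.
#'
#' @param n grid side length (pixels); `n >= 2`.
#' @param fov field-of-view side length in cm (default 20, i.e. a 10 cm
#'   support radius).
#' @return A [ct_image] of size `n x n`.
#' @examples
#' ph <- shepp_logan(64)
#' range(ph)
#' @export
shepp_logan <- function(n, fov = 20) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  ax <- -1 + (seq_len(n) - 0.5) * 2 / n   # pixel-centre coordinates, unit scale
  x <- matrix(ax, n, n, byrow = TRUE)     # column c -> x
  y <- matrix(rev(ax), n, n)              # row 1 -> top (y = +1 - 1/n)
  # accumulate in integer tenths (all table intensities are multiples of 0.1)
  # so regions where intensities cancel come out exactly zero
  f <- matrix(0, n, n)
  ell <- shepp_logan_ellipses()
  for (i in seq_len(nrow(ell))) {
    t <- ell$phi[i] * pi / 180
    xr <- (x - ell$x0[i]) * cos(t) + (y - ell$y0[i]) * sin(t)
    yr <- -(x - ell$x0[i]) * sin(t) + (y - ell$y0[i]) * cos(t)
    inside <- (xr / ell$a[i])^2 + (yr / ell$b[i])^2 <= 1
    f <- f + round(10 * ell$intensity[i]) * inside
  }
  ct_image(f / 10, fov = fov)
}

#' Clamp an image to a display window
#'
#' Linearly maps values in `[window[1], window[2]]` to `[0, 1]`, clamping
#' values outside the window, as done when displaying reconstructions with a
#' fixed grey-level window.
#'
#' @param f a [ct_image] or numeric matrix.
#' @param window length-2 numeric `c(lo, hi)`, `lo < hi`.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
render_image <- function(f, window = c(0, 0.5)) {
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2]) {
    stop("`window` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  m <- as.matrix(f)
  m <- (m - window[1]) / (window[2] - window[1])
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

#' @export
autoplot.ct_image <- function(object, window = NULL, ...) {
  n <- nrow(object)
  if (is.null(window)) window <- range(object)
  df <- data.frame(
    x = rep(seq_len(n), each = n),
    y = rep(rev(seq_len(n)), n),
    value = as.vector(as.matrix(object)[, seq_len(n)])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = window, oob = scales_squish) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "f") +
    ggplot2::theme_void()
}

# clamp out-of-bounds values instead of dropping them (avoids a scales dep)
scales_squish <- function(x, range = c(0, 1), ...) {
  x[x < range[1]] <- range[1]
  x[x > range[2]] <- range[2]
  x
}
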