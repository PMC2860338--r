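# Independent oracles, kept deliberately naive (scalar loops, dense algebra)
# so they share no code with the package implementation.

# Brute-force phantom: evaluate the ten ellipse membership inequalities at
# one pixel-centre coordinate at a time.
oracle_phantom <- function(n) {
  tab <- list(
    c(1.0, .69, .92, 0, 0, 0),
    c(-.8, .6624, .8740, 0, -.0184, 0),
    c(-.2, .1100, .3100, .22, 0, -18),
    c(-.2, .1600, .4100, -.22, 0, 18),
    c(.1, .2100, .2500, 0, .35, 0),
    c(.1, .0460, .0460, 0, .1, 0),
    c(.1, .0460, .0460, 0, -.1, 0),
    c(.1, .0460, .0230, -.08, -.605, 0),
    c(.1, .0230, .0230, 0, -.605, 0),
    c(.1, .0230, .0460, .06, -.605, 0))
  f <- matrix(0, n, n)
  for (r in seq_len(n)) {
    for (c in seq_len(n)) {
      x <- -1 + (c - 0.5) * 2 / n
      y <- 1 - (r - 0.5) * 2 / n
      v <- 0
      for (e in tab) {
        t <- e[6] * pi / 180
        xr <- (x - e[4]) * cos(t) + (y - e[5]) * sin(t)
        yr <- -(x - e[4]) * sin(t) + (y - e[5]) * cos(t)
        if ((xr / e[2])^2 + (yr / e[3])^2 <= 1) v <- v + e[1]
      }
      f[r, c] <- v
    }
  }
  f
}

# Convex polygon clipping in plain R (clip `poly` = list(x, y) against the
# half-plane a*x + b*y >= d), plus the shoelace area.
oracle_clip <- function(poly, a, b, d) {
  np <- length(poly$x)
  x <- c(); y <- c()
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    si <- a * poly$x[i] + b * poly$y[i] - d
    sj <- a * poly$x[j] + b * poly$y[j] - d
    if (si >= 0) { x <- c(x, poly$x[i]); y <- c(y, poly$y[i]) }
    if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
      t <- si / (si - sj)
      x <- c(x, poly$x[i] + t * (poly$x[j] - poly$x[i]))
      y <- c(y, poly$y[i] + t * (poly$y[j] - poly$y[i]))
    }
  }
  list(x = x, y = y)
}

oracle_area <- function(poly) {
  np <- length(poly$x)
  if (np < 3) return(0)
  s <- 0
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    s <- s + poly$x[i] * poly$y[j] - poly$x[j] * poly$y[i]
  }
  abs(s) / 2
}

# The beam strip of measurement m = (v-1)*n_det + d as an extended triangle
# (same geometric convention as the package, independent code path).
oracle_beam_triangle <- function(geom, m) {
  v <- (m - 1) %/% geom$n_detectors + 1L
  d <- (m - 1) %% geom$n_detectors + 1L
  th <- 2 * pi * (v - 1) / geom$n_views
  S <- c(-geom$source_radius * sin(th), geom$source_radius * cos(th))
  u <- c(cos(th), sin(th))
  w <- geom$detector_length / geom$n_detectors
  t0 <- -geom$detector_length / 2 + (d - 1) * w
  ends <- lapply(c(t0, t0 + w), function(t) {
    P <- t * u
    S + 4 * (P - S)   # well past the far side of any test image
  })
  list(x = c(S[1], ends[[1]][1], ends[[2]][1]),
       y = c(S[2], ends[[1]][2], ends[[2]][2]))
}

# Area of beam strip m clipped to the image square [-fov/2, fov/2]^2.
oracle_strip_area <- function(geom, m, fov) {
  h <- fov / 2
  poly <- oracle_beam_triangle(geom, m)
  poly <- oracle_clip(poly, 1, 0, -h)
  poly <- oracle_clip(poly, -1, 0, -h)
  poly <- oracle_clip(poly, 0, 1, -h)
  poly <- oracle_clip(poly, 0, -1, -h)
  oracle_area(poly)
}

# Area of beam strip m intersected with one pixel square, by dense subpixel
# point sampling (ns x ns points per pixel).
oracle_pixel_area <- function(geom, m, fov, n, row, col, ns = 48) {
  tri <- oracle_beam_triangle(geom, m)
  # inside test via sign of cross products against all three edges
  inside_tri <- function(x, y) {
    s <- numeric(3)
    for (i in 1:3) {
      j <- if (i == 3) 1L else i + 1L
      s[i] <- (tri$x[j] - tri$x[i]) * (y - tri$y[i]) -
        (tri$y[j] - tri$y[i]) * (x - tri$x[i])
    }
    all(s >= 0) || all(s <= 0)
  }
  psz <- fov / n
  x0 <- -fov / 2 + (col - 1) * psz
  y0 <- fov / 2 - row * psz
  hits <- 0L
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (inside_tri(x0 + (i - 0.5) * psz / ns, y0 + (j - 0.5) * psz / ns)) {
        hits <- hits + 1L
      }
    }
  }
  hits / ns^2 * psz^2
}

# Exact sort-based projection of a vector onto the l1 ball of radius R
# (Duchi-style threshold from the sorted magnitudes).
oracle_l1_project <- function(c, R) {
  a <- abs(c)
  if (sum(a) <= R) return(list(coeffs = c, mu = 0))
  u <- sort(a, decreasing = TRUE)
  cs <- cumsum(u)
  k <- max(which(u > (cs - R) / seq_along(u)))
  mu <- (cs[k] - R) / k
  list(coeffs = sign(c) * pmax(a - mu, 0), mu = mu)
}

# Full-depth orthonormal 1D Haar analysis matrix by level recursion.
oracle_haar_matrix <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  h <- n / 2
  T <- matrix(0, n, n)
  for (i in seq_len(h)) {
    T[i, 2 * i - 1] <- 1 / sqrt(2); T[i, 2 * i] <- 1 / sqrt(2)
    T[h + i, 2 * i - 1] <- 1 / sqrt(2); T[h + i, 2 * i] <- -1 / sqrt(2)
  }
  rbind(cbind(oracle_haar_matrix(h), matrix(0, h, h)),
        cbind(matrix(0, h, h), diag(h))) %*% T
}

# Small cached fan-beam fixtures shared across tests.
.fixtures <- new.env(parent = emptyenv())
fixture_system <- function(n, n_views, n_det = n, fov = 20) {
  key <- sprintf("sys_%d_%d_%d_%g", n, n_views, n_det, fov)
  if (is.null(.fixtures[[key]])) {
    geom <- fan_geometry(n_views, n_detectors = n_det)
    .fixtures[[key]] <- build_system_matrix(geom, n, fov = fov)
  }
  .fixtures[[key]]
}
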