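test_that("a pixel wholly inside a beam strip gets its full area", {
  # one wide detector element, a 1x1 grid: the single 2x2 cm pixel sits
  # entirely inside the beam strip
  geom <- fan_geometry(1, n_detectors = 1, detector_length = 20)
  sys <- build_system_matrix(geom, 1, fov = 2)
  expect_equal(as.matrix(sys$A)[1, 1], 4, tolerance = 1e-12)
})

test_that("row sums equal the beam strip area clipped to the image square", {
  geom <- fan_geometry(4, n_detectors = 8)
  sys <- build_system_matrix(geom, 16)
  expected <- vapply(seq_len(nrow(sys$A)), function(m) {
    oracle_strip_area(geom, m, fov = 20)
  }, numeric(1))
  expect_equal(sys$row_sums, expected, tolerance = 1e-9)
})

test_that("individual interaction areas match a dense subpixel oracle", {
  geom <- fan_geometry(2, n_detectors = 4)
  n <- 8L
  sys <- build_system_matrix(geom, n)
  A <- as.matrix(sys$A)
  psz <- 20 / n
  set.seed(42)
  cells <- which(A > 0.05 * psz^2, arr.ind = TRUE)
  cells <- cells[sample(nrow(cells), 12L), , drop = FALSE]
  for (i in seq_len(nrow(cells))) {
    m <- cells[i, 1]
    j <- cells[i, 2]
    col <- (j - 1) %/% n + 1L
    row <- (j - 1) %% n + 1L
    approx <- oracle_pixel_area(geom, m, 20, n, row, col)
    expect_lt(abs(A[m, j] - approx), 0.05 * psz^2)
  }
})

test_that("forward projection is the sparse product A f", {
  sys <- fixture_system(16L, 8L)
  expect_equal(as.numeric(forward_project(sys, matrix(0, 16, 16))),
               rep(0, nrow(sys$A)))
  g <- forward_project(sys, matrix(3, 16, 16))
  expect_equal(as.numeric(g), 3 * sys$row_sums, tolerance = 1e-12)
  expect_error(forward_project(sys, matrix(1, 8, 8)), "size")
})

test_that("back projection is the dense transpose product", {
  geom <- fan_geometry(2, n_detectors = 4)
  sys <- build_system_matrix(geom, 4)
  Ad <- as.matrix(sys$A)
  set.seed(1)
  r <- rnorm(nrow(Ad))
  expect_equal(as.vector(back_project(sys, r)), as.vector(t(Ad) %*% r),
               tolerance = 1e-12)
  expect_equal(back_project(sys, rep(0, nrow(Ad))), matrix(0, 4, 4))
  # a unit sinogram vector picks out one beam footprint
  e <- numeric(nrow(Ad)); e[5] <- 1
  expect_equal(as.vector(back_project(sys, e)), Ad[5, ], tolerance = 1e-14)
})

test_that("forward and back projection are adjoint to 1e-10 relative", {
  sys <- fixture_system(16L, 8L)
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(ncol(sys$A))
    y <- rnorm(nrow(sys$A))
    lhs <- sum(as.numeric(sys$A %*% x) * y)
    rhs <- sum(x * as.vector(back_project(sys, y)))
    expect_lt(abs(lhs - rhs), 1e-10 * max(1, abs(lhs)))
  }
})

test_that("quarter-turn symmetry: rotated phantom, rotated views, same sinogram", {
  n <- 16L
  ph <- as.matrix(shepp_logan(n))
  geomA <- fan_geometry(6, n_detectors = 8)
  sysA <- build_system_matrix(geomA, n)
  # rotate view angles by 90 degrees and the image by 90 degrees
  geomB <- geomA
  geomB$view_angles <- geomA$view_angles + pi / 2
  sysB <- build_system_matrix(geomB, n)
  rot90 <- function(m) t(m[, ncol(m):1])  # 90 deg counter-clockwise
  gA <- as.numeric(forward_project(sysA, ph))
  gB <- as.numeric(forward_project(sysB, rot90(ph)))
  expect_equal(gA, gB, tolerance = 1e-9)
  # and the total intercepted area is exactly invariant under quarter turns
  expect_equal(sum(sysA$row_sums), sum(sysB$row_sums), tolerance = 1e-10)
})

test_that("degenerate geometry is rejected", {
  geom <- fan_geometry(4, source_radius = 5)
  expect_error(build_system_matrix(geom, 16), "degenerate")
  expect_error(fan_geometry(0), "n_views")
})

test_that("additive Gaussian noise is max-referenced, seeded and exact at level 0", {
  sys <- fixture_system(16L, 8L)
  g <- forward_project(sys, shepp_logan(16))
  expect_identical(add_noise(g, 0), g)
  n1 <- add_noise(g, 0.001, seed = 11)
  n2 <- add_noise(g, 0.001, seed = 11)
  expect_identical(n1, n2)
  expect_false(identical(as.numeric(n1), as.numeric(g)))
  expect_error(add_noise(g, -1), "nonnegative")
  # Monte-Carlo check of the noise scale over 1e5 draws
  gg <- rep(as.numeric(g), length.out = 1e5)
  e <- add_noise(gg, 0.001, seed = 3) - gg
  expect_lt(abs(sd(e) / (0.001 * max(gg)) - 1), 0.02)
})

test_that("sinogram and geometry round-trip through their text formats", {
  geom <- fan_geometry(5, n_detectors = 8, source_radius = 57,
                       detector_length = 20)
  sys <- build_system_matrix(geom, 16)
  g <- forward_project(sys, shepp_logan(16))
  tmp <- tempfile(fileext = ".csv")
  write_sinogram(g, tmp)
  g2 <- read_sinogram(tmp, geom)
  expect_equal(as.numeric(g2), as.numeric(g), tolerance = 1e-12)
  expect_equal(dim(as.matrix(g)), c(5L, 8L))
  tmp2 <- tempfile(fileext = ".txt")
  write_geometry(geom, tmp2)
  geom2 <- read_geometry(tmp2)
  expect_equal(geom2$source_radius, 57)
  expect_equal(geom2$n_views, 5L)
  expect_equal(geom2$view_angles, geom$view_angles)
  unlink(c(tmp, tmp2))
})
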