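dense_sart_residual <- function(A, g, f) {
  # straight dense evaluation of LamC A' LamR (g - A f)
  lamR <- ifelse(rowSums(A) > 0, 1 / rowSums(A), 0)
  lamC <- ifelse(colSums(A) > 0, 1 / colSums(A), 0)
  as.vector(diag(lamC) %*% t(A) %*% diag(lamR) %*% (g - A %*% f))
}

test_that("the SART residual vanishes on consistent data and matches dense algebra", {
  geom <- fan_geometry(2, n_detectors = 4)
  sys <- build_system_matrix(geom, 4)
  ph <- matrix(runif(16), 4, 4)
  g <- forward_project(sys, ph)
  expect_lt(max(abs(sart_residual(sys, g, ph))), 1e-12)
  # from zero, against the dense oracle
  Ad <- as.matrix(sys$A)
  expect_equal(as.vector(sart_residual(sys, as.numeric(g), matrix(0, 4, 4))),
               dense_sart_residual(Ad, as.numeric(g), numeric(16)),
               tolerance = 1e-12)
  # linear in the data residual
  r1 <- sart_residual(sys, as.numeric(g), matrix(0, 4, 4))
  r2 <- sart_residual(sys, 2 * as.numeric(g), matrix(0, 4, 4))
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
})

test_that("classical SART: fixed point at truth, error decreases on a well-posed toy", {
  sys <- fixture_system(16L, 30L)
  ph <- shepp_logan(16)
  g <- forward_project(sys, ph)
  expect_equal(sart_step(ph, sys, g, lambda = 0), as.matrix(ph),
               tolerance = 1e-14)
  expect_equal(sart_step(ph, sys, g, lambda = 1), as.matrix(ph),
               tolerance = 1e-10)
  f <- matrix(0, 16, 16)
  errs <- numeric(20)
  for (k in 1:20) {
    f <- sart_step(f, sys, g, lambda = 1)
    errs[k] <- rre(f, ph)
  }
  expect_true(all(diff(errs) < 0))
})

test_that("alpha estimation: identity system gives alpha0, dense oracle agrees", {
  sysI <- as_ct_system(Matrix::Diagonal(16, 1), n = 4)
  expect_equal(estimate_alpha(sysI, 2), 2, tolerance = 1e-12)
  expect_equal(estimate_alpha(sysI, 0.7), 0.7, tolerance = 1e-12)
  set.seed(4)
  A <- matrix(runif(8 * 16), 8, 16)
  sys <- as_ct_system(A, n = 4)
  lamR <- diag(1 / rowSums(A)); lamC <- diag(1 / colSums(A))
  ones <- rep(1, 16)
  num <- max(t(A) %*% A %*% ones)
  den <- max(lamC %*% t(A) %*% lamR %*% lamR %*% A %*% lamC %*% ones)
  expect_equal(estimate_alpha(sys, 2), 2 * sqrt(num / den), tolerance = 1e-12)
  expect_error(estimate_alpha(sys, 0), "positive")
})

test_that("steepest-descent step length: identity, homogeneity, dense check", {
  sysI <- as_ct_system(Matrix::Diagonal(16, 1), n = 4)
  expect_equal(step_size_beta(sysI, rnorm(16)), 1, tolerance = 1e-12)
  set.seed(14)
  A <- matrix(runif(8 * 16), 8, 16)
  r <- rnorm(16)
  for (c in c(1, 3)) {
    sys <- as_ct_system(c * A, n = 4)
    expect_equal(step_size_beta(sys, r),
                 sum(r^2) / sum((c * A %*% r)^2), tolerance = 1e-12)
  }
  expect_error(step_size_beta(sysI, numeric(16)), "nonzero")
})

test_that("the interior radius schedule has its anchor values", {
  expect_identical(interior_radius(20000, 20000, 3.5), 3.5)
  expect_equal(interior_radius(2^(-20) * 20000, 20000, 1), 0.7, tolerance = 1e-14)
  expect_equal(interior_radius(1, 20000, 1), 0.76567, tolerance = 1e-4)
  ks <- seq_len(100) * 200
  expect_true(all(diff(interior_radius(ks, 20000, 2)) > 0))
})

test_that("ISTA step: Landweber at w = 0 and the scalar recurrence converges to 2", {
  sys <- fixture_system(16L, 8L)
  ph <- shepp_logan(16)
  g <- forward_project(sys, ph)
  f <- matrix(rnorm(256), 16, 16)
  expect_equal(ista_step(f, sys, g, w = 0),
               f + back_project(sys, as.numeric(g) - as.numeric(forward_project(sys, f))),
               tolerance = 1e-12)
  # 1-pixel, 1-measurement system with a = 0.5, g = 1: f_k = 2 (1 - 0.75^k)
  sys1 <- as_ct_system(matrix(0.5, 1, 1), n = 1)
  f <- matrix(0, 1, 1)
  for (k in 1:60) {
    f <- ista_step(f, sys1, 1, w = 0)
    expect_equal(f[1, 1], 2 * (1 - 0.75^k), tolerance = 1e-12)
  }
  expect_equal(f[1, 1], 2, tolerance = 1e-6)
})

test_that("relative reconstruction error behaves as a scaled l2 distance", {
  ph <- shepp_logan(16)
  expect_identical(rre(ph, ph), 0)
  expect_identical(rre(matrix(0, 16, 16), ph), 100)
  expect_equal(rre(1.01 * as.matrix(ph), ph), 1, tolerance = 1e-10)
  expect_error(rre(ph, matrix(0, 16, 16)), "nonzero")
})

test_that("starting at the truth with consistent data stops immediately", {
  sys <- fixture_system(16L, 8L)
  ph <- shepp_logan(16)
  g <- forward_project(sys, ph)
  rec <- reconstruct(sys, g, "B", f_true = ph, max_iter = 50, f_init = ph)
  expect_equal(rec$iterations, 1L)
  expect_equal(rec$final_rre, 0, tolerance = 1e-8)
  expect_equal(rec$status, "converged")
})

test_that("the compiled scheme loop reproduces R-composed iterations exactly", {
  sys <- fixture_system(16L, 12L)
  ph <- shepp_logan(16)
  g <- forward_project(sys, ph)

  # classical SART path vs an sart_step() loop
  recS <- reconstruct(sys, g, "SART", f_true = ph, max_iter = 10,
                      rre_stop = 0, lambda = 0.9)
  f <- matrix(0, 16, 16)
  for (k in 1:10) f <- sart_step(f, sys, g, lambda = 0.9)
  expect_equal(as.matrix(recS$image), f, tolerance = 1e-12)

  # Scheme A vs explicit residual / beta / projection composition
  alpha <- estimate_alpha(sys, 2)
  R_star <- lp_radius(haar2(ph), 1)
  recA <- reconstruct(sys, g, "A", f_true = ph, max_iter = 5, rre_stop = 0)
  f <- matrix(0, 16, 16)
  for (k in 1:5) {
    rt <- sart_residual(sys, g, f)
    beta <- step_size_beta(sys, rt)
    pr <- project_lp_ball(haar2(f + alpha * beta * rt), R_star, p = 1)
    f <- as.matrix(ihaar2(pr$coeffs))
    expect_equal(recA$log$beta[k], beta, tolerance = 1e-10)
    expect_equal(recA$log$mu[k], pr$mu, tolerance = 1e-10)
  }
  expect_equal(as.matrix(recA$image), f, tolerance = 1e-10)

  # direct variant uses the unweighted residual and alpha = 1
  recAD <- reconstruct(sys, g, "AD", f_true = ph, max_iter = 3, rre_stop = 0)
  f <- matrix(0, 16, 16)
  for (k in 1:3) {
    rt <- sart_residual(sys, g, f, weighted = FALSE)
    beta <- step_size_beta(sys, rt)
    pr <- project_lp_ball(haar2(f + beta * rt), R_star, p = 1)
    f <- as.matrix(ihaar2(pr$coeffs))
  }
  expect_equal(as.matrix(recAD$image), f, tolerance = 1e-10)
})

test_that("projected schemes respect their radius budgets", {
  sys <- fixture_system(16L, 10L)
  ph <- shepp_logan(16)
  g <- forward_project(sys, ph)
  R_star <- lp_radius(haar2(ph), 1)
  recA <- reconstruct(sys, g, "A", f_true = ph, max_iter = 40, rre_stop = 0)
  expect_lte(lp_radius(haar2(recA$image), 1), R_star + 1e-6 * R_star)
  recC <- reconstruct(sys, g, "C", f_true = ph, max_iter = 40, rre_stop = 0)
  expect_lte(lp_radius(haar2(recC$image), 1),
             interior_radius(recC$iterations, 40, R_star) + 1e-6 * R_star)
  expect_equal(recC$R_star, R_star)
})

test_that("divergent configurations abort with actionable advice", {
  sys <- fixture_system(16L, 10L)
  ph <- shepp_logan(16)
  g <- forward_project(sys, ph)
  expect_error(
    reconstruct(sys, g, "B", f_true = ph, max_iter = 200, alpha0 = 400),
    "alpha0")
})

test_that("convergence logs are tidy and summaries truthful", {
  sys <- fixture_system(16L, 10L)
  ph <- shepp_logan(16)
  g <- forward_project(sys, ph)
  rec <- reconstruct(sys, g, "A", f_true = ph, max_iter = 25, rre_stop = 0)
  log <- tidy(rec)
  expect_s3_class(log, "tbl_df")
  expect_named(log, c("iteration", "rre", "beta", "mu", "discrepancy"))
  expect_identical(log$iteration, 1:25)
  expect_true(all(log$rre >= 0))
  expect_true(all(diff(log$iteration) == 1))
  gl <- glance(rec)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$iterations, 25L)
  expect_equal(gl$final_rre, log$rre[25])
  expect_s3_class(autoplot(rec), "ggplot")
})

test_that("RRE is eventually monotone on a mildly underdetermined problem", {
  sys <- fixture_system(32L, 20L, n_det = 32L)
  ph <- shepp_logan(32)
  g <- forward_project(sys, ph)
  rec <- reconstruct(sys, g, "A", f_true = ph, max_iter = 600, rre_stop = 0)
  e <- rec$log$rre
  # compare consecutive 100-iteration windows after a burn-in
  win <- sapply(seq(200, 600, by = 100), function(k) max(e[(k - 99):k]))
  expect_true(all(diff(win) < 0))
})
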