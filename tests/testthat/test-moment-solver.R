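test_that("Legendre basis (n = 3) has the stated spectral structure", {
  b <- gegenbauer_basis(3, 10)
  expect_equal(b$eigvals[1:4], c(0, -2, -6, -12))
  expect_true(all(b$eigvals[-1] < 0))
  expect_equal(b$norms, 2 / (2 * (0:10) + 1))
  expect_equal(b$sdiag[1], 1 / sqrt(3))
  expect_equal(b$sdiag[2], 2 / sqrt(15))
  # coupling: symmetric tridiagonal, zero diagonal, entries approaching the
  # constant 1/2 (from above, monotonically, for the Legendre case)
  expect_equal(b$coupling, t(b$coupling))
  expect_true(all(diag(b$coupling) == 0))
  expect_true(all(diff(b$sdiag) < 0))
  expect_true(all(b$sdiag > 0.5))
  expect_lt(tail(b$sdiag, 1), 0.51)
  # its eigenvalues act like s-multiplication: all inside (-1, 1)
  expect_true(all(abs(b$lamS) < 1))
  expect_error(gegenbauer_basis(5, 10), "2 or 3")
})

test_that("basis polynomials are eigenfunctions of the angular operator", {
  for (n in c(3, 2)) {
    b <- gegenbauer_basis(n, 6)
    s <- seq(-0.999, 0.999, length.out = 4001)
    P <- basis_polynomials(b, s)
    expect_equal(P[, 1], rep(1, length(s)))
    expect_equal(P[, 2], s)
    h <- s[2] - s[1]
    for (k in c(1, 2, 4)) {
      y <- P[, k + 1]
      d1 <- (y[c(2:length(s), length(s))] - y[c(1, 1:(length(s) - 1))]) / (2 * h)
      d2 <- (y[c(2:length(s), length(s))] - 2 * y +
               y[c(1, 1:(length(s) - 1))]) / h^2
      lhs <- (1 - s^2) * d2 - (n - 1) * s * d1
      core <- 100:(length(s) - 100)
      expect_equal(lhs[core], b$eigvals[k + 1] * y[core], tolerance = 1e-4)
    }
  }
  # orthogonality under the sphere weight; for n = 2 substitute s = cos(theta)
  # so the endpoint-divergent Chebyshev weight integrates exactly
  trap_w <- function(x) {
    h <- x[2] - x[1]
    c(h / 2, rep(h, length(x) - 2), h / 2)
  }
  b3 <- gegenbauer_basis(3, 6)
  s3 <- seq(-1, 1, length.out = 8001)
  P3 <- basis_polynomials(b3, s3)
  gram3 <- t(P3) %*% (P3 * trap_w(s3))
  expect_lt(max(abs(gram3 - diag(diag(gram3)))) / min(diag(gram3)), 1e-4)
  expect_equal(unname(diag(gram3)), b3$norms, tolerance = 1e-3)
  b2 <- gegenbauer_basis(2, 6)
  th <- seq(0, pi, length.out = 8001)
  P2 <- basis_polynomials(b2, cos(th))
  gram2 <- t(P2) %*% (P2 * trap_w(th))
  expect_lt(max(abs(gram2 - diag(diag(gram2)))) / min(diag(gram2)), 1e-4)
  expect_equal(unname(diag(gram2)), b2$norms, tolerance = 1e-3)
})

test_that("Chebyshev limit (n = 2) uses the correct coupling", {
  b <- gegenbauer_basis(2, 5)
  expect_equal(b$eigvals, -(0:5)^2)
  expect_equal(b$sdiag, c(1 / sqrt(2), rep(0.5, 4)))
})

test_that("moment system conserves mass and sources anisotropy correctly", {
  basis <- gegenbauer_basis(3, 6)
  fg <- seq(0, 3, length.out = 400)
  df <- fg[2] - fg[1]
  m <- matrix(0, 400, 7)
  m[, 1] <- stats::dnorm(fg, p_mid$f0, 0.1)
  rhs <- moment_rhs(m, basis, p_mid, fg)
  # zero-flux conservative scheme: total mass derivative is zero
  expect_lt(abs(sum(rhs[, 1]) * df), 1e-14)
  # the gradient term sources the first moment antisymmetrically: positive
  # above f0 (uphill movers gain f), negative below
  i_up <- which.min(abs(fg - (p_mid$f0 + 0.15)))
  i_dn <- which.min(abs(fg - (p_mid$f0 - 0.15)))
  expect_gt(rhs[i_up, 2], 0)
  expect_lt(rhs[i_dn, 2], 0)
  # no gradient, isotropic state: higher moments stay unsourced (the upwind
  # dissipation matrix is then diagonal, so only round-off leaks across modes)
  rhs0 <- moment_rhs(m, basis, dimensionless_params(Inf, 1), fg)
  expect_lt(max(abs(rhs0[, 2:7])), 1e-11)
  expect_error(moment_rhs(m * NA, basis, p_mid, fg), "finite")
})

test_that("steady-state solve is normalized, positive, and self-consistent", {
  sol <- solve_steady(p_mid, basis_K = 8, grid_points = 1500, tau_end = 8)
  expect_equal(sol$mass, 1, tolerance = 1e-4)
  expect_gt(sol$min_p0, -1e-9)
  # |p1| <= n p0 (the |s| <= 1 constraint), up to a small tolerance
  expect_true(all(abs(sol$p1) <= 3 * pmax(sol$p0, 0) + 1e-6))
  vd <- drift_from_moments(sol)
  expect_lt(attr(vd, "rel_gap"), 0.01)
  expect_equal(as.numeric(vd), 0.0988, tolerance = 5e-3)
  # strong positive feedback: mean far above f0 with the density peaking
  # near the upper support bound (the ratchet signature)
  solf <- solve_steady(p_fast, basis_K = 8, grid_points = 2500, tau_end = 8)
  pdf <- moment_pdf(solf)
  expect_gt(pdf_mean(pdf), p_fast$f0 + 3)
  eb <- exact_bounds(p_fast)
  mode_f <- pdf$f_grid[which.max(pdf$density)]
  expect_gt(mode_f, p_fast$f0 + 0.5 * (eb[["f_u"]] - p_fast$f0))
})

test_that("no gradient collapses the solution onto the adapted state", {
  # the collapse onto f0 narrows by roughly one grid cell per unit tau once
  # it reaches the grid scale, so full shape convergence needs a long horizon
  sol <- solve_steady(dimensionless_params(Inf, 1), basis_K = 4,
                      grid_points = 800, tau_end = 30, margin = 0.4)
  expect_lt(abs(as.numeric(drift_from_moments(sol))), 1e-8)
  i0 <- which.min(abs(sol$f_grid - log(4)))
  expect_gt(sum(sol$p0[abs(sol$f_grid - log(4)) < 0.1]) /
              sum(sol$p0), 0.99)
})

test_that("solver agrees with the closed form where the closure is valid", {
  # tau_D0 << 1 is the closure's derivation regime: distribution-level match
  p <- dimensionless_params(3, 0.1)
  sol <- solve_steady(p, basis_K = 10, grid_points = 1500, tau_end = 8)
  ana <- steady_state_pdf(p)
  expect_lt(ks_distance(ana, moment_pdf(sol)), 0.01)
  expect_lt(abs(drift_from_pdf(ana) /
                  as.numeric(drift_from_moments(sol)) - 1), 0.05)
})

test_that("drift is robust to the truncation order", {
  v10 <- as.numeric(drift_from_moments(solve_steady(p_mid, 10, 2000, 8)))
  v14 <- as.numeric(drift_from_moments(solve_steady(p_mid, 14, 2000, 8)))
  expect_lt(abs(v14 - v10) / v10, 0.01)
})

test_that("drift decreases with tau_E (positive feedback accelerates)", {
  vds <- sapply(c(0.3, 1, 3), function(te) {
    as.numeric(drift_from_moments(solve_steady(
      dimensionless_params(te, 1), basis_K = 8, grid_points = 2000,
      tau_end = 8)))
  })
  expect_true(all(diff(vds) < 0))
  expect_true(all(vds > 0))
})
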