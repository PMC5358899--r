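test_that("runs are reproducible from the seed and guard the step size", {
  e1 <- langevin_fs(p_mid, n_walkers = 50, dt = 1e-3, tau_end = 2, seed = 4)
  e2 <- langevin_fs(p_mid, n_walkers = 50, dt = 1e-3, tau_end = 2, seed = 4)
  expect_identical(e1$x, e2$x)
  expect_identical(e1$f, e2$f)
  e3 <- langevin_fs(p_mid, n_walkers = 50, dt = 1e-3, tau_end = 2, seed = 5)
  expect_false(identical(e3$x, e1$x))
  expect_error(langevin_fs(p_fast, dt = 5e-3), "too large")
  expect_error(langevin_rv(dimensionless_params(1, 0.05), dt = 1e-3),
               "too large")
})

test_that("gradient off: unbiased walk with the internal state pinned", {
  p <- dimensionless_params(Inf, 1)
  ens <- langevin_fs(p, n_walkers = 800, dt = 1e-3, tau_end = 15, seed = 51,
                     save_dt = 0.05)
  xf <- ens$x[nrow(ens$x), ]
  expect_lt(abs(mean(xf)), 2 * stats::sd(xf) / sqrt(length(xf)))
  expect_lt(max(abs(ens$f[nrow(ens$f), ] - p$f0)), 1e-6)
  # orientation autocorrelation decays at 1/tau_D0
  S <- ens$s[ens$times > 3, ]
  lags <- 1:40
  ac <- sapply(lags, function(L) {
    a <- S[1:(nrow(S) - L), ]; b <- S[(1 + L):nrow(S), ]
    mean(a * b) / mean(S^2)
  })
  rate <- -unname(stats::coef(stats::lm(log(ac) ~ I(lags * 0.05) + 0)))
  expect_lt(abs(rate - 1 / p$tau_d0), 0.1)
  # |s| never leaves [-1, 1]
  expect_true(all(abs(ens$s) <= 1))
})

test_that("stationary f statistics match the closed forms", {
  # near-Gaussian regime: sample variance within 15% of sigma2
  pg <- dimensionless_params(3, 0.1)
  ens <- langevin_fs(pg, n_walkers = 2000, dt = 1e-3, tau_end = 20,
                     seed = 52, save_dt = 0.01, save = "f")
  h <- internal_state_histogram(ens, window = c(10, 20))
  expect_lt(abs(stats::var(h$samples) / gaussian_limit(pg)$sigma2 - 1), 0.15)
  expect_equal(runtumble:::trapz_q(h$f_grid, h$density), 1, tolerance = 1e-6)
  # all samples inside the exact bounds (up to a single-step increment)
  eb <- exact_bounds(pg)
  slack <- 5e-3
  expect_true(all(h$samples > eb[["f_l"]] - slack &
                    h$samples < eb[["f_u"]] + slack))
  # strong positive feedback: mass piles above f0
  ensf <- langevin_fs(p_fast, n_walkers = 600, dt = 1e-3, tau_end = 20,
                      seed = 53, save_dt = 0.05, save = "f")
  hf <- internal_state_histogram(ensf, window = c(10, 20))
  expect_gt(mean(hf$samples > p_fast$f0), 0.5)
  ebf <- exact_bounds(p_fast)
  expect_true(all(hf$samples > ebf[["f_l"]] - slack &
                    hf$samples < ebf[["f_u"]] + slack))
  expect_error(internal_state_histogram(ensf, window = c(30, 40)), "window")
})

test_that("the two dimensionless engines agree in law", {
  e1 <- langevin_fs(p_mid, n_walkers = 1500, dt = 1e-3, tau_end = 25,
                    seed = 21, save = c("x", "f"))
  e2 <- langevin_rv(p_mid, n_walkers = 1500, dt = 1e-3, tau_end = 25,
                    seed = 22, save = c("x", "r"))
  d1 <- estimate_drift(e1); d2 <- estimate_drift(e2)
  se <- sqrt(d1$stderr^2 + d2$stderr^2)
  expect_lt(abs(d1$v_d - d2$v_d), 2.5 * se)
  f1 <- as.numeric(e1$f[e1$times > 10, ])
  r2 <- as.numeric(e2$r[e2$times > 10, ])
  expect_lt(ks_distance(run_probability(f1), r2), 0.05)
})

test_that("(r, v) engine: fixed point, noise cone, transient asymmetry", {
  # noise off, adapted start: the fixed point is stationary
  e0 <- langevin_rv(p_mid, n_walkers = 3, dt = 1e-3, tau_end = 3, seed = 1,
                    start = c(0.8, 0), noise = FALSE)
  expect_lt(max(abs(e0$r - 0.8)), 1e-9)
  expect_lt(max(abs(e0$v)), 1e-9)
  # |v| <= r is enforced throughout
  e1 <- langevin_rv(p_fast, n_walkers = 200, dt = 1e-3, tau_end = 5,
                    seed = 2, save_dt = 0.01)
  expect_true(all(abs(e1$v) <= e1$r + 1e-12))
  # ratchet regime: starting uphill reaches farther uphill speeds than the
  # mirrored downhill start reaches downhill, over a short window
  exc <- function(p, delta, seed) {
    up <- langevin_rv(p, n_walkers = 500, dt = 1e-3, tau_end = 2,
                      seed = seed, save_dt = 0.01, start = c(p$r0, delta),
                      save = "v")
    dn <- langevin_rv(p, n_walkers = 500, dt = 1e-3, tau_end = 2,
                      seed = seed + 1, save_dt = 0.01,
                      start = c(p$r0, -delta), save = "v")
    mean(apply(up$v, 2, max)) / mean(apply(-dn$v, 2, max))
  }
  expect_gt(exc(p_fast, 0.05, 41), 1.4)
  r3 <- exc(p_slow, 0.05, 43)
  expect_gt(r3, 0.8)
  expect_lt(r3, 1.25)
})

test_that("drift estimator recovers exact and null slopes", {
  times <- seq(0.5, 30, by = 0.5)
  x <- outer(times, rep(0.3, 40)) + 0.05  # exactly linear mean, offset
  ens <- structure(list(times = times, x = x,
                        meta = list(engine = "synthetic", n_walkers = 40,
                                    dt = NA, seed = 0)),
                   class = "rt_ensemble")
  d <- estimate_drift(ens, discard = 5)
  expect_equal(d$v_d, 0.3, tolerance = 1e-12)
  expect_error(estimate_drift(ens, discard = 28), "5 memory times")
  # zero-gradient ensemble is statistically null
  p <- dimensionless_params(Inf, 1)
  e0 <- langevin_fs(p, n_walkers = 600, dt = 1e-3, tau_end = 15, seed = 77,
                    save = "x")
  d0 <- estimate_drift(e0)
  expect_lt(abs(d0$v_d), 3 * d0$stderr)
})

test_that("agent engine reproduces adapted run-and-tumble statistics", {
  mp <- model_params(t_m = 10, N = 5, H = 10, v0 = 20, d_r = 0.0625,
                     d_t = 2.3125, t_s = 0.02)
  g0 <- gradient_profile("exponential", C0 = 1, L0 = 1e12,
                         saturating = FALSE, geometry = "planar")
  ens <- agent_simulate(mp, g0, n_walkers = 300, dt = 0.002, t_end = 150,
                        seed = 53, save_dt = 0.002)
  # run/tumble durations: exponential with means t_S/(1-r0) and t_S/r0
  durs <- function(mat, val) {
    out <- c()
    for (w in seq_len(ncol(mat))) {
      r <- rle(mat[, w]); k <- which(r$values == val)
      k <- k[k > 1 & k < length(r$lengths)]   # drop censored end segments
      out <- c(out, r$lengths[k])
    }
    out * 0.002
  }
  d_run <- durs(ens$state, 1L); d_tum <- durs(ens$state, 0L)
  expect_lt(abs(mean(d_run) / (0.02 / 0.2) - 1), 0.1)
  expect_lt(abs(mean(d_tum) / (0.02 / 0.8) - 1), 0.1)
  # geometric distribution check: sd ~ mean for an exponential
  expect_lt(abs(stats::sd(d_run) / mean(d_run) - 1), 0.15)
  # direction decorrelation at the fast-switching composite rate
  S <- ens$s[ens$times > 0.05, ]
  thin <- S[seq(1, nrow(S), by = 25), ]      # every 0.05 s
  lags <- 1:40
  ac <- sapply(lags, function(L) {
    a <- thin[1:(nrow(thin) - L), ]; b <- thin[(1 + L):nrow(thin), ]
    mean(a * b) / mean(thin^2)
  })
  rate <- -unname(stats::coef(stats::lm(log(pmax(ac, 1e-8)) ~
                                          I(lags * 0.05) + 0)))
  expect_lt(abs(rate / (2 * (0.8 * 0.0625 + 0.2 * 2.3125)) - 1), 0.1)
  # no gradient: no drift
  d0 <- estimate_drift(ens, discard = 5)
  expect_lt(abs(d0$v_d), 3 * d0$stderr)
  # tumbles do not translate the walker
  expect_error(agent_simulate(mp, g0, dt = 0.05), "t_s")
})

test_that("agent engine matches the dimensionless engine in a ramp", {
  ens_a <- agent_simulate(mp_unit, g_ramp, n_walkers = 1000, dt = 1e-3,
                          t_end = 20, seed = 9, R_start = 0)
  p <- dimensionless_from_physical(mp_unit, 1)
  ens_f <- langevin_fs(p, n_walkers = 1000, dt = 1e-3, tau_end = 20,
                       seed = 7, save = c("x", "f"))
  da <- estimate_drift(ens_a); df_ <- estimate_drift(ens_f)
  expect_lt(abs(da$v_d - df_$v_d),
            2.5 * sqrt(da$stderr^2 + df_$stderr^2))
  ha <- internal_state_histogram(ens_a, c(10, 20))
  hf <- internal_state_histogram(ens_f, c(10, 20))
  expect_lt(ks_distance(ha$samples, hf$samples), 0.05)
})

test_that("internal-state noise widens the stationary distribution", {
  p <- dimensionless_params(3, 1)
  e0 <- langevin_fs(p, n_walkers = 500, dt = 1e-3, tau_end = 15, seed = 61,
                    save = "f")
  e1 <- langevin_fs(p, n_walkers = 500, dt = 1e-3, tau_end = 15, seed = 61,
                    sigma_f = 0.3, save = "f")
  v0 <- stats::var(as.numeric(e0$f[e0$times > 8, ]))
  v1 <- stats::var(as.numeric(e1$f[e1$times > 8, ]))
  # additive white noise of amplitude sigma_f adds ~ sigma_f^2/2 variance
  expect_gt(v1, v0 + 0.3^2 / 4)
})
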