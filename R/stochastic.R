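# Monte-Carlo engines: dimensionless Langevin systems in (f, s) and (r, v)
# coordinates and the event-level agent simulator in physical units, plus the
# ensemble estimators (drift fit, stationary histogram).

new_ensemble <- function(times, x, f = NULL, s = NULL, r = NULL, v = NULL,
                         state = NULL, meta) {
  structure(list(times = times, x = x, f = f, s = s, r = r, v = v,
                 state = state, meta = meta),
            class = "rt_ensemble")
}

#' @export
print.rt_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble trajectory (%s engine): %d walkers, tau in [%g, %g]\n",
              x$meta$engine, x$meta$n_walkers, min(x$times), max(x$times)))
  cat(sprintf("  dt = %g, seed = %d, saved every %g time units\n",
              x$meta$dt, x$meta$seed, x$times[2] - x$times[1]))
  invisible(x)
}

check_dt <- function(dt, p) {
  lim <- 0.01 * min(1, p$tau_d0, if (is.finite(p$tau_e)) p$tau_e else 1)
  if (dt > lim * (1 + 1e-9)) {
    stop(sprintf("dt = %g too large: must be <= 0.01 * min(1, tau_D0, tau_E) = %g",
                 dt, lim))
  }
}

#' Langevin simulation in internal-state/orientation coordinates
#'
#' Euler-Maruyama integration of the dimensionless system
#' \deqn{df = [-(f - f_0) + r(f) s / \tau_E] d\tau, \quad
#'       ds = -\frac{s}{\tau_D(f)} d\tau +
#'            \sqrt{\frac{2 (1 - s^2)}{(n-1) \tau_D(f)}} dW, \quad
#'       dx = r(f) s \, d\tau,}
#' with `s` reflected into `[-1, 1]` after each step. Walkers start adapted
#' (`f = f0`, `x = 0`) with isotropic orientations.
#'
#' @param p An [dimensionless_params()] object (`tau_e = Inf` switches the
#'   gradient off).
#' @param n_walkers Ensemble size.
#' @param dt Time step (units `t_M`); must satisfy
#'   `dt <= 0.01 * min(1, tau_D0, tau_E)`.
#' @param tau_end Horizon (units `t_M`).
#' @param seed Integer seed; fully determines the run.
#' @param save_dt Interval at which states are recorded. Default 0.1.
#' @param sigma_f Additive white-noise amplitude on `f` (signaling-noise
#'   analogue). Default 0.
#' @param save Character subset of `c("x", "f", "s")` to record. Default all.
#' @return An `rt_ensemble` with matrices `[time, walker]`.
#' @export
langevin_fs <- function(p, n_walkers = 2000, dt = 1e-3, tau_end = 20,
                        seed = 1, save_dt = 0.1, sigma_f = 0,
                        save = c("x", "f", "s")) {
  stopifnot(inherits(p, "rt_params"))
  check_dt(dt, p)
  save_every <- max(1L, round(save_dt / dt))
  n_steps <- round(tau_end / dt)
  set.seed(seed)
  out <- langevin_fs_cpp(n_walkers, dt, n_steps, save_every,
                         if (is.finite(p$tau_e)) 1 / p$tau_e else 0,
                         p$tau_d0, p$r0, p$f0, p$n, p$dtr, sigma_f,
                         "x" %in% save, "f" %in% save, "s" %in% save)
  new_ensemble(out$times,
               if ("x" %in% save) out$x,
               if ("f" %in% save) out$f,
               if ("s" %in% save) out$s,
               meta = list(engine = "fs", n_walkers = n_walkers, dt = dt,
                           seed = seed, sigma_f = sigma_f, params = p))
}

#' Langevin simulation in run-probability/projected-speed coordinates
#'
#' The same stochastic process as [langevin_fs()] after the change of
#' variables `r(f)` and `v = r s` (the normalized expected speed along the
#' gradient):
#' \deqn{dr = r(1-r)\left[-(f(r) - f_0) + v/\tau_E\right] d\tau, \quad
#'       dv = v(1-r)\left[-(f(r) - f_0) + v/\tau_E\right] d\tau
#'            - \frac{v}{\tau_D(r)} d\tau +
#'            \sqrt{\frac{2(r^2 - v^2)}{(n-1)\tau_D(r)}} dW.}
#' The noise vanishes on `|v| = r`; `r` is clipped to
#' `[1e-6, 1 - 1e-6]` and `|v| <= r` enforced by projection. For `n = 3` the
#' noise amplitude reduces to `sqrt((r^2 - v^2)/tau_D(r))`.
#'
#' @inheritParams langevin_fs
#' @param start Either `"adapted"` (walkers start at the adapted `r0` with isotropic
#'   `v = r0 s`) or a numeric `c(r, v)` deterministic start for all walkers.
#' @param noise Logical; `FALSE` integrates the deterministic skeleton
#'   (used for phase-space excursion analysis).
#' @param save Character subset of `c("x", "r", "v")`.
#' @return An `rt_ensemble` with matrices `r`, `v` (and `x`).
#' @export
langevin_rv <- function(p, n_walkers = 2000, dt = 1e-3, tau_end = 20,
                        seed = 1, save_dt = 0.1, start = "adapted",
                        noise = TRUE, save = c("x", "r", "v")) {
  stopifnot(inherits(p, "rt_params"))
  check_dt(dt, p)
  save_every <- max(1L, round(save_dt / dt))
  n_steps <- round(tau_end / dt)
  random_init <- identical(start, "adapted")
  if (!random_init &&
      (!is.numeric(start) || length(start) != 2 ||
       start[1] <= 0 || start[1] >= 1 || abs(start[2]) > start[1])) {
    stop("'start' must be \"adapted\" or c(r, v) with 0 < r < 1, |v| <= r")
  }
  set.seed(seed)
  out <- langevin_rv_cpp(n_walkers, dt, n_steps, save_every,
                         if (is.finite(p$tau_e)) 1 / p$tau_e else 0,
                         p$tau_d0, p$r0, p$f0, p$n, p$dtr,
                         if (random_init) 0 else start[1],
                         if (random_init) 0 else start[2],
                         random_init, if (noise) 1 else 0,
                         "x" %in% save, "r" %in% save, "v" %in% save)
  new_ensemble(out$times,
               if ("x" %in% save) out$x,
               r = if ("r" %in% save) out$r,
               v = if ("v" %in% save) out$v,
               meta = list(engine = "rv", n_walkers = n_walkers, dt = dt,
                           seed = seed, noise = noise, params = p))
}

#' Event-level agent simulation in physical units
#'
#' Simulates run-and-tumble walkers in `n` dimensions: Poisson switching
#' between runs and tumbles with rates `lambda_R = (1 - r(f))/t_S`,
#' `lambda_T = r(f)/t_S`; straight swimming at `v0` during runs with
#' rotational diffusion `D_R`; zero speed and rotational diffusion `D_T`
#' during tumbles; internal state driven by the perceived-signal change along
#' the path, `dF = -(F - F0)/t_M dt + N dphi`. Directions decorrelate at rate
#' `(n-1)(r D_R + (1-r) D_T)`.
#'
#' Profiles with radial geometry place the source at the origin and walkers
#' at distance `R_start`; for planar geometry the gradient runs along one
#' axis. A walker that leaves the perceived gradient (zero concentration,
#' inside a source ball) simply performs adapted run-and-tumble there.
#'
#' @param mp An [model_params()] object.
#' @param g An [gradient_profile()] object.
#' @param n_walkers Ensemble size.
#' @param dt Time step, s; must be well below `mp$t_s`.
#' @param t_end Horizon, s.
#' @param seed Integer seed.
#' @param R_start Initial distance from the source, um.
#' @param save_dt Recording interval, s. Default `mp$t_m / 10`.
#' @return An `rt_ensemble`: `times` (converted to units of `t_M`), `x`
#'   (uphill displacement in units `v0 t_M`), `R` (raw distance, um), `f`
#'   (scaled internal state), `s` (uphill orientation cosine), `state`
#'   (1 = run), and metadata.
#' @export
agent_simulate <- function(mp, g, n_walkers = 2000, dt = 0.01 * mp$t_m / 10,
                           t_end = 20 * mp$t_m, seed = 1, R_start = 0,
                           save_dt = mp$t_m / 10) {
  stopifnot(inherits(mp, "rt_model_params"), inherits(g, "rt_gradient"))
  if (dt >= mp$t_s) stop("dt must be smaller than the switching timescale t_s")
  if (g$geometry == "planar" && !(g$kind %in% c("exponential", "linear"))) {
    stop("planar geometry is supported for exponential and linear profiles")
  }
  kind_code <- match(g$kind, c("exponential", "linear", "localized_source",
                               "custom")) - 1L
  R_tab <- numeric(0); phi_tab <- numeric(0)
  p1 <- p2 <- 0
  if (g$kind == "exponential") { p1 <- g$C0; p2 <- g$L0 }
  if (g$kind == "linear") { p1 <- g$C1; p2 <- g$a1 }
  if (g$kind == "localized_source") { p1 <- g$C2; p2 <- g$R0 }
  if (g$kind == "custom") {
    R_tab <- seq(min(g$R_tab), max(g$R_tab), length.out = 4096)
    phi_tab <- perceived_signal(g, concentration(g, R_tab))
  }
  save_every <- max(1L, round(save_dt / dt))
  n_steps <- round(t_end / dt)
  set.seed(seed)
  out <- agent_sim_cpp(n_walkers, dt, n_steps, save_every, mp$n, mp$v0,
                       mp$t_m, mp$N, mp$H, mp$f0 / mp$H, mp$d_r, mp$d_t,
                       mp$t_s, mp$sigma_f, kind_code, p1, p2, g$K_i, g$K_a,
                       g$saturating && g$kind != "custom",
                       g$geometry == "radial", R_start, R_tab, phi_tab)
  ens <- new_ensemble(out$times / mp$t_m,
                      (R_start - out$R) / (mp$v0 * mp$t_m),
                      f = out$f, s = out$s, state = out$state,
                      meta = list(engine = "agent", n_walkers = n_walkers,
                                  dt = dt, seed = seed, model = mp,
                                  gradient = g, R_start = R_start))
  ens$R <- out$R
  ens
}

#' Drift speed from an ensemble
#'
#' Ordinary least squares fit of the ensemble-mean position against time
#' after discarding the start-up transient; the standard error comes from a
#' bootstrap over walkers (the mean-trajectory slope is the mean of
#' per-walker slopes).
#'
#' @param ens An `rt_ensemble` with an `x` component.
#' @param discard Initial time span to drop (same units as `ens$times`).
#'   Default 5.
#' @param n_boot Bootstrap resamples. Default 200.
#' @return A list of class `rt_drift`: `v_d`, `stderr`, `window`.
#' @export
estimate_drift <- function(ens, discard = 5, n_boot = 200) {
  stopifnot(inherits(ens, "rt_ensemble"))
  if (is.null(ens$x)) stop("ensemble was saved without 'x'")
  keep <- ens$times > discard
  if (sum(keep) < 3 || (max(ens$times) - discard) < 5) {
    stop("window after discarding the transient must span at least 5 memory times")
  }
  tt <- ens$times[keep]
  X <- ens$x[keep, , drop = FALSE]
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  # per-walker OLS slopes (sum(tc) = 0, so centering x is unnecessary);
  # the fit of the mean trajectory is their average
  slopes <- as.numeric(crossprod(tc, X)) / denom
  v_d <- mean(slopes)
  nb <- vapply(seq_len(n_boot), function(i) {
    mean(slopes[sample.int(length(slopes), replace = TRUE)])
  }, numeric(1))
  structure(list(v_d = v_d, stderr = stats::sd(nb),
                 window = c(min(tt), max(tt)), n_walkers = ncol(X)),
            class = "rt_drift")
}

#' @export
print.rt_drift <- function(x, ...) {
  cat(sprintf("Drift speed V_D = %.4f +/- %.4f (v0 units), window [%.1f, %.1f]\n",
              x$v_d, x$stderr, x$window[1], x$window[2]))
  invisible(x)
}

#' Stationary histogram of the internal state
#'
#' Pools `f` across walkers and recorded times inside a window (default the
#' protocol `tau` in `[10, 20]`) and bins it into a normalized empirical
#' density.
#'
#' @param ens An `rt_ensemble` with an `f` component.
#' @param window Time window `c(tau1, tau2)`. Default `c(10, 20)`.
#' @param breaks Bin edges, or a single bin count (default 100 bins spanning
#'   the exact support bounds extended to the data range).
#' @return An `rt_pdf` (kind "empirical") with the pooled samples attached as
#'   attribute `samples`.
#' @export
internal_state_histogram <- function(ens, window = c(10, 20), breaks = 100) {
  stopifnot(inherits(ens, "rt_ensemble"))
  if (is.null(ens$f)) stop("ensemble was saved without 'f'")
  keep <- ens$times >= window[1] & ens$times <= window[2]
  if (!any(keep)) stop("empty sampling window")
  samples <- as.numeric(ens$f[keep, , drop = FALSE])
  p <- ens$meta$params
  eb <- if (!is.null(p) && is.finite(p$tau_e)) exact_bounds(p) else
    range(samples)
  if (length(breaks) == 1) {
    lo <- min(eb[1], min(samples)); hi <- max(eb[2], max(samples))
    breaks <- seq(lo - 1e-9, hi + 1e-9, length.out = breaks + 1)
  }
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  structure(
    list(f_grid = h$mids, density = h$density,
         support_trunc = c(f_l_t = min(breaks), f_u_t = max(breaks)),
         support_exact = eb, edge_mass = c(lower = 0, upper = 0),
         params = p, kind = "empirical", samples = samples),
    class = "rt_pdf"
  )
}
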