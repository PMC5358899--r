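#' Logistic run probability
#'
#' Probability to be in the run state as a function of the scaled internal
#' state `f = H * F`, in the fast-switching limit of the run/tumble Poisson
#' process: `r(f) = 1 / (1 + exp(-f))`.
#'
#' @param f Numeric vector of scaled internal states. Must be finite.
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' run_probability(0)        # 0.5
#' run_probability(log(4))   # 0.8, the adapted value used throughout
#' @seealso [adapted_state()] for the inverse map.
#' @export
run_probability <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f))) {
    stop("'f' must be finite numeric")
  }
  stats::plogis(f)
}

#' Adapted internal state for a given run probability
#'
#' Inverse of [run_probability()]: the logit `f0 = log(r0 / (1 - r0))`.
#'
#' @param r0 Run probability, strictly inside (0, 1).
#' @return Scaled internal state `f0` with `run_probability(f0) == r0`.
#' @export
adapted_state <- function(r0) {
  if (!is.numeric(r0) || any(!is.finite(r0)) || any(r0 <= 0) || any(r0 >= 1)) {
    stop("'r0' must lie strictly inside (0, 1)")
  }
  stats::qlogis(r0)
}

#' Dimensionless model parameters
#'
#' The reduced parameter set in which the run-and-tumble dynamics are
#' analysed: time is measured in units of the memory time `t_M` and length in
#' units of `v0 * t_M`.
#'
#' @param tau_e Positive-feedback timescale ratio `t_E / t_M` with
#'   `t_E = L / (N * H * v0)`. `tau_e < 1` means the motion-sensation positive
#'   feedback dominates over adaptation. `Inf` is allowed (gradient switched
#'   off).
#' @param tau_d0 Direction-decorrelation time at the adapted state over the
#'   memory time, `t_D(f0) / t_M`.
#' @param r0 Adapted run probability, in (0, 1). Default 0.8.
#' @param n Spatial dimension, 2 or 3. Default 3.
#' @param dtr Ratio of tumble to run rotational diffusion, `D_T / D_R >= 1`.
#'   Default 37.
#' @return An object of class `rt_params` (a named list with fields `tau_e`,
#'   `tau_d0`, `r0`, `n`, `dtr` and the derived `f0 = adapted_state(r0)`).
#' @examples
#' p <- dimensionless_params(tau_e = 0.1, tau_d0 = 1)
#' p$f0   # log(4)
#' @export
dimensionless_params <- function(tau_e, tau_d0, r0 = 0.8, n = 3, dtr = 37) {
  if (!is.numeric(tau_e) || length(tau_e) != 1L || is.na(tau_e) || tau_e <= 0) {
    stop("'tau_e' must be a single positive number (Inf allowed)")
  }
  if (!is.numeric(tau_d0) || length(tau_d0) != 1L || !is.finite(tau_d0) ||
      tau_d0 <= 0) {
    stop("'tau_d0' must be a single positive finite number")
  }
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) ||
      r0 <= 0 || r0 >= 1) {
    stop("'r0' must lie strictly inside (0, 1)")
  }
  if (!(n %in% c(2, 3))) stop("'n' must be 2 or 3")
  if (!is.numeric(dtr) || length(dtr) != 1L || !is.finite(dtr) || dtr < 1) {
    stop("'dtr' (= D_T / D_R) must be >= 1")
  }
  structure(
    list(tau_e = tau_e, tau_d0 = tau_d0, r0 = r0, n = as.integer(n),
         dtr = dtr, f0 = adapted_state(r0)),
    class = "rt_params"
  )
}

#' @export
print.rt_params <- function(x, ...) {
  cat("Dimensionless run-and-tumble parameters\n")
  cat(sprintf("  tau_E  = %g   (positive feedback / memory)\n", x$tau_e))
  cat(sprintf("  tau_D0 = %g   (direction decorrelation / memory)\n", x$tau_d0))
  cat(sprintf("  r0     = %g   (adapted run probability, f0 = %.4f)\n",
              x$r0, x$f0))
  cat(sprintf("  n      = %d, D_T/D_R = %g\n", x$n, x$dtr))
  invisible(x)
}

#' Physical model parameters
#'
#' Parameter set of the minimal run-and-tumble model in physical units. The
#' internal state `F` relaxes to the adapted value `F0` over the memory time
#' `t_M` and is driven by changes of the perceived signal with receptor gain
#' `N`; the run probability is `r(F) = 1/(1 + exp(-H F))` with motor gain `H`.
#'
#' @param t_m Memory (adaptation) time, s.
#' @param N Receptor gain, dimensionless.
#' @param H Motor gain, dimensionless.
#' @param f0 Adapted scaled internal state `f0 = H * F0`; default
#'   `adapted_state(0.8)`.
#' @param v0 Run speed, um/s.
#' @param d_r Rotational diffusion coefficient during runs, rad^2/s.
#' @param d_t Rotational diffusion coefficient during tumbles, rad^2/s.
#'   Must satisfy `d_t >= d_r`.
#' @param n Spatial dimension, 2 or 3.
#' @param t_s Run-tumble switching timescale `1/(lambda_R + lambda_T)`, s.
#'   Defaults to `0.01 * t_m` so that the fast-switching limit underlying the
#'   coarse-grained theory holds; a value above `0.1 * t_m` triggers a
#'   warning (not an error).
#' @param sigma_f Optional white-noise amplitude on the scaled internal state
#'   (per sqrt of dimensionless time), the minimal-model analogue of signaling
#'   noise in the adaptation pathway. Default 0.
#' @return An object of class `rt_model_params`.
#' @examples
#' mp <- model_params(t_m = 10, N = 5, H = 10, v0 = 20,
#'                    d_r = 0.0625, d_t = 2.3125)
#' dimensionless_from_physical(mp, L = 1000)
#' @export
model_params <- function(t_m, N, H, f0 = adapted_state(0.8), v0,
                         d_r, d_t, n = 3, t_s = 0.01 * t_m, sigma_f = 0) {
  num1 <- function(x, nm, pos = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (pos && x <= 0)) {
      stop(sprintf("'%s' must be a single positive finite number", nm))
    }
    x
  }
  t_m <- num1(t_m, "t_m"); N <- num1(N, "N"); H <- num1(H, "H")
  v0 <- num1(v0, "v0"); d_r <- num1(d_r, "d_r"); d_t <- num1(d_t, "d_t")
  t_s <- num1(t_s, "t_s")
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0)) {
    stop("'f0' must be a single finite number")
  }
  if (!is.numeric(sigma_f) || length(sigma_f) != 1L || !is.finite(sigma_f) ||
      sigma_f < 0) {
    stop("'sigma_f' must be a single nonnegative number")
  }
  if (d_t < d_r) stop("'d_t' must be >= 'd_r'")
  if (!(n %in% c(2, 3))) stop("'n' must be 2 or 3")
  if (t_s >= 0.1 * t_m) {
    warning("t_s >= 0.1 * t_m: fast-switching limit is questionable")
  }
  structure(
    list(t_m = t_m, N = N, H = H, f0 = f0, v0 = v0, d_r = d_r, d_t = d_t,
         n = as.integer(n), t_s = t_s, sigma_f = sigma_f,
         r0 = run_probability(f0)),
    class = "rt_model_params"
  )
}

#' @export
print.rt_model_params <- function(x, ...) {
  cat("Physical run-and-tumble parameters\n")
  cat(sprintf("  t_M = %g s, N = %g, H = %g, f0 = %.4f (r0 = %.3f)\n",
              x$t_m, x$N, x$H, x$f0, x$r0))
  cat(sprintf("  v0 = %g um/s, D_R = %g, D_T = %g rad^2/s, n = %d\n",
              x$v0, x$d_r, x$d_t, x$n))
  cat(sprintf("  t_S = %g s, sigma_f = %g\n", x$t_s, x$sigma_f))
  invisible(x)
}

#' Direction-decorrelation time as a function of the internal state
#'
#' In units of the memory time,
#' `tau_D(f) = tau_D0 * (r0 * D_R + (1 - r0) * D_T) /
#'            (r(f) * D_R + (1 - r(f)) * D_T)`,
#' which depends on `D_T`, `D_R` only through the ratio `dtr = D_T / D_R`.
#' Running cells keep their heading longer than tumbling cells, so `tau_d`
#' increases with `f` whenever `dtr > 1` and is constant when `dtr = 1`.
#'
#' @param f Scaled internal state (vectorised).
#' @param p An [dimensionless_params()] object.
#' @return `tau_D(f)` in units of `t_M`; equals `p$tau_d0` at `f = p$f0`.
#' @export
tau_d <- function(f, p) {
  stopifnot(inherits(p, "rt_params"))
  r <- run_probability(f)
  p$tau_d0 * (p$r0 + (1 - p$r0) * p$dtr) / (r + (1 - r) * p$dtr)
}

#' Run/tumble switching rates
#'
#' The model fixes only the run probability `r(f)` and the total switching
#' timescale `t_S = 1/(lambda_R + lambda_T)`; the individual rates are taken
#' as `lambda_T = r(f)/t_S` (tumble-to-run) and `lambda_R = (1 - r(f))/t_S`
#' (run-to-tumble), the simplest split consistent with both definitions.
#'
#' @param f Scaled internal state (vectorised).
#' @param t_s Switching timescale, s (or any time unit); must be positive.
#' @return A list with components `lambda_r` and `lambda_t` (units 1/time).
#' @export
switching_rates <- function(f, t_s) {
  if (!is.numeric(t_s) || length(t_s) != 1L || !is.finite(t_s) || t_s <= 0) {
    stop("'t_s' must be a single positive number")
  }
  r <- run_probability(f)
  list(lambda_r = (1 - r) / t_s, lambda_t = r / t_s)
}

#' Reduce physical parameters to dimensionless ones
#'
#' Given a local gradient length scale `L`, computes
#' `tau_E = L / (t_M * N * H * v0)` and
#' `tau_D0 = 1 / (t_M * (n - 1) * (r0 * D_R + (1 - r0) * D_T))`.
#'
#' @param mp An [model_params()] object.
#' @param L Gradient length scale `1 / ||grad phi||`, um; must be positive
#'   (`Inf` allowed, meaning no gradient).
#' @return An [dimensionless_params()] object.
#' @export
dimensionless_from_physical <- function(mp, L) {
  stopifnot(inherits(mp, "rt_model_params"))
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L <= 0) {
    stop("'L' must be a single positive number (Inf allowed)")
  }
  tau_e <- L / (mp$t_m * mp$N * mp$H * mp$v0)
  tau_d0 <- 1 / (mp$t_m * (mp$n - 1) *
                   (mp$r0 * mp$d_r + (1 - mp$r0) * mp$d_t))
  dimensionless_params(tau_e = tau_e, tau_d0 = tau_d0, r0 = mp$r0,
                       n = mp$n, dtr = mp$d_t / mp$d_r)
}

#' Distance travelled at a given drift speed
#'
#' Convenience for sizing tracking experiments: a cell drifting at a fraction
#' `vd_frac` of its run speed `v0` for a time `T` covers
#' `Delta X = vd_frac * v0 * T`. At `vd_frac = 0.5`, `v0 = 20` um/s and
#' `T = 200` s this is 2000 um = 2 mm, the distance over which a
#' ratchet-like climber must be observed to be identified as such.
#'
#' @param vd_frac Drift speed as a fraction of the run speed.
#' @param v0 Run speed, um/s.
#' @param T Observation time, s.
#' @return Distance, um.
#' @export
travel_distance <- function(vd_frac, v0, T) {
  vd_frac * v0 * T
}

#' Methylation-noise amplitude equivalent to expression noise
#'
#' Maps relative fluctuations of the response regulator concentration
#' (`sigma_Y / Y`) onto the amplitude `sigma_m` of white noise on the receptor
#' methylation level, using the receptor linearisation
#' `dY/dm = Y (1 - a) eps1`: `sigma_m = (sigma_Y/Y) / ((1 - a) |eps1|)`.
#' With `sigma_Y/Y = 0.1`, activity `a = 0.5` and methylation free-energy
#' slope `eps1 = -1` this gives 0.2, the value used when comparing the
#' minimal model's additive internal-state noise `sigma_f` to pathway-level
#' signaling noise.
#'
#' @param sigma_y_rel Relative noise of the regulator concentration.
#' @param a Adapted receptor activity.
#' @param eps1 Free-energy change per methyl group (dimensionless).
#' @return The equivalent methylation noise amplitude `sigma_m`.
#' @export
sigma_m_from_expression_noise <- function(sigma_y_rel = 0.1, a = 0.5,
                                          eps1 = -1) {
  if (a >= 1) stop("'a' must be < 1")
  if (eps1 == 0) stop("'eps1' must be nonzero")
  sigma_y_rel / ((1 - a) * abs(eps1))
}
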