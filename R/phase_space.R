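# Deterministic skeleton of the (r, v) system: nullclines, noise field,
# streamlines, linearization at the fixed point, and the non-normality index
# quantifying how far the eigenvectors are from orthogonal.

rv_field <- function(r, v, p) {
  f <- stats::qlogis(r)
  inv_te <- if (is.finite(p$tau_e)) 1 / p$tau_e else 0
  drive <- -(f - p$f0) + v * inv_te
  td <- tau_d_r(r, p)
  list(dr = r * (1 - r) * drive, dv = v * (1 - r) * drive - v / td)
}

tau_d_r <- function(r, p) {
  p$tau_d0 * (p$r0 + (1 - p$r0) * p$dtr) / (r + (1 - r) * p$dtr)
}

#' Nullclines of the deterministic (r, v) system
#'
#' The `r`-nullcline is `v = tau_E (f(r) - f0)` with `f(r) = logit(r)`; the
#' `v`-nullclines are `v = 0` and
#' `v = tau_E [ (f(r) - f0) + 1/((1 - r) tau_D(r)) ]`. The `r`-nullcline and
#' `v = 0` intersect exactly at the fixed point `(r0, 0)`; the non-trivial
#' `v`-nullcline misses it by `tau_E / ((1 - r0) tau_D0)`.
#'
#' @param p An [dimensionless_params()] object (finite `tau_e`).
#' @param r_grid Run-probability grid in (0, 1). Default 400 points on
#'   (0.001, 0.999).
#' @return A list of data frames `r_nullcline`, `v_null_zero`,
#'   `v_null_balance`, each with columns `r`, `v`.
#' @export
nullclines <- function(p, r_grid = seq(0.001, 0.999, length.out = 400)) {
  stopifnot(inherits(p, "rt_params"), is.finite(p$tau_e))
  f <- stats::qlogis(r_grid)
  v_r <- p$tau_e * (f - p$f0)
  v_b <- p$tau_e * ((f - p$f0) + 1 / ((1 - r_grid) * tau_d_r(r_grid, p)))
  list(
    r_nullcline = data.frame(r = r_grid, v = v_r),
    v_null_zero = data.frame(r = r_grid, v = 0),
    v_null_balance = data.frame(r = r_grid, v = v_b)
  )
}

#' Noise magnitude of the projected-speed equation
#'
#' `sqrt(2 (r^2 - v^2) / ((n-1) tau_D(r)))`, the state-dependent amplitude of
#' the white noise driving `v` (for `n = 3` this is
#' `sqrt((r^2 - v^2)/tau_D(r))`). Maximal along `v = 0`, exactly zero on
#' `|v| = r`, and undefined (returned as `NA`) outside that cone. Low noise
#' near `(r, v) = (1, 1)` is what lets a cell persist in long fast runs up
#' the gradient; high noise near the fixed point makes it resample directions
#' quickly.
#'
#' @param p An [dimensionless_params()] object.
#' @param r,v Numeric vectors (recycled against each other like in `outer`).
#' @return Noise magnitudes, `NA` where `|v| > r`.
#' @export
noise_field <- function(p, r, v) {
  stopifnot(inherits(p, "rt_params"))
  amp2 <- 2 * (r^2 - v^2) / ((p$n - 1) * tau_d_r(r, p))
  out <- sqrt(pmax(amp2, 0))
  out[r^2 - v^2 < 0] <- NA_real_
  out
}

#' Linearization of the (r, v) system at the fixed point
#'
#' The relaxation matrix at `(r0, 0)` is upper triangular,
#' `[[-1, r0 (1 - r0)/tau_E], [0, -1/tau_D0]]`, with eigenvalues `-1` and
#' `-1/tau_D0` (both negative: the fixed point is always stable). For
#' `tau_D0 != 1` the eigenvectors are `(1, 0)` and
#' `(r0 (1 - r0) tau_D0 / (tau_E (tau_D0 - 1)), 1)`; for `tau_D0 = 1` with a
#' nonzero off-diagonal the matrix is defective (a Jordan block with the
#' single eigendirection `(1, 0)`).
#'
#' @param p An [dimensionless_params()] object.
#' @return A list: `matrix`, `eigvals`, `eigvecs` (columns, unit norm; `NULL`
#'   if defective), `defective`.
#' @export
jacobian_eigensystem <- function(p) {
  stopifnot(inherits(p, "rt_params"))
  off <- if (is.finite(p$tau_e)) p$r0 * (1 - p$r0) / p$tau_e else 0
  J <- matrix(c(-1, 0, off, -1 / p$tau_d0), 2, 2)
  eigvals <- c(-1, -1 / p$tau_d0)
  defective <- abs(p$tau_d0 - 1) < 1e-12 && off != 0
  eigvecs <- NULL
  if (off == 0) {
    eigvecs <- cbind(c(1, 0), c(0, 1))         # diagonal matrix
  } else if (!defective) {
    b <- off * p$tau_d0 / (p$tau_d0 - 1)
    eigvecs <- cbind(c(1, 0), c(b, 1) / sqrt(b^2 + 1))
  }
  list(matrix = J, eigvals = eigvals, eigvecs = eigvecs,
       defective = defective)
}

#' Non-normality index of the linearized dynamics
#'
#' Absolute cosine of the angle between the two eigendirections of the
#' relaxation matrix: 0 for orthogonal eigenvectors (normal dynamics, no
#' transient growth), approaching 1 as the positive feedback strengthens
#' (`tau_E -> 0`), and defined as 1 in the defective case `tau_D0 = 1`
#' (coinciding eigendirections). Non-orthogonal eigenvectors let linear
#' deviations grow transiently despite both eigenvalues being negative.
#'
#' @param p An [dimensionless_params()] object.
#' @return A number in `[0, 1]`.
#' @export
nonnormality_index <- function(p) {
  es <- jacobian_eigensystem(p)
  if (es$defective) return(1)
  abs(sum(es$eigvecs[, 1] * es$eigvecs[, 2]))
}

#' Deterministic streamlines of the (r, v) system
#'
#' Integrates the noise-free flow from given starting points with an
#' adaptive solver (tolerance 1e-9). On the sampled domain every path
#' converges to the fixed point `(r0, 0)`; paths that leave
#' `(0,1) x (-r, r)` are truncated and flagged.
#'
#' @param p An [dimensionless_params()] object.
#' @param starts A matrix or data frame with columns `r`, `v`, one row per
#'   starting point (must satisfy `0 < r < 1`, `|v| < r`).
#' @param tau_span Integration horizon. Default 50.
#' @param n_out Output points per path. Default 500.
#' @return A list of data frames (columns `tau`, `r`, `v`) with attribute
#'   `truncated` (logical per path).
#' @export
streamlines <- function(p, starts, tau_span = 50, n_out = 500) {
  stopifnot(inherits(p, "rt_params"))
  starts <- as.matrix(starts)
  if (ncol(starts) != 2) stop("'starts' needs columns r and v")
  if (any(starts[, 1] <= 0 | starts[, 1] >= 1 |
          abs(starts[, 2]) > starts[, 1])) {
    stop("starts must lie inside 0 < r < 1, |v| <= r")
  }
  deriv <- function(t, y, parms) {
    r <- min(max(y[1], 1e-9), 1 - 1e-9)
    fl <- rv_field(r, y[2], p)
    list(c(fl$dr, fl$dv))
  }
  times <- seq(0, tau_span, length.out = n_out)
  trunc <- logical(nrow(starts))
  paths <- lapply(seq_len(nrow(starts)), function(i) {
    sol <- deSolve::ode(y = c(r = starts[i, 1], v = starts[i, 2]),
                        times = times, func = deriv, parms = NULL,
                        rtol = 1e-9, atol = 1e-9, method = "lsoda")
    d <- as.data.frame(sol)
    names(d) <- c("tau", "r", "v")
    bad <- d$r <= 0 | d$r >= 1 | abs(d$v) > 1
    if (any(bad)) {
      trunc[i] <<- TRUE
      d <- d[seq_len(which(bad)[1] - 1), ]
    }
    d
  })
  attr(paths, "truncated") <- trunc
  paths
}

#' Maximal deterministic excursions from symmetric perturbations
#'
#' Integrates the noise-free (r, v) flow from `(r0, +delta)` and
#' `(r0, -delta)` and reports the maximal `|v|` reached on each path. Under
#' strong positive feedback the uphill perturbation is transiently amplified
#' toward `(1, 1)` while the downhill one decays, so the ratio of the two
#' maxima is large; under dominant adaptation both simply relax and the ratio
#' is near 1. This is the package's quantitative handle on the asymmetric
#' transient growth of the non-normal dynamics.
#'
#' @param p An [dimensionless_params()] object.
#' @param delta Perturbation size in `v`. Default 0.05.
#' @param tau_span Horizon. Default 50.
#' @return A list: `up` and `down` (maximal `|v|`), `ratio` (up/down), and
#'   the two paths.
#' @export
excursion_asymmetry <- function(p, delta = 0.05, tau_span = 50) {
  paths <- streamlines(p, rbind(c(p$r0, delta), c(p$r0, -delta)),
                       tau_span = tau_span, n_out = 2000)
  up <- max(abs(paths[[1]]$v))
  down <- max(abs(paths[[2]]$v))
  list(up = up, down = down, ratio = up / down,
       path_up = paths[[1]], path_down = paths[[2]])
}

#' Full phase portrait of the (r, v) system
#'
#' Convenience bundle: grids, the deterministic drift field, the noise
#' magnitude field, nullclines, the fixed point and its eigen-structure, and
#' the non-normality index.
#'
#' @param p An [dimensionless_params()] object.
#' @param r_grid,v_grid Grid vectors. Defaults: 80 points on (0.01, 0.99) and
#'   81 points on (-1, 1).
#' @return An object of class `rt_portrait`.
#' @export
phase_portrait <- function(p, r_grid = seq(0.01, 0.99, length.out = 80),
                           v_grid = seq(-1, 1, length.out = 81)) {
  stopifnot(inherits(p, "rt_params"))
  G <- expand.grid(r = r_grid, v = v_grid)
  fl <- rv_field(G$r, G$v, p)
  drift <- data.frame(G, dr = fl$dr, dv = fl$dv)
  noise <- matrix(noise_field(p, G$r, G$v), length(r_grid), length(v_grid))
  es <- jacobian_eigensystem(p)
  structure(
    list(r_grid = r_grid, v_grid = v_grid, drift_field = drift,
         noise_field = noise, nullclines = nullclines(p),
         fixed_point = c(r = p$r0, v = 0), eigvals = es$eigvals,
         eigvecs = es$eigvecs, defective = es$defective,
         nonnormality = nonnormality_index(p), params = p),
    class = "rt_portrait"
  )
}

#' @export
print.rt_portrait <- function(x, ...) {
  cat(sprintf("Phase portrait at tau_E = %g, tau_D0 = %g\n",
              x$params$tau_e, x$params$tau_d0))
  cat(sprintf("  fixed point (%.3f, 0), eigenvalues %.3f, %.3f%s\n",
              x$fixed_point[1], x$eigvals[1], x$eigvals[2],
              if (x$defective) " (defective)" else ""))
  cat(sprintf("  non-normality index %.4f\n", x$nonnormality))
  invisible(x)
}
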