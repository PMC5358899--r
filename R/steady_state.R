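# Closed-form steady state of the internal-state marginal, its support
# bounds, potential decomposition, Gaussian / mean-field limits, and the
# drift-speed identity V_D = tau_E * <f - f0>.

# Solve f = f0 +/- r(f)/(scale * tau_e) by damped fixed-point iteration with a
# monotone-bracket bisection fallback; polished by Newton steps.
solve_bound <- function(p, side = c("upper", "lower"), scale = 1,
                        tol = 1e-12, max_iter = 2000L) {
  side <- match.arg(side)
  sgn <- if (side == "upper") 1 else -1
  a <- scale * p$tau_e
  g <- function(f) p$f0 + sgn * run_probability(f) / a
  h <- function(f) f - g(f)
  # start beyond all fixed points so the damped iteration walks in monotonely
  f <- p$f0 + sgn * (1 / a + 1)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    fn <- f + 0.5 * (g(f) - f)
    if (abs(fn - f) < tol) { f <- fn; converged <- TRUE; break }
    f <- fn
  }
  if (!converged || abs(h(f)) > 1e-10) {
    lo <- min(p$f0, p$f0 + sgn * (1 / a + 1))
    hi <- max(p$f0, p$f0 + sgn * (1 / a + 1))
    f <- tryCatch(
      stats::uniroot(h, c(lo, hi), tol = .Machine$double.eps^0.75)$root,
      error = function(e) {
        stop(sprintf(
          "support bound solve failed (%s, scale %g): residual %.3e after %d iterations",
          side, scale, abs(h(f)), max_iter))
      })
  }
  # Newton polish: h'(f) = 1 - sgn * r(1-r)/a
  for (i in 1:4) {
    r <- run_probability(f)
    f <- f - h(f) / (1 - sgn * r * (1 - r) / a)
  }
  if (abs(h(f)) > 1e-10) {
    stop(sprintf("support bound residual %.3e exceeds 1e-10 (%s)",
                 abs(h(f)), side))
  }
  f
}

#' Exact support bounds of the internal-state distribution
#'
#' With the orientation cosine bounded by `|s| <= 1`, the flux in `f` is
#' strictly restoring outside `f0 - r(f)/tau_E < f < f0 + r(f)/tau_E`, so the
#' stationary distribution is confined to the fixed points
#' `f_L = f0 - r(f_L)/tau_E` and `f_U = f0 + r(f_U)/tau_E`.
#' For small `tau_E`, `f_U -> 1/tau_E` and `f_L -> ln(tau_E)`.
#'
#' @param p An [dimensionless_params()] object.
#' @return Named numeric vector `c(f_l, f_u)` with `f_l < f0 < f_u`; residuals
#'   of the fixed-point equations are below 1e-10.
#' @export
exact_bounds <- function(p) {
  stopifnot(inherits(p, "rt_params"))
  if (!is.finite(p$tau_e)) return(c(f_l = p$f0, f_u = p$f0))
  c(f_l = solve_bound(p, "lower", 1), f_u = solve_bound(p, "upper", 1))
}

#' Support bounds of the truncated (first-moment closure) solution
#'
#' The closed-form marginal (see [steady_state_pdf()]) vanishes where
#' `(r(f)/(sqrt(n) tau_E))^2 < (f - f0)^2`; its support solves
#' `f = f0 +/- r(f)/(sqrt(n) tau_E)`, nested strictly inside the exact bounds
#' for `n > 1`.
#'
#' @param p An [dimensionless_params()] object.
#' @return Named numeric vector `c(f_l_t, f_u_t)`.
#' @export
truncated_bounds <- function(p) {
  stopifnot(inherits(p, "rt_params"))
  if (!is.finite(p$tau_e)) return(c(f_l_t = p$f0, f_u_t = p$f0))
  sn <- sqrt(p$n)
  c(f_l_t = solve_bound(p, "lower", sn), f_u_t = solve_bound(p, "upper", sn))
}

# bracket term of the closed-form density and its derivative
pdf_bracket <- function(f, p) {
  (run_probability(f) / (sqrt(p$n) * p$tau_e))^2 - (f - p$f0)^2
}
pdf_bracket_deriv <- function(f, p) {
  r <- run_probability(f)
  2 * r^2 * (1 - r) / (p$n * p$tau_e^2) - 2 * (f - p$f0)
}

#' Closed-form steady-state marginal distribution of the internal state
#'
#' First-angular-moment closure of the stationary Fokker-Planck equation for a
#' log-sensing walker in an exponential gradient:
#' \deqn{\bar p(f) \propto \frac{r(f)/\tau_E}{B(f)}
#'   \exp\left(-\int_{f_0}^{f} \frac{f_1 - f_0}{\tau_D(f_1) B(f_1)} d f_1\right),
#'   \quad B(f) = \left(\frac{r(f)}{\sqrt{n}\,\tau_E}\right)^2 - (f - f_0)^2.}
#'
#' The density has integrable power-law singularities `B^(c-1)` at the edges
#' of the truncated support with exponents
#' `c = |f_edge - f0| / (tau_D(f_edge) |B'(f_edge)|)`; when `c` is small
#' (strong positive feedback) a large fraction of the mass sits closer to the
#' edge than floating point can resolve. The density is therefore evaluated
#' on a uniform core grid plus geometrically edge-clustered points, and the
#' unresolved tails beyond the outermost grid points are carried as explicit
#' point masses (`edge_mass`) computed from the analytic exponents. Total
#' mass (trapezoid integral of the density plus the two atoms) is 1.
#'
#' @param p An [dimensionless_params()] object (finite `tau_e`).
#' @param grid_size Total number of grid points, at least 1000. Default 6000.
#' @param edge_depth Innermost clustered point, as a fraction of the support
#'   half-width. Default 1e-13.
#' @return An object of class `rt_pdf`: `f_grid`, `density`, normalization
#'   `W`, `support_trunc`, `support_exact`, `edge_mass` (lower/upper atoms),
#'   and the parameter set.
#' @references The closure and its potential interpretation follow the
#'   angular-moment expansion of the rotational Fokker-Planck operator in
#'   Gegenbauer polynomials, truncated after the first moment.
#' @export
steady_state_pdf <- function(p, grid_size = 6000, edge_depth = 1e-13) {
  stopifnot(inherits(p, "rt_params"))
  if (!is.finite(p$tau_e)) stop("tau_e must be finite for the closed form")
  if (grid_size < 1000) stop("'grid_size' must be at least 1000")
  tb <- truncated_bounds(p)
  eb <- exact_bounds(p)
  f_l <- tb[["f_l_t"]]; f_u <- tb[["f_u_t"]]
  hw_l <- p$f0 - f_l; hw_u <- f_u - p$f0
  n_edge <- max(200L, round(0.1 * grid_size))
  n_core <- grid_size - 2L * n_edge
  core <- seq(f_l + 1e-3 * hw_l, f_u - 1e-3 * hw_u, length.out = n_core)
  e_u <- f_u - hw_u * 10^seq(-3, log10(edge_depth), length.out = n_edge)
  e_l <- f_l + hw_l * 10^seq(-3, log10(edge_depth), length.out = n_edge)
  fg <- sort(unique(c(core, e_u, e_l)))
  B <- pdf_bracket(fg, p)
  A <- (fg - p$f0) / (tau_d(fg, p) * B)
  i0 <- which.min(abs(fg - p$f0))
  I <- cumtrapz_q(fg, A)
  I <- I - I[i0]
  dens <- (run_probability(fg) / p$tau_e) / B * exp(-I)
  if (any(!is.finite(dens))) {
    stop("density evaluation overflowed; grid too coarse to resolve support")
  }
  # analytic tail atoms beyond the outermost resolved points:
  # dens ~ K u^(c-1) near an edge (u = distance to edge), so the remaining
  # mass is dens(u_last) * u_last / c
  G <- length(fg)
  c_u <- (f_u - p$f0) / (tau_d(f_u, p) * abs(pdf_bracket_deriv(f_u, p)))
  c_l <- (p$f0 - f_l) / (tau_d(f_l, p) * abs(pdf_bracket_deriv(f_l, p)))
  atom_u <- dens[G] * (f_u - fg[G]) / c_u
  atom_l <- dens[1] * (fg[1] - f_l) / c_l
  W <- trapz_q(fg, dens) + atom_u + atom_l
  structure(
    list(f_grid = fg, density = dens / W, W = W,
         support_trunc = c(f_l_t = f_l, f_u_t = f_u),
         support_exact = eb,
         edge_mass = c(lower = atom_l / W, upper = atom_u / W),
         edge_exponent = c(lower = c_l, upper = c_u),
         params = p, kind = "analytic"),
    class = "rt_pdf"
  )
}

#' @export
print.rt_pdf <- function(x, ...) {
  cat(sprintf("Steady-state internal-state distribution (%s)\n", x$kind))
  cat(sprintf("  grid: %d points on [%.4f, %.4f]\n", length(x$f_grid),
              min(x$f_grid), max(x$f_grid)))
  if (!is.null(x$edge_mass) && any(x$edge_mass > 1e-12)) {
    cat(sprintf("  edge atoms: %.4g (lower), %.4g (upper)\n",
                x$edge_mass[["lower"]], x$edge_mass[["upper"]]))
  }
  cat(sprintf("  mean f = %.4f, var f = %.4g\n", pdf_mean(x), pdf_var(x)))
  invisible(x)
}

#' @export
as.data.frame.rt_pdf <- function(x, ...) {
  data.frame(f = x$f_grid, density = x$density)
}

#' Mean and variance of an `rt_pdf`
#'
#' Trapezoid moments of the gridded density plus any edge point masses.
#'
#' @param pdf An `rt_pdf` object.
#' @return A single number.
#' @export
pdf_mean <- function(pdf) {
  stopifnot(inherits(pdf, "rt_pdf"))
  m <- trapz_q(pdf$f_grid, pdf$f_grid * pdf$density)
  if (!is.null(pdf$edge_mass)) {
    m <- m + pdf$edge_mass[["lower"]] * pdf$support_trunc[["f_l_t"]] +
      pdf$edge_mass[["upper"]] * pdf$support_trunc[["f_u_t"]]
  }
  m
}

#' @rdname pdf_mean
#' @export
pdf_var <- function(pdf) {
  stopifnot(inherits(pdf, "rt_pdf"))
  m <- pdf_mean(pdf)
  v <- trapz_q(pdf$f_grid, (pdf$f_grid - m)^2 * pdf$density)
  if (!is.null(pdf$edge_mass)) {
    v <- v + pdf$edge_mass[["lower"]] * (pdf$support_trunc[["f_l_t"]] - m)^2 +
      pdf$edge_mass[["upper"]] * (pdf$support_trunc[["f_u_t"]] - m)^2
  }
  v
}

#' Total probability mass of an `rt_pdf`
#'
#' Trapezoid integral of the gridded density plus edge atoms; 1 up to
#' quadrature error.
#'
#' @param pdf An `rt_pdf` object.
#' @export
pdf_mass <- function(pdf) {
  stopifnot(inherits(pdf, "rt_pdf"))
  m <- trapz_q(pdf$f_grid, pdf$density)
  if (!is.null(pdf$edge_mass)) m <- m + sum(pdf$edge_mass)
  m
}

#' CDF of an `rt_pdf` evaluated at given points
#'
#' @param pdf An `rt_pdf` object.
#' @param q Numeric vector of evaluation points.
#' @return CDF values in `[0, 1]` (right-continuous at edge atoms).
#' @export
pdf_cdf <- function(pdf, q) {
  stopifnot(inherits(pdf, "rt_pdf"))
  fg <- pdf$f_grid
  inc <- c(0, cumsum(diff(fg) * (utils::head(pdf$density, -1) +
                                   utils::tail(pdf$density, -1)) / 2))
  lower_atom <- if (is.null(pdf$edge_mass)) 0 else pdf$edge_mass[["lower"]]
  upper_edge <- if (is.null(pdf$support_trunc)) max(fg) else
    pdf$support_trunc[["f_u_t"]]
  lower_edge <- if (is.null(pdf$support_trunc)) min(fg) else
    pdf$support_trunc[["f_l_t"]]
  v <- stats::approx(fg, lower_atom + inc, xout = q, yleft = NA,
                     yright = NA)$y
  v[q < lower_edge] <- 0
  v[q >= lower_edge & q < fg[1]] <- lower_atom
  v[q >= fg[length(fg)] & q < upper_edge] <- lower_atom + inc[length(inc)]
  v[q >= upper_edge] <- 1
  pmin(1, pmax(0, v))
}

#' Kolmogorov-Smirnov distance between two distributions
#'
#' Sup-norm distance between CDFs. Each argument may be an `rt_pdf` (gridded
#' density with optional edge atoms) or a numeric vector of samples (empirical
#' CDF). Used for the cross-method agreement checks between the closed form,
#' the spectral solver, and Monte-Carlo histograms.
#'
#' @param a,b `rt_pdf` objects or numeric sample vectors.
#' @param n_eval Number of evaluation points. Default 2000.
#' @return The KS distance in `[0, 1]`.
#' @export
ks_distance <- function(a, b, n_eval = 2000) {
  cdf_of <- function(obj) {
    if (inherits(obj, "rt_pdf")) {
      list(cdf = function(q) pdf_cdf(obj, q),
           range = range(obj$f_grid))
    } else {
      obj <- sort(as.numeric(obj))
      ec <- stats::ecdf(obj)
      list(cdf = function(q) ec(q), range = range(obj))
    }
  }
  ca <- cdf_of(a); cb <- cdf_of(b)
  lo <- min(ca$range[1], cb$range[1]); hi <- max(ca$range[2], cb$range[2])
  qs <- seq(lo, hi, length.out = n_eval)
  max(abs(ca$cdf(qs) - cb$cdf(qs)))
}

#' Drift speed from a steady-state distribution
#'
#' The stationary Fokker-Planck balance ties the spatial flux to the
#' internal-state excess: `V_D = tau_E * <f - f0>`, in units of the run
#' speed `v0`.
#'
#' @param pdf An `rt_pdf` object.
#' @param tau_e Positive-feedback timescale ratio; defaults to the value
#'   stored in `pdf$params`.
#' @return Drift speed (units of `v0`).
#' @export
drift_from_pdf <- function(pdf, tau_e = NULL) {
  stopifnot(inherits(pdf, "rt_pdf"))
  if (is.null(tau_e)) tau_e <- pdf$params$tau_e
  f0 <- pdf$params$f0
  tau_e * (pdf_mean(pdf) - f0)
}

#' Near-Gaussian limit of the steady state
#'
#' When adaptation dominates (`tau_E >~ 1`) and reorientation is fast
#' (`tau_D0 < 1`), the stationary marginal is nearly Gaussian with variance
#' `sigma2 = tau_D0 * r0^2 / (n * tau_E^2)` and normalization correction
#' `Z = 1 + tau_D0/4`. Both are leading terms of an expansion in small
#' `tau_D0`; outside that regime `valid` is set to `FALSE` (at `tau_D0 = 1`
#' the actual variance is about half of `sigma2`).
#'
#' @param p An [dimensionless_params()] object.
#' @return A list with `sigma2`, `Z`, `f_m` (mean internal state including
#'   the drift shift), `v_d_mft` (the mean-field drift), and `valid`.
#' @export
gaussian_limit <- function(p) {
  stopifnot(inherits(p, "rt_params"))
  sigma2 <- p$tau_d0 * p$r0^2 / (p$n * p$tau_e^2)
  vd <- mft_drift(p)
  list(sigma2 = sigma2,
       Z = 1 + p$tau_d0 / 4,
       f_m = p$f0 + if (is.finite(p$tau_e)) vd / p$tau_e else 0,
       v_d_mft = vd,
       valid = is.finite(p$tau_e) && p$tau_e >= 1 && p$tau_d0 < 1)
}

#' Mean-field drift speed
#'
#' Leading-order mean-field result, valid when adaptation dominates
#' (`tau_E >> 1`):
#' `V_D = r0 * tau_D0' / (n * tau_E * (1 + tau_D0))`, with
#' `tau_D0' = tau_D0 * (D_T - D_R) * r0 * (1 - r0) / (r0 D_R + (1 - r0) D_T)`
#' the sensitivity of the decorrelation time to the internal state. Vanishes
#' when `D_T = D_R` (reorientation blind to the motility state) and decays as
#' `1/tau_E`.
#'
#' @param p An [dimensionless_params()] object.
#' @return Drift speed (units of `v0`).
#' @export
mft_drift <- function(p) {
  stopifnot(inherits(p, "rt_params"))
  if (!is.finite(p$tau_e)) return(0)
  tdp <- p$tau_d0 * (p$dtr - 1) / (p$r0 + (1 - p$r0) * p$dtr) *
    p$r0 * (1 - p$r0)
  p$r0 * tdp / (p$n * p$tau_e * (1 + p$tau_d0))
}

#' Potential decomposition of the steady state
#'
#' Interprets the closed-form marginal as `p(f) ~ exp(-V(f))`. The associated
#' force is
#' `F(f) = d/df ln[(r/tau_E)/B(f)] - (f - f0)/(tau_D(f) B(f))` and the second
#' (dominant) term defines a spring-like restoring force with state-dependent
#' stiffness `k(f) = 1/(tau_D(f) B(f))`. The stiffness diverges at the
#' truncated support edges, decreases with `tau_D`, and is asymmetric in `f`
#' when `r(f)` and `tau_D(f)` are increasing, which shifts the distribution
#' toward high `f`.
#'
#' @param pdf An `rt_pdf` from [steady_state_pdf()].
#' @param p Parameters; default `pdf$params`.
#' @return A list of class `rt_potential` with `f_grid`, `V` (potential, up
#'   to an additive constant), `force`, and `spring_k` on the grid.
#' @export
potential_decomposition <- function(pdf, p = pdf$params) {
  stopifnot(inherits(pdf, "rt_pdf"), inherits(p, "rt_params"))
  fg <- pdf$f_grid
  B <- pdf_bracket(fg, p)
  r <- run_probability(fg)
  V <- -log(pmax(pdf$density, 1e-300))
  # d/df ln[(r/tau_E)/B] = (1-r) - B'/B
  force <- (1 - r) - pdf_bracket_deriv(fg, p) / B -
    (fg - p$f0) / (tau_d(fg, p) * B)
  spring_k <- 1 / (tau_d(fg, p) * B)
  structure(list(f_grid = fg, V = V, force = force, spring_k = spring_k),
            class = "rt_potential")
}

#' @export
as.data.frame.rt_potential <- function(x, ...) {
  data.frame(f = x$f_grid, V = x$V, force = x$force, spring_k = x$spring_k)
}
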