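#' Gradient profiles
#'
#' Static attractant fields used by the agent simulator and the experiment
#' runners. Three analytic geometries are provided, all parameterised by a
#' single coordinate `R` (distance from the source):
#'
#' * `"exponential"`: `C(R) = C0 * exp(-R / L0)`. For a log-sensing receptor
#'   the gradient length scale `L = 1/|d ln C / dR| = L0` is constant, so the
#'   positive-feedback timescale `tau_E` is constant too.
#' * `"linear"`: `C(R) = C1 - a1 * R`, clipped at zero beyond `R = C1/a1`.
#'   `L = C/a1 = C1/a1 - R` grows toward the source.
#' * `"localized_source"`: constant `C2` inside a ball of radius `R0`; outside,
#'   `C(R) = C2 * R0 / R` (the steady state of diffusion from a spherical
#'   source without decay), so `L = R` shrinks toward the source.
#'
#' A `"custom"` kind accepts a tabulated profile `(R, C)` interpolated with a
#' monotone cubic spline; `L` is computed from the analytic derivative of the
#' interpolant.
#'
#' The perceived signal is `phi(C) = ln((1 + C/K_i)/(1 + C/K_a))`, the
#' free-energy change of a two-state receptor with inactive/active
#' dissociation constants `K_i < K_a`. Between `K_i << C << K_a` the receptor
#' is log-sensing (`phi ~ ln C + const`); above `K_a` it saturates, which
#' inflates the effective length scale `L` and hence `tau_E`. With
#' `saturating = FALSE` pure log-sensing `phi = ln C` is used instead.
#'
#' @param kind One of `"exponential"`, `"linear"`, `"localized_source"`,
#'   `"custom"`.
#' @param C0,L0 Source concentration (mM) and decay length (um) of the
#'   exponential profile.
#' @param C1,a1 Source concentration (mM) and slope (mM/um) of the linear
#'   profile.
#' @param C2,R0 Plateau concentration (mM) and source radius (um) of the
#'   localized source.
#' @param R_tab,C_tab Tabulated radii (um) and concentrations (mM) for
#'   `kind = "custom"`.
#' @param K_i,K_a Inactive/active receptor dissociation constants, mM
#'   (defaults are the methyl-aspartate values 0.0182 and 3).
#' @param saturating Use the full two-state receptor signal (default `TRUE`);
#'   `FALSE` gives pure log-sensing.
#' @param geometry `"radial"` (R = distance from a point/ball source in n-D)
#'   or `"planar"` (R = a single Cartesian coordinate, gradient along one
#'   axis).
#' @return An object of class `rt_gradient`.
#' @examples
#' g <- gradient_profile("exponential", C0 = 10, L0 = 1000)
#' concentration(g, 0)           # 10 mM
#' length_scale(g, 500)          # > L0: C(500) ~ 6 mM is near saturation
#' @export
gradient_profile <- function(kind = c("exponential", "linear",
                                      "localized_source", "custom"),
                             C0 = NULL, L0 = NULL, C1 = NULL, a1 = NULL,
                             C2 = NULL, R0 = NULL, R_tab = NULL, C_tab = NULL,
                             K_i = 0.0182, K_a = 3, saturating = TRUE,
                             geometry = c("radial", "planar")) {
  kind <- match.arg(kind)
  geometry <- match.arg(geometry)
  pos1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(sprintf("'%s' must be a single positive number", nm))
    }
    x
  }
  if (!is.numeric(K_i) || !is.numeric(K_a) || K_i <= 0 || K_a <= 0 ||
      K_i >= K_a) {
    stop("must have 0 < K_i < K_a")
  }
  g <- list(kind = kind, K_i = K_i, K_a = K_a,
            saturating = isTRUE(saturating), geometry = geometry)
  if (kind == "exponential") {
    g$C0 <- pos1(C0, "C0"); g$L0 <- pos1(L0, "L0")
  } else if (kind == "linear") {
    g$C1 <- pos1(C1, "C1"); g$a1 <- pos1(a1, "a1")
  } else if (kind == "localized_source") {
    g$C2 <- pos1(C2, "C2"); g$R0 <- pos1(R0, "R0")
  } else {
    if (is.null(R_tab) || is.null(C_tab) || length(R_tab) != length(C_tab) ||
        length(R_tab) < 4L || is.unsorted(R_tab, strictly = TRUE) ||
        any(C_tab < 0)) {
      stop("custom profile needs sorted R_tab and nonnegative C_tab (>= 4 points)")
    }
    g$R_tab <- as.numeric(R_tab)
    g$C_tab <- as.numeric(C_tab)
    g$spline <- stats::splinefun(R_tab, C_tab, method = "monoH.FC")
  }
  structure(g, class = "rt_gradient")
}

#' @export
print.rt_gradient <- function(x, ...) {
  cat(sprintf("Gradient profile: %s (%s geometry, %s)\n", x$kind, x$geometry,
              if (x$saturating) "saturating receptor" else "pure log-sensing"))
  pars <- switch(x$kind,
    exponential = sprintf("C0 = %g mM, L0 = %g um", x$C0, x$L0),
    linear = sprintf("C1 = %g mM, a1 = %g mM/um", x$C1, x$a1),
    localized_source = sprintf("C2 = %g mM, R0 = %g um", x$C2, x$R0),
    custom = sprintf("%d tabulated points", length(x$R_tab)))
  cat(sprintf("  %s; K_i = %g, K_a = %g mM\n", pars, x$K_i, x$K_a))
  invisible(x)
}

#' Concentration at a radial position
#'
#' @param g An [gradient_profile()] object.
#' @param R Radial position(s), um; must be nonnegative.
#' @return Concentration(s), mM (nonnegative, continuous in `R`).
#' @export
concentration <- function(g, R) {
  stopifnot(inherits(g, "rt_gradient"))
  if (!is.numeric(R) || any(!is.finite(R)) || any(R < 0)) {
    stop("'R' must be finite and >= 0")
  }
  switch(g$kind,
    exponential = g$C0 * exp(-R / g$L0),
    linear = pmax(0, g$C1 - g$a1 * R),
    localized_source = ifelse(R <= g$R0, g$C2, g$C2 * g$R0 / R),
    custom = pmax(0, g$spline(pmin(pmax(R, min(g$R_tab)), max(g$R_tab))))
  )
}

# dC/dR, same kinds; used for length scales. Zero where the profile is flat.
concentration_slope <- function(g, R) {
  switch(g$kind,
    exponential = -g$C0 * exp(-R / g$L0) / g$L0,
    linear = ifelse(R < g$C1 / g$a1, -g$a1, 0),
    localized_source = ifelse(R <= g$R0, 0, -g$C2 * g$R0 / R^2),
    custom = g$spline(pmin(pmax(R, min(g$R_tab)), max(g$R_tab)), deriv = 1L)
  )
}

#' Perceived signal of the two-state receptor
#'
#' `phi(C) = ln((1 + C/K_i)/(1 + C/K_a))` when the profile is saturating,
#' `phi(C) = ln(C)` for pure log-sensing. The saturating signal satisfies
#' `phi(0) = 0`, is strictly increasing, and is bounded by `ln(K_a/K_i)`.
#'
#' @param g An [gradient_profile()] object.
#' @param C Concentration(s), mM; must be nonnegative.
#' @return Dimensionless perceived signal.
#' @export
perceived_signal <- function(g, C) {
  stopifnot(inherits(g, "rt_gradient"))
  if (!is.numeric(C) || any(!is.finite(C)) || any(C < 0)) {
    stop("'C' must be finite and >= 0")
  }
  if (g$saturating) {
    log1p(C / g$K_i) - log1p(C / g$K_a)
  } else {
    ifelse(C > 0, log(C), -Inf)
  }
}

# d phi / dC
signal_slope <- function(g, C) {
  if (g$saturating) {
    1 / (g$K_i + C) - 1 / (g$K_a + C)
  } else {
    ifelse(C > 0, 1 / C, Inf)
  }
}

#' Local gradient length scale
#'
#' `L(R) = 1 / |d phi / dR| = 1 / |phi'(C) * C'(R)|`. For pure log-sensing
#' profiles this reduces to `L0` (exponential), `C1/a1 - R` (linear) and `R`
#' (localized source, outside the ball). Receptor saturation can only reduce
#' sensitivity, so the saturating `L` is always at least the log-sensing
#' value. Where the perceived gradient vanishes (inside the source ball,
#' beyond the zero of a linear profile) the length scale is `Inf`, not an
#' error.
#'
#' @param g An [gradient_profile()] object.
#' @param R Radial position(s), um; nonnegative.
#' @return Length scale(s), um; possibly `Inf`.
#' @export
length_scale <- function(g, R) {
  stopifnot(inherits(g, "rt_gradient"))
  if (!is.numeric(R) || any(!is.finite(R)) || any(R < 0)) {
    stop("'R' must be finite and >= 0")
  }
  C <- concentration(g, R)
  dCdR <- concentration_slope(g, R)
  dphidR <- abs(signal_slope(g, C) * dCdR)
  # 0 * Inf (flat profile, log-sensing at C = 0) means no perceived gradient
  dphidR[is.na(dphidR) | C <= 0] <- 0
  ifelse(dphidR > 0, 1 / dphidR, Inf)
}

#' Local positive-feedback timescale
#'
#' `tau_E(R) = L(R) / (t_M * N * H * v0)`, the position-dependent ratio of
#' the positive-feedback timescale to the memory time. Constant for a
#' non-saturating exponential profile; decreasing toward the source for a
#' localized source; increasing toward the source for a linear profile.
#'
#' @param g An [gradient_profile()] object.
#' @param mp An [model_params()] object.
#' @param R Radial position(s), um; nonnegative.
#' @return `tau_E(R)` (dimensionless), possibly `Inf`.
#' @export
tau_e_local <- function(g, mp, R) {
  stopifnot(inherits(mp, "rt_model_params"))
  length_scale(g, R) / (mp$t_m * mp$N * mp$H * mp$v0)
}
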