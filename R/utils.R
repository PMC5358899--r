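# Trapezoid quadrature on (possibly non-uniform) grids. Interval-area
# summation is numerically robust for densities with huge dynamic range
# (edge-clustered grids carry values spanning ~15 orders of magnitude, where
# shoelace-style formulas lose ~1e-5 to cancellation).
trapz_q <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

cumtrapz_q <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}
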