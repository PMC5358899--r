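# JSON (de)serialization of parameter sets, gradient profiles and experiment
# specifications. Field names follow the model's standard symbols (tau_E,
# tau_D0, t_M, D_R, ...).

#' Write parameters, profiles or experiment specs to JSON
#'
#' @param x An `rt_params`, `rt_model_params`, `rt_gradient` or
#'   `rt_experiment` object.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_config <- function(x, path = NULL) {
  lst <- if (inherits(x, "rt_params")) {
    list(type = "dimensionless", tau_E = x$tau_e, tau_D0 = x$tau_d0,
         r0 = x$r0, n = x$n, dtr = x$dtr)
  } else if (inherits(x, "rt_model_params")) {
    list(type = "physical", t_M = x$t_m, N = x$N, H = x$H, f0 = x$f0,
         v0 = x$v0, D_R = x$d_r, D_T = x$d_t, n = x$n, t_S = x$t_s,
         sigma_f = x$sigma_f)
  } else if (inherits(x, "rt_gradient")) {
    keep <- intersect(c("kind", "C0", "L0", "C1", "a1", "C2", "R0",
                        "R_tab", "C_tab", "K_i", "K_a", "saturating",
                        "geometry"), names(x))
    c(list(type = "gradient"), x[keep])
  } else if (inherits(x, "rt_experiment")) {
    lst <- unclass(x)
    c(list(type = "experiment"), lst[!vapply(lst, is.null, TRUE)])
  } else {
    stop("unsupported object")
  }
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read parameters, profiles or experiment specs from JSON
#'
#' @param path File path, or a JSON string.
#' @return The reconstructed object (class chosen by the `type` field).
#' @export
read_config <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  type <- lst$type
  if (is.null(type)) stop("config lacks a 'type' field")
  switch(type,
    dimensionless = dimensionless_params(tau_e = lst$tau_E,
                                         tau_d0 = lst$tau_D0, r0 = lst$r0,
                                         n = lst$n, dtr = lst$dtr),
    physical = model_params(t_m = lst$t_M, N = lst$N, H = lst$H, f0 = lst$f0,
                            v0 = lst$v0, d_r = lst$D_R, d_t = lst$D_T,
                            n = lst$n, t_s = lst$t_S, sigma_f = lst$sigma_f),
    gradient = do.call(gradient_profile, lst[setdiff(names(lst), "type")]),
    experiment = do.call(experiment_spec, lst[setdiff(names(lst), "type")]),
    stop(sprintf("unknown config type '%s'", type))
  )
}
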