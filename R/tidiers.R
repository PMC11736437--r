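#' Tidy a calibration fit
#'
#' @param x An `rm_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.rm_fit <- function(x, ...) {
  x$estimates
}

#' One-row summary of a calibration fit
#'
#' @param x An `rm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the fitted leakage, residual norm,
#'   convergence flag, observation count and (where applicable) the inferred
#'   dynamical regime.
#' @export
glance.rm_fit <- function(x, ...) {
  tibble(
    method = x$method,
    s = x$estimates$estimate[x$estimates$term == "s"],
    residual_norm = x$residual_norm,
    converged = x$converged,
    n_obs = x$n_obs,
    regime = x$regime %||% NA_character_
  )
}
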