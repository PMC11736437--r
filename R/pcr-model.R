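#' Free C monomer concentration from total C
#'
#' Solves the rescaled monomer-dimer conservation `c_free + 2*c_free^2/alpha =
#' c_total` for the free-monomer concentration, using the positive root of the
#' quadratic in the cancellation-safe form `2*c_total / (1 + sqrt(1 +
#' 8*c_total/alpha))`.
#'
#' @param c_total Rescaled total C concentration(s), >= 0. Vectorised.
#' @param alpha Dimer-formation parameter, > 0.
#' @return Rescaled free-monomer concentration(s), same length as `c_total`.
#' @examples
#' free_monomer(1, alpha = 16.9)
#' @export
free_monomer <- function(c_total, alpha) {
  check_nonnegative(c_total, "c_total")
  check_positive(alpha, "alpha")
  2 * c_total / (1 + sqrt(1 + 8 * c_total / alpha))
}

# derivative d c_free / d c_total (used for stability classification)
free_monomer_deriv <- function(c_total, alpha) {
  1 / sqrt(1 + 8 * c_total / alpha)
}

#' Statistical weights of the C-binding configurations at the CR promoter
#'
#' In rescaled units the activation configuration (C dimer at the distal site)
#' has weight `z1 = c_free^2`, the tetramer repression configuration
#' `z2 = (omega/p) * c_free^4`, and the proximal-site repression configuration
#' `z3 = c_free^2 / p`.
#'
#' @param c_free Rescaled free-monomer concentration(s), >= 0. Vectorised.
#' @param p,omega Internal parameters.
#' @return A tibble with columns `z1`, `z2`, `z3`.
#' @export
binding_weights <- function(c_free, p, omega) {
  check_nonnegative(c_free, "c_free")
  check_positive(p, "p")
  check_nonnegative(omega, "omega")
  tibble(z1 = c_free^2,
         z2 = (omega / p) * c_free^4,
         z3 = c_free^2 / p)
}

# regulated part of the promoter activity, f(c_free)
regulated_activity <- function(c_free, p, omega) {
  c_free^2 / (1 + (1 + 1 / p) * c_free^2 + (omega / p) * c_free^4)
}

# df/dc_free; numerator simplifies to 2*c_free*(1 - (omega/p)*c_free^4)
regulated_activity_deriv <- function(c_free, p, omega) {
  den <- 1 + (1 + 1 / p) * c_free^2 + (omega / p) * c_free^4
  2 * c_free * (1 - (omega / p) * c_free^4) / den^2
}

#' Transcription activity of the CR promoter
#'
#' Rescaled activity `s + z1 / (1 + z1 + z2 + z3)`: leakage plus the
#' statistical weight of the activation configuration over the partition
#' function. Bounded in `[s, s + 1)`; vanishing activation at `c_free = 0`
#' and full repression (activity back to `s`) as `c_free` grows when
#' `omega > 0`.
#'
#' @param c_free Rescaled free-monomer concentration(s). Vectorised.
#' @param s Promoter leakage, >= 0.
#' @param p,omega Internal parameters.
#' @return Activity value(s) in `[s, s + 1)`.
#' @examples
#' pcr_activity(1, s = 0, p = 25, omega = 130)
#' @export
pcr_activity <- function(c_free, s, p, omega) {
  check_nonnegative(c_free, "c_free")
  check_nonnegative(s, "s")
  s + regulated_activity(c_free, p, omega)
}

#' Rescaled C dynamics right-hand side
#'
#' The production-minus-dilution balance of the rescaled total-C dynamics:
#' `s + f(c_free(c_total)) - c_total / r`, whose zeros are the steady states.
#' All roots lie in `[0, r * (s + 1)]` since the activity is bounded by
#' `s + 1`.
#'
#' @param c_total Rescaled total C concentration(s). Vectorised.
#' @param s,r External parameters (leakage and expression strength).
#' @param internal Internal parameters ([internal_params()] or a preset).
#' @return Rate value(s).
#' @export
c_dynamics_rhs <- function(c_total, s, r, internal) {
  internal <- as_internal_params(internal)
  check_nonnegative(s, "s")
  check_positive(r, "r")
  cf <- free_monomer(c_total, internal$alpha)
  s + regulated_activity(cf, internal$p, internal$omega) - c_total / r
}

# d rhs / d c_total, analytic (chain rule through the monomer-dimer map)
c_dynamics_rhs_deriv <- function(c_total, s, r, internal) {
  internal <- as_internal_params(internal)
  cf <- free_monomer(c_total, internal$alpha)
  regulated_activity_deriv(cf, internal$p, internal$omega) *
    free_monomer_deriv(c_total, internal$alpha) - 1 / r
}

#' Absolute-units C dynamics right-hand side
#'
#' The unscaled production-minus-dilution balance
#' `n*phi_l + n*phi_m * f(C/K_d) - lambda * C_t`, with the free monomer `C`
#' obtained from the monomer-dimer equilibrium at dissociation constant `kd1`
#' and `K_d = sqrt(kd1 * kd2)`. Consistent with [c_dynamics_rhs()] under the
#' rescaling `c_total = C_t / K_d`, `s = phi_l / phi_m`,
#' `r = n * phi_m / (lambda * K_d)`, up to the overall rate factor
#' `n * phi_m / K_d`.
#'
#' @param c_total Total C concentration(s), absolute units. Vectorised.
#' @param phi_l,phi_m Basal and maximal transcription rate constants (> 0).
#' @param n Plasmid copy number (> 0).
#' @param lambda Dilution (growth) rate (> 0).
#' @param kd1 Monomer dimerisation dissociation constant (> 0).
#' @param kd2 Dimer/DBS dissociation constant (> 0).
#' @param p,omega Internal parameters.
#' @return Rate value(s) in absolute concentration per time.
#' @export
c_dynamics_rhs_absolute <- function(c_total, phi_l, phi_m, n, lambda,
                                    kd1, kd2, p, omega) {
  check_nonnegative(c_total, "c_total")
  check_nonnegative(phi_l, "phi_l")
  check_positive(phi_m, "phi_m")
  check_positive(n, "n")
  check_positive(lambda, "lambda")
  check_positive(kd1, "kd1")
  check_positive(kd2, "kd2")
  kd <- sqrt(kd1 * kd2)
  # free monomer at absolute scale: C = (kd1/4) * (sqrt(1 + 8 Ct/kd1) - 1)
  cf <- 2 * c_total / (1 + sqrt(1 + 8 * c_total / kd1))
  n * phi_l + n * phi_m * regulated_activity(cf / kd, p, omega) -
    lambda * c_total
}

#' Total restriction endonuclease from total C
#'
#' R is co-transcribed with C on a bicistronic transcript; with no variable
#' attenuation or relative-translation change their amounts are directly
#' proportional: `r_total = k_rc * c_total`.
#'
#' @param c_total Rescaled total C. Vectorised.
#' @param k_rc Proportionality constant (> 0).
#' @return Rescaled total R.
#' @export
r_total <- function(c_total, k_rc = 1) {
  check_nonnegative(c_total, "c_total")
  check_positive(k_rc, "k_rc")
  k_rc * c_total
}
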