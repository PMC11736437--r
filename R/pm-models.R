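#' Steady-state methyltransferase level, Esp1396I architecture
#'
#' The C dimer represses the M promoter; in rescaled units the steady state is
#' `m_total = phi * r / (1 + gamma * c_free^2)` (the dimer concentration is
#' proportional to the squared free monomer).
#'
#' @param c_free Rescaled free C monomer concentration(s). Vectorised.
#' @param r Overall expression strength (> 0).
#' @param phi Maximal P.M-to-P.CR expression-rate ratio (> 0).
#' @param gamma Repression-strength ratio (>= 0; 5.1 for Esp1396I).
#' @return Rescaled total M, same length as `c_free`.
#' @export
m_esp1396i <- function(c_free, r, phi = 1, gamma = 5.1) {
  check_nonnegative(c_free, "c_free")
  check_positive(r, "r")
  check_positive(phi, "phi")
  check_nonnegative(gamma, "gamma")
  phi * r / (1 + gamma * c_free^2)
}

#' Steady-state methyltransferase level, AhdI architecture
#'
#' M negatively autoregulates: the M monomer dimerises and the dimer represses
#' the M promoter. The steady state solves the coupled pair
#' `m_total = phi * r / (1 + m_free^2)` with `m_free` given by the
#' monomer-dimer conservation at dimer-formation parameter `alpha_m`. The
#' left-hand side is increasing and the right-hand side decreasing in
#' `m_total`, so the residual `h(m_total) = m_total * (1 + m_free^2) - phi*r`
#' is strictly increasing and the root is unique; it is bracketed in
#' `[0, phi*r]` and refined by bisection to 1e-12 absolute.
#'
#' @param r Overall expression strength(s) (> 0). Vectorised.
#' @param phi Maximal P.M-to-P.CR expression-rate ratio (0.2 for AhdI).
#' @param alpha_m M dimer-formation parameter (2 * sqrt(5) for AhdI).
#' @return A tibble with columns `m_total` and `m_free`.
#' @export
m_ahdi <- function(r, phi = 0.2, alpha_m = 2 * sqrt(5)) {
  check_positive(r, "r")
  check_positive(phi, "phi")
  check_positive(alpha_m, "alpha_m")
  solve_one <- function(pr) {
    if (pr == 0) return(0)
    h <- function(mt) {
      mf <- free_monomer(mt, alpha_m)
      mt * (1 + mf^2) - pr
    }
    uniroot(h, lower = 0, upper = pr, tol = 1e-12, extendInt = "no")$root
  }
  mt <- vapply(phi * r, solve_one, numeric(1))
  tibble(m_total = mt, m_free = free_monomer(mt, alpha_m))
}

#' Steady-state methyltransferase level, EcoRV architecture
#'
#' The M promoter overlaps the CR promoter and fires only when RNA polymerase
#' is not bound at P.CR, i.e. for the repressed or empty CR-promoter
#' configurations. The steady state is `phi * r` times the summed weights of
#' those configurations over the full partition function.
#'
#' @param c_free Rescaled free C monomer concentration(s). Vectorised.
#' @param r Overall expression strength (> 0).
#' @param phi Maximal P.M-to-P.CR expression-rate ratio.
#' @param p,omega Internal parameters of the CR promoter.
#' @return Rescaled total M.
#' @export
m_ecorv <- function(c_free, r, phi = 1, p, omega) {
  check_nonnegative(c_free, "c_free")
  check_positive(r, "r")
  check_positive(phi, "phi")
  num <- 1 + c_free^2 / p + (omega / p) * c_free^4
  den <- 1 + (1 + 1 / p) * c_free^2 + (omega / p) * c_free^4
  phi * r * num / den
}

# architecture dispatch: rescaled total M for a preset
m_total_for <- function(preset, c_free, r) {
  pm <- preset$pm
  switch(pm$architecture,
    esp1396i = m_esp1396i(c_free, r, phi = pm$phi, gamma = pm$gamma),
    ahdi = m_ahdi(r, phi = pm$phi, alpha_m = pm$alpha_m)$m_total,
    ecorv = m_ecorv(c_free, r, phi = pm$phi,
                    p = preset$internal$p, omega = preset$internal$omega),
    abort(sprintf("Unknown M-promoter architecture '%s'.", pm$architecture))
  )
}

#' M-to-R ratio curve versus expression strength
#'
#' For each `r` on the grid, computes all total-C steady states, maps each to
#' the free monomer, the architecture-specific methyltransferase steady state,
#' the endonuclease level `r_total = k_rc * c_total`, and their ratio. Branch
#' and stability labels propagate from the bifurcation structure; on bistable
#' branches the ratio is reported per branch, never averaged.
#'
#' @param preset An [rm_preset()] (or a list with `internal`, `pm`, `k_rc`).
#' @param s Promoter leakage.
#' @param r_grid Positive, sorted grid of expression strengths.
#' @return A tibble of class `rm_mr_curve` with columns `r`, `branch`,
#'   `stability`, `c_total`, `c_free`, `m_total`, `r_total`, `m_over_r`
#'   (`NA` where `r_total` is zero); attribute `fold_interval`.
#' @examples
#' mr_curve(rm_preset("ahdi"), s = 0.0043, r_grid = c(2, 6.8, 20))
#' @export
mr_curve <- function(preset, s, r_grid) {
  if (!inherits(preset, "rm_preset")) {
    if (is.list(preset) && !is.null(preset$internal) && !is.null(preset$pm)) {
      preset$k_rc <- preset$k_rc %||% 1
      class(preset) <- "rm_preset"
    } else {
      abort("`preset` must be an rm_preset (see rm_preset()).")
    }
  }
  bd <- bifurcation_diagram(preset$internal, s, r_grid)
  out <- dplyr::mutate(
    as_tibble(bd),
    m_total = m_total_for(preset, .data$c_free, .data$r),
    r_total = r_total(.data$c_total, preset$k_rc),
    m_over_r = ifelse(.data$r_total > 0, .data$m_total / .data$r_total,
                      NA_real_)
  )
  out <- dplyr::select(out, "r", "branch", "stability", "c_total", "c_free",
                       "m_total", "r_total", "m_over_r")
  structure(out, class = c("rm_mr_curve", class(out)),
            fold_interval = attr(bd, "fold_interval"), s = s,
            preset = preset)
}
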