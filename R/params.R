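#' Internal (biophysical) parameters of a C-controlled R-M system
#'
#' The three dimensionless constants that characterise C-protein binding at
#' the CR-operon promoter: `p`, the ratio of distal (DBS) to proximal (PBS)
#' binding strength; `omega`, the DBS-PBS binding cooperativity; and `alpha`,
#' the dimer-formation parameter coupling the monomer-dimer equilibrium to the
#' operator affinity scale.
#'
#' @param p DBS-vs-PBS binding-strength ratio (dimensionless, > 0).
#' @param omega DBS-PBS binding cooperativity (dimensionless, > 0).
#' @param alpha Dimer-formation parameter (dimensionless, > 0).
#' @return An object of class `rm_internal`: a named list with elements
#'   `p`, `omega`, `alpha`.
#' @examples
#' internal_params(p = 25, omega = 130, alpha = 16.9)
#' @export
internal_params <- function(p, omega, alpha) {
  check_positive(p, "p")
  check_positive(omega, "omega")
  check_positive(alpha, "alpha")
  structure(list(p = p, omega = omega, alpha = alpha), class = "rm_internal")
}

#' @export
print.rm_internal <- function(x, ...) {
  cat(sprintf("<rm_internal> p = %g, omega = %g, alpha = %g\n",
              x$p, x$omega, x$alpha))
  invisible(x)
}

as_internal_params <- function(x) {
  if (inherits(x, "rm_internal")) return(x)
  if (inherits(x, "rm_preset")) return(x$internal)
  if (is.list(x) && all(c("p", "omega", "alpha") %in% names(x))) {
    return(internal_params(x$p, x$omega, x$alpha))
  }
  abort("Expected internal parameters (`rm_internal`), a preset, or a list with p, omega, alpha.")
}

#' External parameters of a C-controlled R-M system
#'
#' Promoter leakage `s` (basal-to-maximal transcription-rate ratio of the CR
#' promoter) and overall expression strength `r` (rising with plasmid copy
#' number and the expression rate, falling with growth rate). These are the
#' natural bifurcation coordinates of the rescaled dynamics.
#'
#' @param s Promoter leakage (dimensionless, >= 0).
#' @param r Overall C expression strength (dimensionless, > 0).
#' @return An object of class `rm_external`.
#' @export
external_params <- function(s, r) {
  check_nonnegative(s, "s")
  check_positive(r, "r")
  structure(list(s = s, r = r), class = "rm_external")
}

#' Infer internal parameters from measured dissociation constants
#'
#' Maps measured dissociation constants to the dimensionless internal
#' parameters: `p = kd3/kd2`, `omega = kd2 * kd3 / kd23`,
#' `alpha = sqrt(kd1/kd2)`. The map is invariant to a common rescaling of all
#' concentrations (with `kd23` scaling as concentration squared).
#'
#' @param kd1 C-monomer dimerisation dissociation constant (concentration).
#' @param kd2 C-dimer/DBS dissociation constant (concentration).
#' @param kd3 C-dimer/PBS dissociation constant (concentration).
#' @param kd23 Tetramer dissociation constant (concentration squared).
#' @return An [internal_params()] object.
#' @examples
#' infer_internal_params(kd1 = 4, kd2 = 1, kd3 = 25, kd23 = 0.25)
#' @export
infer_internal_params <- function(kd1, kd2, kd3, kd23) {
  check_positive(kd1, "kd1")
  check_positive(kd2, "kd2")
  check_positive(kd3, "kd3")
  check_positive(kd23, "kd23")
  internal_params(p = kd3 / kd2,
                  omega = kd2 * kd3 / kd23,
                  alpha = sqrt(kd1 / kd2))
}

#' Parameters of the methyltransferase (M) promoter model
#'
#' Each studied system represses its M-gene promoter differently:
#' Esp1396I by C-dimer binding (extra parameter `gamma`, the ratio of the DBS
#' dissociation constant to the C-dimer/P.M dissociation constant), AhdI by
#' negative autoregulation of M via its own dimer (extra parameter `alpha_m`,
#' the M dimer-formation parameter), and EcoRV through promoter overlap with
#' the CR promoter (no extra parameter). `phi` is the ratio of maximal M- and
#' CR-promoter expression rates.
#'
#' @param architecture One of `"esp1396i"`, `"ahdi"`, `"ecorv"`.
#' @param phi Maximal P.M-to-P.CR expression-rate ratio (> 0).
#' @param gamma Dimensionless repression strength (Esp1396I only).
#' @param alpha_m M dimer-formation parameter (AhdI only).
#' @return An object of class `rm_pm`.
#' @export
pm_params <- function(architecture = c("esp1396i", "ahdi", "ecorv"),
                      phi = 1, gamma = NULL, alpha_m = NULL) {
  architecture <- match.arg(architecture)
  check_positive(phi, "phi")
  if (architecture == "esp1396i") {
    if (is.null(gamma)) abort("Esp1396I M-promoter model requires `gamma`.")
    check_positive(gamma, "gamma")
  }
  if (architecture == "ahdi") {
    if (is.null(alpha_m)) abort("AhdI M-promoter model requires `alpha_m`.")
    check_positive(alpha_m, "alpha_m")
  }
  structure(list(architecture = architecture, phi = phi,
                 gamma = gamma, alpha_m = alpha_m),
            class = "rm_pm")
}

# Registry of the three experimentally characterised systems. alpha values
# that are known symbolically (5*sqrt(2), 2*sqrt(5)) are stored as the exact
# double-precision expressions, not rounded literals.
rm_preset_registry <- function() {
  list(
    esp1396i = structure(list(
      name = "esp1396i",
      internal = internal_params(p = 25, omega = 130, alpha = 16.9),
      pm = pm_params("esp1396i", phi = 1, gamma = 5.1),
      s_default = 0.2,
      k_rc = 1,
      provenance = "binding/cooperativity constants from published Esp1396I measurements; leakage from steady-state-vs-copy-number fit"
    ), class = "rm_preset"),
    ahdi = structure(list(
      name = "ahdi",
      internal = internal_params(p = 20, omega = 3000, alpha = 5 * sqrt(2)),
      pm = pm_params("ahdi", phi = 0.2, alpha_m = 2 * sqrt(5)),
      s_default = 0.0043,
      k_rc = 1,
      provenance = "binding/cooperativity constants from published AhdI measurements; leakage inferred from activity-vs-C data"
    ), class = "rm_preset"),
    ecorv = structure(list(
      name = "ecorv",
      internal = internal_params(p = 5, omega = 1, alpha = 4.2),
      pm = pm_params("ecorv", phi = 1),
      s_default = NA_real_,
      k_rc = 1,
      provenance = "binding/cooperativity constants from published EcoRV measurements; leakage experimentally unknown"
    ), class = "rm_preset")
  )
}

#' Load a parameter preset for a studied R-M system
#'
#' @param name One of `"esp1396i"`, `"ahdi"`, `"ecorv"`.
#' @return An object of class `rm_preset`: a list with elements `name`,
#'   `internal` ([internal_params()]), `pm` ([pm_params()]), `s_default`
#'   (inferred promoter leakage, `NA` for EcoRV where it is unknown),
#'   `k_rc` (R-to-C proportionality constant, default 1) and `provenance`.
#' @examples
#' rm_preset("esp1396i")$internal
#' @export
rm_preset <- function(name) {
  reg <- rm_preset_registry()
  if (!is.character(name) || length(name) != 1 || !name %in% names(reg)) {
    abort(sprintf("Unknown preset %s. Valid names: %s.",
                  deparse(substitute(name)),
                  paste(names(reg), collapse = ", ")))
  }
  reg[[name]]
}

#' @export
print.rm_preset <- function(x, ...) {
  cat(sprintf("<rm_preset> %s\n", x$name))
  cat(sprintf("  internal: p = %g, omega = %g, alpha = %g\n",
              x$internal$p, x$internal$omega, x$internal$alpha))
  cat(sprintf("  M promoter: %s (phi = %g%s%s)\n", x$pm$architecture, x$pm$phi,
              if (!is.null(x$pm$gamma)) sprintf(", gamma = %g", x$pm$gamma) else "",
              if (!is.null(x$pm$alpha_m)) sprintf(", alpha_m = %g", x$pm$alpha_m) else ""))
  cat(sprintf("  s_default = %s, k_rc = %g\n",
              ifelse(is.na(x$s_default), "unknown", format(x$s_default)), x$k_rc))
  invisible(x)
}

#' Tabulate all registered presets
#'
#' @return A tibble with one row per system and the flattened parameter values.
#' @export
rm_presets <- function() {
  purrr::map_dfr(rm_preset_registry(), function(pr) {
    tibble(
      name = pr$name,
      p = pr$internal$p, omega = pr$internal$omega, alpha = pr$internal$alpha,
      architecture = pr$pm$architecture, phi = pr$pm$phi,
      gamma = pr$pm$gamma %||% NA_real_,
      alpha_m = pr$pm$alpha_m %||% NA_real_,
      s_default = pr$s_default, k_rc = pr$k_rc
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the preset registry as JSON
#'
#' Serialisation keeps full double precision so that presets round-trip
#' bit-identically.
#'
#' @param path File path for the JSON registry.
#' @return `write_rm_presets()` returns `path` invisibly; `read_rm_presets()`
#'   returns a named list of `rm_preset` objects.
#' @export
write_rm_presets <- function(path) {
  reg <- rm_preset_registry()
  plain <- purrr::map(reg, function(pr) {
    list(name = pr$name,
         internal = unclass(pr$internal),
         pm = Filter(Negate(is.null), unclass(pr$pm)),
         s_default = pr$s_default, k_rc = pr$k_rc,
         provenance = pr$provenance)
  })
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_rm_presets
#' @export
read_rm_presets <- function(path) {
  raw <- jsonlite::read_json(path)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  purrr::map(raw, function(pr) {
    structure(list(
      name = pr$name,
      internal = internal_params(num(pr$internal$p), num(pr$internal$omega),
                                 num(pr$internal$alpha)),
      pm = pm_params(pr$pm$architecture, phi = num(pr$pm$phi),
                     gamma = num(pr$pm$gamma), alpha_m = num(pr$pm$alpha_m)),
      s_default = if (is.null(pr$s_default)) NA_real_ else num(pr$s_default),
      k_rc = num(pr$k_rc),
      provenance = pr$provenance
    ), class = "rm_preset")
  })
}
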