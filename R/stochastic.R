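#' Configuration for stochastic single-cell simulations
#'
#' Sets the absolute (molecule-count) parameters of the stochastic model.
#' Only time is rescaled (one cell division per time unit); molecule numbers
#' are kept absolute because fluctuations depend on them. Defaults emulate the
#' Esp1396I system at mid plasmid numbers with R and M of order a few
#' thousand molecules per cell: a dimerisation constant of ~2 uM in a
#' bacterial cell volume (`kd1_n = 1200` molecules), the DBS and M-promoter
#' constants derived from it through the preset's `alpha` and `gamma`
#' (`kd2_n = kd1_n / alpha^2`, `kd_m_n = kd2_n / gamma`), and per-plasmid
#' rates sized so the effective expression strength is ~30.
#'
#' @param mode `"regulated"`, `"constitutive"`, or `"post_segregational"`.
#' @param seed Integer RNG seed (mandatory).
#' @param preset Preset name or [rm_preset()] (Esp1396I architecture).
#' @param n_target Plasmid copy number (default 30).
#' @param n_cells Number of cells / stochastic trajectories (default 2000).
#' @param n_divisions Number of cell divisions (default 10; 7 for the
#'   post-segregational mode).
#' @param s Promoter leakage (defaults to the preset's inferred value).
#' @param phi_m_abs Maximal CR-promoter rate, molecules per plasmid per
#'   division time (default 50).
#' @param phi_M_abs Maximal M-promoter rate, molecules per plasmid per
#'   division time (default 5000).
#' @param k_rc R-to-C production ratio (default 3).
#' @param kd1_n C dimerisation constant in molecules per cell (default 1200).
#' @param cotranscribe If `TRUE`, R molecules are produced in the same events
#'   as C instead of through an independent channel at the proportional rate.
#' @return A list of class `rm_config`.
#' @export
rm_stochastic_config <- function(mode = c("regulated", "constitutive",
                                          "post_segregational"),
                                 seed,
                                 preset = "esp1396i",
                                 n_target = 30, n_cells = 2000,
                                 n_divisions = NULL,
                                 s = NULL,
                                 phi_m_abs = 50, phi_M_abs = 5000,
                                 k_rc = 3, kd1_n = 1200,
                                 cotranscribe = FALSE) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("`seed` is mandatory for stochastic simulation.")
  if (is.character(preset)) preset <- rm_preset(preset)
  if (preset$pm$architecture != "esp1396i") {
    abort("The stochastic model implements the Esp1396I M-promoter architecture.")
  }
  s <- s %||% preset$s_default
  check_nonnegative(s, "s")
  check_positive(n_cells, "n_cells")
  n_divisions <- n_divisions %||% (if (mode == "post_segregational") 7 else 10)
  check_nonnegative(phi_m_abs, "phi_m_abs")
  check_nonnegative(phi_M_abs, "phi_M_abs")
  check_positive(k_rc, "k_rc")
  check_positive(kd1_n, "kd1_n")
  alpha <- preset$internal$alpha
  kd2_n <- kd1_n / alpha^2
  structure(list(
    mode = mode, seed = as.integer(seed), preset = preset,
    n_target = as.integer(n_target), n_cells = as.integer(n_cells),
    n_divisions = as.integer(n_divisions),
    s = s, phi_l_abs = s * phi_m_abs, phi_m_abs = phi_m_abs,
    phi_M_abs = phi_M_abs, k_rc = k_rc,
    kd1_n = kd1_n, kd2_n = kd2_n, kd_m_n = kd2_n / preset$pm$gamma,
    cotranscribe = cotranscribe
  ), class = "rm_config")
}

#' @export
print.rm_config <- function(x, ...) {
  cat(sprintf("<rm_config> %s mode: %d cells, %d divisions, n = %d, seed = %d\n",
              x$mode, x$n_cells, x$n_divisions, x$n_target, x$seed))
  invisible(x)
}

# per-plasmid production rates of the regulated model at C count `C`
regulated_rates <- function(config, C) {
  cf <- 2 * C / (1 + sqrt(1 + 8 * C / config$kd1_n))
  cfr <- cf / sqrt(config$kd1_n * config$kd2_n)
  p <- config$preset$internal$p; omega <- config$preset$internal$omega
  act <- config$phi_l_abs +
    config$phi_m_abs * regulated_activity(cfr, p, omega)
  D <- cf^2 / config$kd1_n
  list(c_rate = act, m_rate = config$phi_M_abs / (1 + D / config$kd_m_n))
}

#' Deterministic division-cycle reference trajectory
#'
#' Integrates the deterministic analogue of the stochastic model: production
#' at the regulated rates within each unit-time cycle, then exact halving of
#' every species (and plasmid number held at `n_target`). Used to calibrate
#' the constitutive mode and to check stochastic equilibration.
#'
#' @param config An [rm_stochastic_config()].
#' @param n_divisions Number of divisions to integrate (default from config).
#' @param converge If `TRUE`, first iterate the cycle map to its periodic
#'   fixed point and return the stationary trajectory instead of the
#'   transient from zero molecules.
#' @return A tibble with columns `division`, `c`, `r_mol`, `m_mol`
#'   (post-division states); attribute `fixed_point` holds the stationary
#'   post-division state and the per-cycle production of each species.
#' @export
rm_deterministic_reference <- function(config, n_divisions = NULL,
                                       converge = FALSE) {
  stopifnot(inherits(config, "rm_config"))
  n_divisions <- n_divisions %||% config$n_divisions
  n <- config$n_target

  cycle <- function(state) {
    sol <- deSolve::ode(
      y = state, times = c(0, 1),
      func = function(t, y, parms) {
        rr <- regulated_rates(config, max(y[["c"]], 0))
        list(c(n * rr$c_rate, config$k_rc * n * rr$c_rate, n * rr$m_rate))
      },
      parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-8)
    sol[2, c("c", "r_mol", "m_mol")]
  }

  state <- c(c = 0, r_mol = 0, m_mol = 0)
  if (converge) {
    for (i in seq_len(200)) {
      pre <- cycle(state)
      new <- pre / 2
      if (max(abs(new - state) / pmax(new, 1e-12)) < 1e-10) {
        state <- new
        break
      }
      state <- new
    }
  }
  start <- state
  rows <- vector("list", n_divisions + 1)
  rows[[1]] <- c(division = 0, state)
  for (d in seq_len(n_divisions)) {
    pre <- cycle(state)
    state <- pre / 2
    rows[[d + 1]] <- c(division = d, state)
  }
  out <- as_tibble(do.call(rbind, rows))
  fp <- state
  structure(out, fixed_point = list(post = fp, production_per_cycle = fp),
            start = start)
}

# constitutive per-plasmid rates matched to the regulated stationary levels:
# per-cycle production at the periodic fixed point equals the post-division
# state, so rate = post-state / n_target
constitutive_rates <- function(config) {
  fp <- attr(rm_deterministic_reference(config, n_divisions = 1,
                                        converge = TRUE), "fixed_point")$post
  list(c_rate_plasmid = fp[["c"]] / config$n_target,
       m_rate_plasmid = fp[["m_mol"]] / config$n_target)
}

#' Stochastic ensemble simulation of single-cell R-M dynamics
#'
#' Simulates `n_cells` independent cells through `n_divisions` deterministic
#' divisions with exact event-driven dynamics between divisions and binomial
#' partitioning of plasmids and molecules at each division (plasmids
#' duplicate before partitioning; one daughter is followed).
#'
#' Modes: `"regulated"` uses the full C-feedback model (C produced at the
#' thermodynamic promoter rate, R at `k_rc` times it, M under C-dimer
#' repression); `"constitutive"` uses constant per-plasmid rates calibrated so
#' the deterministic stationary levels match the regulated model;
#' `"post_segregational"` removes all plasmids at time zero (no production)
#' and requires an `initial` ensemble, typically the equilibrium of a
#' regulated run.
#'
#' @param config An [rm_stochastic_config()].
#' @param initial Optional `rm_ensemble`; its final post-division states seed
#'   the new run (mandatory for the post-segregational mode).
#' @return A tibble of class `rm_ensemble` with columns `cell_id`,
#'   `division`, `phase` (`"post"` = just after division, `"pre"` = just
#'   before), `n`, `c`, `r_mol`, `m_mol`; attribute `config`.
#' @export
rm_simulate <- function(config, initial = NULL) {
  stopifnot(inherits(config, "rm_config"))
  set.seed(config$seed)

  if (!is.null(initial)) {
    stopifnot(inherits(initial, "rm_ensemble"))
    last <- dplyr::filter(initial, .data$phase == "post",
                          .data$division == max(.data$division))
    if (nrow(last) != config$n_cells) {
      last <- last[sample.int(nrow(last), config$n_cells, replace = TRUE), ]
    }
    n0 <- last$n; c0 <- last$c; r0 <- last$r_mol; m0 <- last$m_mol
  } else {
    if (config$mode == "post_segregational") {
      abort("post_segregational mode requires an `initial` ensemble (regulated equilibrium).")
    }
    n0 <- rep(config$n_target, config$n_cells)
    c0 <- r0 <- m0 <- rep(0L, config$n_cells)
  }

  if (config$mode == "regulated") {
    res <- ssa_ensemble_cpp(
      as.integer(n0), as.integer(c0), as.integer(r0), as.integer(m0),
      config$n_divisions,
      config$phi_l_abs, config$phi_m_abs, config$phi_M_abs, config$k_rc,
      config$kd1_n, config$kd2_n, config$kd_m_n,
      config$preset$internal$p, config$preset$internal$omega,
      TRUE, config$cotranscribe)
  } else if (config$mode == "constitutive") {
    rates <- constitutive_rates(config)
    res <- ssa_ensemble_cpp(
      as.integer(n0), as.integer(c0), as.integer(r0), as.integer(m0),
      config$n_divisions,
      rates$c_rate_plasmid, 0, rates$m_rate_plasmid, config$k_rc,
      config$kd1_n, config$kd2_n, config$kd_m_n,
      config$preset$internal$p, config$preset$internal$omega,
      FALSE, config$cotranscribe)
  } else {
    res <- ssa_ensemble_cpp(
      rep(0L, config$n_cells), as.integer(c0), as.integer(r0),
      as.integer(m0), config$n_divisions,
      0, 0, 0, config$k_rc,
      config$kd1_n, config$kd2_n, config$kd_m_n,
      config$preset$internal$p, config$preset$internal$omega,
      FALSE, config$cotranscribe)
  }

  gather <- function(mat, phase) {
    nd <- ncol(mat)
    tibble(cell_id = rep(seq_len(nrow(mat)), nd),
           division = rep(if (phase == "post") 0:(nd - 1) else seq_len(nd),
                          each = nrow(mat)),
           phase = phase,
           value = as.vector(mat))
  }
  assemble <- function(phase) {
    suffix <- if (phase == "post") "_post" else "_pre"
    base <- gather(res[[paste0("n", suffix)]], phase)
    base$n <- base$value
    base$c <- as.vector(res[[paste0("c", suffix)]])
    base$r_mol <- as.vector(res[[paste0("r", suffix)]])
    base$m_mol <- as.vector(res[[paste0("m", suffix)]])
    base$value <- NULL
    base
  }
  out <- dplyr::arrange(dplyr::bind_rows(assemble("post"), assemble("pre")),
                        .data$cell_id, .data$division,
                        dplyr::desc(.data$phase))
  structure(out, class = c("rm_ensemble", class(out)), config = config)
}

robust_cv <- function(x) {
  m <- median(x)
  if (m == 0) return(NA_real_)
  unname(diff(quantile(x, c(0.25, 0.75), type = 7))) / m
}

#' Ensemble summary statistics of the M-to-R ratio
#'
#' Per division (post-division states): median and interquartile range of
#' M/R, the coefficient of variation (sd/mean) and its robust counterpart
#' (IQR/median, quartiles by linear interpolation of order statistics), and
#' the median R count. Trajectories with `r_mol = 0` at a division are
#' excluded from the ratio statistics at that division (and counted); if all
#' trajectories are excluded the statistics are `NA` with `undefined = TRUE`.
#'
#' @param ensemble An `rm_ensemble` (or any data frame with `division`,
#'   `phase`, `r_mol`, `m_mol` columns).
#' @param at_division Optional division index (or vector) to restrict to.
#' @return A tibble with one row per division: `division`, `n_retained`,
#'   `n_excluded`, `median_mr`, `iqr_mr`, `cv_mr`, `robust_cv_mr`,
#'   `median_r`, `undefined`.
#' @export
summarize_ensemble <- function(ensemble, at_division = NULL) {
  df <- dplyr::filter(ensemble, .data$phase == "post")
  if (!is.null(at_division)) {
    df <- dplyr::filter(df, .data$division %in% at_division)
  }
  if (nrow(df) == 0) abort("Empty ensemble selection.")
  df |>
    dplyr::group_by(.data$division) |>
    dplyr::group_modify(function(g, key) {
      keep <- g$r_mol > 0
      med_r <- median(g$r_mol)
      if (!any(keep)) {
        return(tibble(n_retained = 0L, n_excluded = sum(!keep),
                      median_mr = NA_real_, iqr_mr = NA_real_,
                      cv_mr = NA_real_, robust_cv_mr = NA_real_,
                      median_r = med_r, undefined = TRUE))
      }
      mr <- g$m_mol[keep] / g$r_mol[keep]
      tibble(n_retained = sum(keep), n_excluded = sum(!keep),
             median_mr = median(mr),
             iqr_mr = unname(diff(quantile(mr, c(0.25, 0.75), type = 7))),
             cv_mr = sd(mr) / mean(mr),
             robust_cv_mr = robust_cv(mr),
             median_r = med_r, undefined = FALSE)
    }) |>
    dplyr::ungroup()
}

#' Check stochastic equilibration against the deterministic reference
#'
#' Compares ensemble medians of C, R and M at successive post-division states
#' with the deterministic division-cycle trajectory, and checks stationarity
#' (successive medians close to each other) over the final divisions.
#'
#' @param ensemble An `rm_ensemble`, or a reference-shaped tibble (columns
#'   `division`, `c`, `r_mol`, `m_mol`) to compare directly.
#' @param reference Output of [rm_deterministic_reference()] (or any tibble
#'   with `division`, `c`, `r_mol`, `m_mol`).
#' @param tol Relative tolerance (default 0.2).
#' @param last Number of final divisions to check (default 3).
#' @return A list with `ok` (logical) and `report` (per-division tibble of
#'   medians, reference values and relative deviations).
#' @export
equilibrium_check <- function(ensemble, reference, tol = 0.2, last = 3) {
  meds <- if ("phase" %in% names(ensemble)) {
    ensemble |>
      dplyr::filter(.data$phase == "post") |>
      dplyr::group_by(.data$division) |>
      dplyr::summarise(c = median(.data$c), r_mol = median(.data$r_mol),
                       m_mol = median(.data$m_mol), .groups = "drop")
  } else {
    dplyr::select(as_tibble(ensemble), "division", "c", "r_mol", "m_mol")
  }
  joint <- dplyr::inner_join(meds, as_tibble(reference), by = "division",
                             suffix = c("", "_ref"))
  if (nrow(joint) == 0) abort("Ensemble and reference share no divisions.")
  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
  report <- dplyr::mutate(
    joint,
    dev_c = rel(.data$c, .data$c_ref),
    dev_r = rel(.data$r_mol, .data$r_mol_ref),
    dev_m = rel(.data$m_mol, .data$m_mol_ref))
  tail_rows <- dplyr::slice_tail(report, n = last)
  close_ref <- all(tail_rows$dev_c <= tol & tail_rows$dev_r <= tol &
                     tail_rows$dev_m <= tol)
  stationary <- all(
    abs(diff(tail_rows$r_mol)) / pmax(tail_rows$r_mol[-1], 1e-12) <= tol,
    abs(diff(tail_rows$m_mol)) / pmax(tail_rows$m_mol[-1], 1e-12) <= tol,
    abs(diff(tail_rows$c)) / pmax(tail_rows$c[-1], 1e-12) <= tol)
  list(ok = close_ref && stationary, report = report)
}
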