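#' Deterministic rescaled C trajectory
#'
#' Integrates the rescaled total-C dynamics from `c0` with an adaptive
#' stiff-capable scheme (lsoda, rtol 1e-8, atol 1e-10).
#'
#' @param times Output times (rescaled), strictly increasing, >= 0.
#' @param s,r External parameters.
#' @param internal Internal parameters or a preset.
#' @param c0 Initial total C (default 0: establishment in a naive host).
#' @return A tibble with columns `time` and `c_total`.
#' @export
c_trajectory <- function(times, s, r, internal, c0 = 0) {
  internal <- as_internal_params(internal)
  check_nonnegative(times, "times")
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  tt <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::ode(
    y = c(ct = c0), times = tt,
    func = function(t, y, parms) {
      list(c_dynamics_rhs(max(y[1], 0), s, r, internal))
    },
    parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-10
  )
  ct <- sol[, "ct"]
  if (times[1] > 0) ct <- ct[-1]
  tibble(time = times, c_total = ct)
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl) # unit mean, CV = cv
}

#' Synthetic calibration datasets
#'
#' Forward-simulates one of the three calibration data kinds from known
#' ("truth") parameters and applies multiplicative unit-mean log-normal noise
#' with coefficient of variation `noise_level`. Deterministic given `seed`.
#'
#' Kinds and their truth fields (all have defaults reflecting the studied
#' systems):
#' \describe{
#'   \item{`"activity"`}{CR-promoter activity versus total C. Truth: `internal`
#'     (default AhdI), `s` (default 0.0043), `scale` (overall activity scale,
#'     default 1), `c_total` grid (default `n_points` log-spaced on
#'     `[1e-3, 10]`). Columns: `c_total`, `activity`.}
#'   \item{`"timeseries"`}{Endonuclease amount versus time during system
#'     establishment. Truth: `internal` (default Esp1396I), `s` (default
#'     0.21), `r` (default 10), `amplitude`, `time_scale` (defaults 1),
#'     `n_points` (default 100) times on `(0, 3r]`. Columns: `time`,
#'     `r_amount`; attribute `metadata` carries `r` and the internal
#'     parameters.}
#'   \item{`"steady_vs_n"`}{Steady-state R and M levels versus plasmid copy
#'     number. Truth: `preset` (default Esp1396I), `s` (default 0.2),
#'     `n_scale` (r per plasmid, default 1), `a_r`, `a_m` (level scales,
#'     default 1), `n` grid (default 6 values on `[5, 60]`). Columns: `n`,
#'     `r_level`, `m_level`.}
#' }
#'
#' @param kind One of `"activity"`, `"timeseries"`, `"steady_vs_n"`.
#' @param truth Named list overriding the defaults above.
#' @param noise_level Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param n_points Number of records (kind-specific default).
#' @param seed Integer RNG seed (required).
#' @return A tibble (see kinds above) with attribute `truth`.
#' @export
rm_fixture <- function(kind = c("activity", "timeseries", "steady_vs_n"),
                       truth = list(), noise_level = 0, n_points = NULL,
                       seed) {
  kind <- match.arg(kind)
  check_nonnegative(noise_level, "noise_level")
  if (missing(seed)) abort("`seed` is required for fixture generation.")
  set.seed(seed)

  if (kind == "activity") {
    n_points <- n_points %||% 20
    tr <- utils::modifyList(
      list(internal = rm_preset("ahdi")$internal, s = 0.0043, scale = 1,
           c_total = exp(seq(log(1e-3), log(10), length.out = n_points))),
      truth)
    cf <- free_monomer(tr$c_total, as_internal_params(tr$internal)$alpha)
    y <- tr$scale * pcr_activity(cf, tr$s, as_internal_params(tr$internal)$p,
                                 as_internal_params(tr$internal)$omega)
    out <- tibble(c_total = tr$c_total,
                  activity = y * lognormal_noise(length(y), noise_level))
  } else if (kind == "timeseries") {
    n_points <- n_points %||% 100
    tr <- utils::modifyList(
      list(internal = rm_preset("esp1396i")$internal, s = 0.21, r = 10,
           amplitude = 1, time_scale = 1),
      truth)
    t_max <- 3 * tr$r
    times <- seq(t_max / 50, t_max, length.out = n_points)
    traj <- c_trajectory(times / tr$time_scale, tr$s, tr$r, tr$internal)
    y <- tr$amplitude * traj$c_total
    out <- tibble(time = times,
                  r_amount = y * lognormal_noise(length(y), noise_level))
    attr(out, "metadata") <- list(r = tr$r,
                                  internal = as_internal_params(tr$internal))
  } else {
    tr <- utils::modifyList(
      list(preset = rm_preset("esp1396i"), s = 0.2, n_scale = 1,
           a_r = 1, a_m = 1,
           n = round(seq(5, 60, length.out = n_points %||% 6))),
      truth)
    pred <- steady_levels(tr$preset, tr$s, tr$n * tr$n_scale)
    out <- tibble(
      n = tr$n,
      r_level = tr$a_r * pred$r_level *
        lognormal_noise(length(tr$n), noise_level),
      m_level = tr$a_m * pred$m_level *
        lognormal_noise(length(tr$n), noise_level))
  }
  attr(out, "truth") <- truth
  attr(out, "kind") <- kind
  out
}

# stable-branch (establishment-path) steady levels of R and M versus r;
# from C = 0 the system settles on the lowest stable state
steady_levels <- function(preset, s, r_values, n_grid = 600) {
  purrr::map_dfr(r_values, function(r) {
    st <- steady_states(s, r, preset$internal, n_grid = n_grid)
    st <- st[st$stability == "stable", ]
    ct <- st$c_total[1]
    cf <- st$c_free[1]
    tibble(r = r, c_total = ct,
           r_level = r_total(ct, preset$k_rc),
           m_level = m_total_for(preset, cf, r),
           bistable = nrow(st) > 1)
  })
}

new_rm_fit <- function(method, estimates, residual_norm, converged, bounds,
                       n_obs, extra = list()) {
  structure(c(list(method = method, estimates = estimates,
                   residual_norm = residual_norm, converged = converged,
                   bounds = bounds, n_obs = n_obs), extra),
            class = "rm_fit")
}

#' @export
print.rm_fit <- function(x, ...) {
  cat(sprintf("<rm_fit> %s fit, %d observations, residual norm %.4g\n",
              x$method, x$n_obs, x$residual_norm))
  print(x$estimates)
  invisible(x)
}

#' Infer promoter leakage from an activity-versus-C dataset
#'
#' Least-squares fit of `activity = scale * (s + f(c_free))` over the overall
#' scale and the leakage `s`, with `s` bounded in `[0, 1]` (leakage cannot
#' exceed maximal activity). When the dataset is in total-C units the free
#' monomer is obtained through the monomer-dimer equilibrium. The model is
#' linear in `(scale, scale*s)`, so the unconstrained solution is closed-form;
#' if it violates the bounds the fit falls back to a profiled 1-D search on
#' `s`.
#'
#' @param data A data frame with column `activity` and one of `c_total` or
#'   `c_free`; optional column `weight`.
#' @param internal Internal parameters or a preset (held fixed).
#' @return An `rm_fit` with terms `s` and `scale`.
#' @export
fit_s_from_activity <- function(data, internal) {
  internal <- as_internal_params(internal)
  if (!"activity" %in% names(data)) abort("`data` must have an `activity` column.")
  if (nrow(data) < 4) abort("Underdetermined: need at least 4 activity records.")
  if (any(data$activity < 0)) abort("Activities must be non-negative.")
  cf <- if ("c_free" %in% names(data)) {
    data$c_free
  } else if ("c_total" %in% names(data)) {
    free_monomer(data$c_total, internal$alpha)
  } else {
    abort("`data` must have a `c_total` or `c_free` column.")
  }
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  y <- data$activity
  f <- regulated_activity(cf, internal$p, internal$omega)

  # y ~ a*f + b with a = scale, b = scale*s
  X <- cbind(f = f, one = 1)
  coef <- solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), y * sqrt(w)))
  a <- coef[1]; b <- coef[2]
  s_hat <- b / a
  if (!is.finite(s_hat) || a <= 0 || s_hat < 0 || s_hat > 1) {
    prof <- function(s) {
      m <- s + f
      a <- sum(w * y * m) / sum(w * m^2)
      sum(w * (y - a * m)^2)
    }
    opt <- optimize(prof, c(0, 1), tol = 1e-10)
    s_hat <- opt$minimum
    m <- s_hat + f
    a <- sum(w * y * m) / sum(w * m^2)
  }
  resid <- y - a * (s_hat + f)
  new_rm_fit(
    method = "activity",
    estimates = tibble(term = c("s", "scale"),
                       estimate = c(s_hat, a)),
    residual_norm = sqrt(sum(w * resid^2)),
    converged = TRUE,
    bounds = list(s = c(0, 1)),
    n_obs = nrow(data)
  )
}

#' Infer promoter leakage from an establishment time series
#'
#' Fits the deterministic establishment dynamics (integrated from zero total
#' C, with the full monomer-dimer equilibrium) to a measured R-versus-time
#' series, estimating the leakage `s`, an amplitude scale, and a time scale.
#' The residual is least squares on the log scale, the exact maximum
#' likelihood under the multiplicative log-normal noise that dominates such
#' reporter data; amplitude and time scale are profiled out for each `s`
#' (one spline-interpolated trajectory solve per `s` evaluation), and `s` is
#' located by a coarse log-grid search refined by golden-section.
#'
#' @param data A data frame with columns `time` and `r_amount`; metadata
#'   attribute (as produced by [rm_fixture()]) or the `r` argument supplies
#'   the expression strength.
#' @param internal Internal parameters or a preset.
#' @param r Expression strength during the experiment (defaults to the
#'   dataset metadata).
#' @param s_bounds Search bounds for the leakage.
#' @param ts_halfwidth Half-width of the log time-scale search interval.
#' @return An `rm_fit` with terms `s`, `amplitude`, `time_scale`.
#' @export
fit_s_from_dynamics <- function(data, internal, r = NULL,
                                s_bounds = c(1e-3, 1), ts_halfwidth = 1.5) {
  internal <- as_internal_params(internal)
  if (!all(c("time", "r_amount") %in% names(data))) {
    abort("`data` must have `time` and `r_amount` columns.")
  }
  if (is.null(r)) r <- attr(data, "metadata")$r
  if (is.null(r)) abort("Supply `r` (expression strength) or dataset metadata.")
  keep <- data$r_amount > 0 & data$time > 0
  if (sum(keep) < 6) abort("Underdetermined: need at least 6 positive records.")
  tt <- data$time[keep]
  ly <- log(data$r_amount[keep])
  if (is.unsorted(tt, strictly = TRUE)) abort("Times must be strictly increasing.")

  t_top <- max(tt) * exp(ts_halfwidth)
  obj_s <- function(ls) {
    s <- exp(ls)
    fine <- seq(0, t_top, length.out = 1000)
    traj <- c_trajectory(fine[-1], s, r, internal)
    fun <- splinefun(c(0, fine[-1]), c(0, traj$c_total), method = "monoH.FC")
    inner <- function(lts) {
      lm_ <- log(pmax(fun(tt / exp(lts)), 1e-300))
      a <- mean(ly - lm_)
      sum((ly - lm_ - a)^2)
    }
    optimize(inner, c(-ts_halfwidth, ts_halfwidth), tol = 1e-10)
  }
  sg <- seq(log(s_bounds[1]), log(s_bounds[2]), length.out = 25)
  vals <- vapply(sg, function(ls) obj_s(ls)$objective, numeric(1))
  i <- which.min(vals)
  lo <- sg[max(1, i - 1)]; hi <- sg[min(length(sg), i + 1)]
  ref <- optimize(function(ls) obj_s(ls)$objective, c(lo, hi), tol = 1e-9)
  ls_hat <- ref$minimum
  inner_fit <- obj_s(ls_hat)
  lts_hat <- inner_fit$minimum
  # recover profiled amplitude
  fine <- seq(0, t_top, length.out = 1000)
  traj <- c_trajectory(fine[-1], exp(ls_hat), r, internal)
  fun <- splinefun(c(0, fine[-1]), c(0, traj$c_total), method = "monoH.FC")
  lm_ <- log(pmax(fun(tt / exp(lts_hat)), 1e-300))
  a <- exp(mean(ly - lm_))
  new_rm_fit(
    method = "dynamics",
    estimates = tibble(term = c("s", "amplitude", "time_scale"),
                       estimate = c(exp(ls_hat), a, exp(lts_hat))),
    residual_norm = sqrt(ref$objective),
    converged = is.finite(ref$objective),
    bounds = list(s = s_bounds,
                  time_scale = exp(c(-1, 1) * ts_halfwidth)),
    n_obs = sum(keep),
    extra = list(r = r)
  )
}

#' Infer leakage and scales from steady-state-versus-copy-number data
#'
#' Fits stable-branch steady-state predictions of R and M levels against
#' measurements at several plasmid copy numbers. Free parameters: the leakage
#' `s` (log-grid search over `[0.001, 1]` with golden-section refinement), a
#' common copy-number-to-`r` scale `n_scale` (1-D local optimisation per `s`),
#' and two level scales `a_r`, `a_m` (profiled in closed form). The stable
#' branch is the establishment path: the lowest stable steady state. The fit
#' reports whether the best leakage puts the measured copy-number range in
#' the mono- or bistable regime.
#'
#' @param data A data frame with columns `n`, `r_level`, `m_level` (>= 3
#'   distinct copy-number conditions).
#' @param preset An [rm_preset()].
#' @param s_grid_size Number of leakage grid points.
#' @return An `rm_fit` with terms `s`, `n_scale`, `a_r`, `a_m`; element
#'   `regime` is `"monostable"` or `"bistable"` over the fitted data range.
#' @export
fit_steady_state_scales <- function(data, preset, s_grid_size = 30) {
  if (!all(c("n", "r_level", "m_level") %in% names(data))) {
    abort("`data` must have `n`, `r_level`, `m_level` columns.")
  }
  if (length(unique(data$n)) < 3) {
    abort("Underdetermined: need at least 3 distinct copy-number conditions.")
  }
  nn <- data$n; yR <- data$r_level; yM <- data$m_level
  ln_scale_bounds <- log(c(0.05, 500) / stats::median(nn))

  ssr_at <- function(s, n_scale) {
    pred <- steady_levels(preset, s, n_scale * nn, n_grid = 500)
    a_r <- sum(yR * pred$r_level) / sum(pred$r_level^2)
    a_m <- sum(yM * pred$m_level) / sum(pred$m_level^2)
    list(ssr = sum((yR - a_r * pred$r_level)^2) +
           sum((yM - a_m * pred$m_level)^2),
         a_r = a_r, a_m = a_m, bistable = any(pred$bistable))
  }
  best_for_s <- function(s) {
    opt <- optimize(function(lns) ssr_at(s, exp(lns))$ssr,
                    ln_scale_bounds, tol = 1e-6)
    c(ssr = opt$objective, lns = opt$minimum)
  }
  sg <- exp(seq(log(0.001), log(1), length.out = s_grid_size))
  grid <- vapply(sg, best_for_s, numeric(2))
  i <- which.min(grid["ssr", ])
  lo <- log(sg[max(1, i - 1)]); hi <- log(sg[min(length(sg), i + 1)])
  ref <- optimize(function(ls) best_for_s(exp(ls))["ssr"], c(lo, hi),
                  tol = 1e-7)
  s_hat <- exp(ref$minimum)
  lns_hat <- best_for_s(s_hat)["lns"]
  final <- ssr_at(s_hat, exp(lns_hat))
  new_rm_fit(
    method = "steady_vs_n",
    estimates = tibble(
      term = c("s", "n_scale", "a_r", "a_m"),
      estimate = unname(c(s_hat, exp(lns_hat), final$a_r, final$a_m))),
    residual_norm = sqrt(final$ssr),
    converged = TRUE,
    bounds = list(s = c(0.001, 1), n_scale = exp(ln_scale_bounds)),
    n_obs = nrow(data),
    extra = list(regime = if (final$bistable) "bistable" else "monostable",
                 branch = "low")
  )
}
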