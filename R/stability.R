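#' Steady states of the rescaled C dynamics
#'
#' Finds all roots of [c_dynamics_rhs()] in `[0, r*(s+1)]` (the activity bound
#' guarantees every root lies in that interval), and classifies each by the
#' sign of the analytic derivative of the right-hand side: negative slope is
#' stable, positive unstable. Roots are bracketed by sign changes over a dense
#' log-spaced grid and refined by bisection ([stats::uniroot()]) to 1e-12
#' absolute; roots closer than 1e-8 relative are merged.
#'
#' @param s Promoter leakage (>= 0).
#' @param r Overall expression strength (> 0).
#' @param internal Internal parameters ([internal_params()] or a preset).
#' @param n_grid Number of bracketing grid points (default 2000).
#' @return A tibble of class `rm_steady` with columns `c_total`, `c_free`,
#'   `stability` (`"stable"`/`"unstable"`), sorted ascending in `c_total`.
#'   Attribute `degenerate` is `TRUE` when the root count is not 1 or 3 after
#'   merging (possible exactly at a fold point); this is flagged, never an
#'   error.
#' @examples
#' steady_states(s = 0.02, r = 3.3, internal = rm_preset("esp1396i"))
#' @export
steady_states <- function(s, r, internal, n_grid = 2000) {
  internal <- as_internal_params(internal)
  check_nonnegative(s, "s")
  check_positive(r, "r")
  ub <- r * (s + 1)
  x <- c(0, exp(seq(log(ub * 1e-9), log(ub), length.out = n_grid)))
  y <- c_dynamics_rhs(x, s, r, internal)

  roots <- numeric(0)
  if (s == 0) roots <- 0 # rhs(0) = s, an exact root when leakage vanishes
  hit <- which(y[-1] == 0)
  if (length(hit)) roots <- c(roots, x[hit + 1])
  sgn <- sign(y)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flip) {
    rt <- uniroot(function(ct) c_dynamics_rhs(ct, s, r, internal),
                  lower = x[i], upper = x[i + 1], tol = 1e-12)$root
    roots <- c(roots, rt)
  }
  roots <- sort(unique(roots))
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) / pmax(roots[-1], 1e-300) > 1e-8)
    roots <- roots[keep]
  }
  deriv <- c_dynamics_rhs_deriv(roots, s, r, internal)
  stab <- ifelse(deriv < 0, "stable", "unstable")
  degenerate <- !(length(roots) %in% c(1L, 3L)) || any(deriv == 0)
  out <- tibble(c_total = roots,
                c_free = free_monomer(roots, internal$alpha),
                stability = stab)
  structure(out, class = c("rm_steady", class(out)),
            degenerate = degenerate, s = s, r = r)
}

#' Parametric fold (saddle-node) boundary in the leakage/strength plane
#'
#' At a fold point both the rescaled right-hand side and its derivative with
#' respect to total C vanish. Solving the two conditions in closed form for
#' the external parameters, with total C as the curve parameter, gives
#' `r = 1 / (f'(c_free) * dc_free/dc_total)` and then
#' `s = c_total / r - f(c_free)`. The admissible range is
#' `c_free < (p/omega)^(1/4)`, where `f' > 0` so `r > 0`; `r` diverges at both
#' ends of the range, so the curve parameter is log-spaced to resolve the cusp
#' (the interior maximum of `s`, the tip of the bistable wedge).
#'
#' @param internal Internal parameters or a preset.
#' @param grid_size Number of curve points (>= 100, default 2000).
#' @param cf_min Lower end of the free-monomer parameter grid.
#' @return A tibble of class `rm_boundary` with columns `c_total`, `c_free`,
#'   `r`, `s`, `fold` (`"lower"`/`"upper"` for the branch below/above the cusp
#'   in total C) and `is_cusp`. Attributes: `cusp` (list with `r`, `s`,
#'   `c_total`), `s_max` (maximum leakage admitting bistability) and
#'   `internal`.
#' @examples
#' b <- stability_boundary(rm_preset("esp1396i"))
#' attr(b, "s_max")
#' @export
stability_boundary <- function(internal, grid_size = 2000, cf_min = 1e-8) {
  internal <- as_internal_params(internal)
  if (grid_size < 100) abort("`grid_size` must be at least 100.")
  p <- internal$p; omega <- internal$omega; alpha <- internal$alpha
  cf_max <- (p / omega)^0.25 * 0.999999
  cf <- exp(seq(log(cf_min), log(cf_max), length.out = grid_size))
  ct <- cf + 2 * cf^2 / alpha
  r <- 1 / (regulated_activity_deriv(cf, p, omega) *
              free_monomer_deriv(ct, alpha))
  s <- ct / r - regulated_activity(cf, p, omega)
  i_cusp <- which.max(s)
  out <- tibble(c_total = ct, c_free = cf, r = r, s = s,
                fold = ifelse(seq_along(ct) <= i_cusp, "lower", "upper"),
                is_cusp = seq_along(ct) == i_cusp)
  structure(out, class = c("rm_boundary", class(out)),
            cusp = list(r = r[i_cusp], s = s[i_cusp], c_total = ct[i_cusp]),
            s_max = s[i_cusp],
            internal = internal)
}

# interpolate r(s) along one fold branch; s is monotone along each branch
# but may run in either direction
interp_branch <- function(s_vals, r_vals, xout, rule = 1) {
  ord <- order(s_vals)
  approx(s_vals[ord], r_vals[ord], xout = xout, rule = rule,
         ties = "ordered")$y
}

#' Bistable interval of expression strength at fixed leakage
#'
#' Intersects the two fold branches of a [stability_boundary()] with the
#' horizontal line at leakage `s`. Inside the returned interval the system has
#' three steady states; outside, one.
#'
#' @param boundary An `rm_boundary` object.
#' @param s Leakage value.
#' @return Numeric `c(r_low, r_high)`, or `NULL` when `s` exceeds the cusp
#'   leakage (no bistability).
#' @export
fold_interval <- function(boundary, s) {
  stopifnot(inherits(boundary, "rm_boundary"))
  if (s > attr(boundary, "s_max") || s < 0) return(NULL)
  lower <- boundary[boundary$fold == "lower" | boundary$is_cusp, ]
  upper <- boundary[boundary$fold == "upper" | boundary$is_cusp, ]
  if (s < min(lower$s) || s < min(upper$s)) return(NULL)
  # the lower-C branch carries the larger fold r; the upper-C branch the smaller
  r_high <- interp_branch(lower$s, lower$r, s)
  r_low <- interp_branch(upper$s, upper$r, s)
  if (anyNA(c(r_low, r_high))) return(NULL)
  sort(c(r_low, r_high))
}

#' Bifurcation diagram: steady-state branches versus expression strength
#'
#' For each value of `r` on the grid, computes all steady states at fixed
#' leakage `s` and labels branches: with three roots the lowest and highest
#' are the stable low/high branches and the middle root is unstable; a single
#' root below (above) the fold interval continues the low (high) branch, and
#' in a system with no fold interval the unique branch is labelled
#' `"stable"`.
#'
#' @param internal Internal parameters or a preset.
#' @param s Fixed promoter leakage.
#' @param r_grid Positive, sorted grid of expression strengths.
#' @param boundary Optional precomputed [stability_boundary()] (recomputed
#'   otherwise).
#' @return A tibble of class `rm_bifurcation` with columns `r`, `c_total`,
#'   `c_free`, `stability`, `branch`; attribute `fold_interval` (numeric
#'   `c(r_low, r_high)` or `NULL`) and `s`.
#' @export
bifurcation_diagram <- function(internal, s, r_grid, boundary = NULL) {
  internal <- as_internal_params(internal)
  check_positive(r_grid, "r_grid")
  if (is.unsorted(r_grid)) abort("`r_grid` must be sorted ascending.")
  if (is.null(boundary)) boundary <- stability_boundary(internal)
  fi <- fold_interval(boundary, s)

  rows <- purrr::map_dfr(r_grid, function(r) {
    st <- steady_states(s, r, internal)
    k <- nrow(st)
    branch <- if (k == 3) {
      c("low", "unstable", "high")
    } else if (is.null(fi)) {
      rep("stable", k)
    } else {
      rep(if (r < mean(fi)) "low" else "high", k)
    }
    tibble(r = r, c_total = st$c_total, c_free = st$c_free,
           stability = st$stability, branch = branch)
  })
  structure(rows, class = c("rm_bifurcation", class(rows)),
            fold_interval = fi, s = s, internal = internal)
}

#' Cusp catastrophe surface of the steady states
#'
#' Total-C steady-state sheets over the leakage/strength plane: the lower
#' stable sheet, the upper stable sheet, and the in-between unstable sheet
#' that connects them inside the bistable wedge. Monostable cells carry
#' exactly one sheet.
#'
#' @param internal Internal parameters or a preset.
#' @param r_grid,s_grid Positive axis grids.
#' @return A tibble of class `rm_cusp` with columns `r`, `s`, `c_total`,
#'   `c_free`, `sheet` (`"lower"`, `"unstable"`, `"upper"`); attribute
#'   `boundary` (the [stability_boundary()] used).
#' @export
cusp_surface <- function(internal, r_grid, s_grid) {
  internal <- as_internal_params(internal)
  check_positive(r_grid, "r_grid")
  check_nonnegative(s_grid, "s_grid")
  boundary <- stability_boundary(internal)
  rows <- purrr::map_dfr(s_grid, function(s) {
    bd <- bifurcation_diagram(internal, s, r_grid, boundary = boundary)
    sheet <- dplyr::case_when(
      bd$stability == "unstable" ~ "unstable",
      bd$branch == "high" ~ "upper",
      bd$branch == "low" ~ "lower",
      TRUE ~ "lower"
    )
    tibble(r = bd$r, s = s, c_total = bd$c_total, c_free = bd$c_free,
           sheet = sheet)
  })
  structure(rows, class = c("rm_cusp", class(rows)), boundary = boundary)
}

#' Area of the bistable wedge within a plotting window
#'
#' Integrates the width of the bistable region between the two fold curves
#' over leakage, clipping at `r_max` (the wedge is unbounded in `r` as the
#' leakage goes to zero) and at leakage 1. Used to compare how internal
#' parameters expand or shrink the bistable region.
#'
#' @param internal Internal parameters or a preset.
#' @param r_max Right edge of the window in `r`.
#' @param grid_size Resolution of the boundary curve and of the leakage
#'   integration grid.
#' @return The window-clipped area (dimensionless). Zero, with a warning, when
#'   `r_max` does not reach the cusp.
#' @export
bistable_region_area <- function(internal, r_max, grid_size = 4000) {
  internal <- as_internal_params(internal)
  check_positive(r_max, "r_max")
  b <- stability_boundary(internal, grid_size = grid_size)
  cusp <- attr(b, "cusp")
  if (r_max <= cusp$r) {
    warning("`r_max` does not reach the cusp; bistable area in window is zero.")
    return(0)
  }
  s_top <- min(attr(b, "s_max"), 1)
  sg <- seq(0, s_top, length.out = grid_size)
  lower <- b[b$fold == "lower" | b$is_cusp, ]
  upper <- b[b$fold == "upper" | b$is_cusp, ]
  r_outer <- interp_branch(lower$s, lower$r, sg, rule = 2)
  r_inner <- interp_branch(upper$s, upper$r, sg, rule = 2)
  width <- pmax(0, pmin(r_outer, r_max) - pmin(r_inner, r_max))
  sum((width[-1] + width[-length(width)]) / 2 * diff(sg))
}
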