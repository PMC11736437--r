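esp <- rm_preset("esp1396i")
ahdi <- rm_preset("ahdi")
eco <- rm_preset("ecorv")

test_that("steady-state finder matches the dense-grid sign-change oracle", {
  # zero leakage keeps the origin as a fixed point
  st0 <- steady_states(s = 0, r = 2, esp)
  expect_equal(min(st0$c_total), 0)

  b <- stability_boundary(esp)
  fi <- fold_interval(b, 0.02)
  st <- steady_states(s = 0.02, r = log_mid(fi), esp)
  expect_equal(nrow(st), 3)
  expect_equal(st$stability, c("stable", "unstable", "stable"))
  expect_false(attr(st, "degenerate"))
  expect_equal(dense_grid_root_count(0.02, log_mid(fi), esp$internal), 3)
  # roots sorted, all inside the trapping interval
  expect_true(all(diff(st$c_total) > 0))
  expect_true(all(st$c_total <= log_mid(fi) * 1.02))

  # monostable leakage: single root for every r on a log grid
  rg <- exp(seq(log(1e-2), log(1e3), length.out = 60))
  counts <- vapply(rg, function(r) nrow(steady_states(0.08, r, esp)),
                   integer(1))
  expect_true(all(counts == 1L))
})

test_that("fold boundary points satisfy both saddle-node conditions", {
  b <- stability_boundary(esp, grid_size = 500)
  ok <- b$s >= 0 # physically admissible portion
  resid <- abs(c_dynamics_rhs(b$c_total[ok], b$s[ok], b$r[ok], esp))
  expect_lt(max(resid), 1e-10)
  # slope vanishes at the fold: central difference on the rhs
  slope <- vapply(which(ok), function(i) {
    num_deriv(function(ct) c_dynamics_rhs(ct, b$s[i], b$r[i], esp),
              b$c_total[i], h = 1e-6 * b$c_total[i])
  }, numeric(1))
  expect_lt(max(abs(slope)), 1e-6)
  expect_true(all(b$r > 0))
})

test_that("cusp is the unique interior maximum of the boundary leakage", {
  b <- stability_boundary(esp)
  s_max <- attr(b, "s_max")
  expect_gt(s_max, 0.04)
  expect_lt(s_max, 0.06)
  i <- which(b$is_cusp)
  expect_true(all(diff(b$s[1:i]) > 0))
  expect_true(all(diff(b$s[i:nrow(b)]) < 0))
  expect_equal(attr(b, "cusp")$s, s_max)
})

test_that("parametric boundary classification matches brute-force root counts", {
  set.seed(91)
  internals <- c(
    list(esp$internal),
    replicate(3, internal_params(p = rlnorm(1, 2.5, 0.5),
                                 omega = rlnorm(1, 3, 1),
                                 alpha = rlnorm(1, 1.5, 0.5)),
              simplify = FALSE))
  for (internal in internals) {
    b <- stability_boundary(internal)
    s_max <- attr(b, "s_max")
    rg <- exp(seq(log(0.5), log(50), length.out = 25))
    sg <- exp(seq(log(s_max / 20), log(min(2 * s_max, 1)), length.out = 25))
    predicted <- outer(sg, rg, Vectorize(function(s, r) {
      fi <- fold_interval(b, s)
      !is.null(fi) && r > fi[1] && r < fi[2]
    }))
    observed <- outer(sg, rg, Vectorize(function(s, r) {
      nrow(steady_states(s, r, internal, n_grid = 800)) == 3
    }))
    mismatch <- which(predicted != observed, arr.ind = TRUE)
    # any disagreement must sit against the curve: a neighbouring cell in the
    # same row or column has the opposite predicted class
    for (k in seq_len(nrow(mismatch))) {
      i <- mismatch[k, 1]; j <- mismatch[k, 2]
      nb <- c(
        if (i > 1) predicted[i - 1, j], if (i < 25) predicted[i + 1, j],
        if (j > 1) predicted[i, j - 1], if (j < 25) predicted[i, j + 1])
      expect_true(any(nb != predicted[i, j]))
    }
    expect_lt(nrow(mismatch) / length(predicted), 0.05)
  }
})

test_that("bifurcation diagrams reflect the fold structure", {
  rg <- exp(seq(log(1), log(20), length.out = 80))
  bd <- bifurcation_diagram(esp$internal, s = 0.02, rg)
  fi <- attr(bd, "fold_interval")
  expect_false(is.null(fi))
  inside <- dplyr::count(dplyr::filter(bd, r > fi[1], r < fi[2]), r)
  expect_true(all(inside$n == 3))
  outside <- dplyr::count(dplyr::filter(bd, r < fi[1] | r > fi[2]), r)
  expect_true(all(outside$n == 1))

  bd8 <- bifurcation_diagram(esp$internal, s = 0.08, rg)
  expect_null(attr(bd8, "fold_interval"))
  # any leakage above the cusp value: no fold interval by definition
  b <- stability_boundary(esp)
  expect_null(fold_interval(b, attr(b, "s_max") * 1.01))
})

test_that("hysteresis: stable branches are monotone and jumps sit at the folds", {
  rg <- exp(seq(log(1.5), log(8), length.out = 300))
  bd <- bifurcation_diagram(esp$internal, s = 0.02, rg)
  fi <- attr(bd, "fold_interval")
  high <- dplyr::filter(bd, branch == "high", stability == "stable")
  expect_true(all(diff(high$c_total) > 0))
  # state-following sweep up: the low branch disappears at the upper fold
  low <- dplyr::filter(bd, branch == "low", stability == "stable")
  r_jump_up <- max(low$r)
  expect_lt(abs(log(r_jump_up / fi[2])), log(rg[2] / rg[1]) * 1.5)
  # sweep down: the high branch disappears at the lower fold
  r_jump_down <- min(high$r)
  expect_lt(abs(log(r_jump_down / fi[1])), log(rg[2] / rg[1]) * 1.5)
})

test_that("cusp surface sheets tile the bistable wedge", {
  rg <- exp(seq(log(2), log(30), length.out = 25))
  sg <- c(0.002, 0.006, 0.02)
  surf <- cusp_surface(ahdi$internal, rg, sg)
  b <- attr(surf, "boundary")
  cells <- dplyr::count(surf, r, s)
  for (k in seq_len(nrow(cells))) {
    fi <- fold_interval(b, cells$s[k])
    inside <- !is.null(fi) && cells$r[k] > fi[1] && cells$r[k] < fi[2]
    expect_equal(cells$n[k], if (inside) 3L else 1L)
  }
  # three sheets exactly inside the wedge; slices agree with the diagram
  bd <- bifurcation_diagram(ahdi$internal, s = 0.002, rg)
  slice <- dplyr::filter(surf, s == 0.002)
  expect_equal(sort(slice$c_total), sort(bd$c_total), tolerance = 1e-8)
})

test_that("bistable area ordering and parameter trends match the wedge geometry", {
  r_max <- 100
  a_eco <- bistable_region_area(eco, r_max)
  a_esp <- bistable_region_area(esp, r_max)
  a_ahdi <- bistable_region_area(ahdi, r_max)
  expect_gt(a_eco, a_esp)
  expect_gt(a_esp, a_ahdi)
  # monotone in the window bound
  expect_gte(bistable_region_area(esp, 200), a_esp)
  # cooperativity shrinks the wedge, DBS binding strength expands it
  expect_gt(bistable_region_area(internal_params(25, 65, 16.9), r_max), a_esp)
  expect_lt(bistable_region_area(internal_params(25, 260, 16.9), r_max), a_esp)
  expect_gt(bistable_region_area(internal_params(50, 130, 16.9), r_max), a_esp)
  expect_lt(bistable_region_area(internal_params(12.5, 130, 16.9), r_max), a_esp)
  expect_warning(a0 <- bistable_region_area(esp, 1), "cusp")
  expect_equal(a0, 0)
})
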