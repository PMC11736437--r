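test_that("Esp1396I methyltransferase follows C-dimer repression", {
  expect_equal(m_esp1396i(0, r = 10, phi = 1, gamma = 5.1), 10)
  expect_equal(m_esp1396i(3, r = 10, phi = 1, gamma = 0), 10)
  expect_equal(m_esp1396i(1, r = 10, phi = 1, gamma = 5.1), 10 / 6.1)
  cf <- seq(0, 5, length.out = 100)
  expect_true(all(diff(m_esp1396i(cf, r = 4)) < 0))
})

test_that("AhdI autoregulated steady state solves the coupled pair uniquely", {
  # vanishing expression
  expect_lt(m_ahdi(1e-9)$m_total, 1e-8)
  # defining residual and the phi*r bound over random strengths
  set.seed(7)
  r <- rlnorm(30, 1, 1.5)
  res <- m_ahdi(r)
  expect_true(all(res$m_total <= 0.2 * r + 1e-12))
  resid <- res$m_total * (1 + res$m_free^2) - 0.2 * r
  expect_lt(max(abs(resid)), 1e-10)
  # monomer-dimer conservation for M
  alpha_m <- 2 * sqrt(5)
  expect_lt(max(abs(res$m_free + 2 * res$m_free^2 / alpha_m - res$m_total) /
                  res$m_total), 1e-12)
  # bisection oracle at phi*r = 2
  oracle <- bisect(function(mt) {
    mf <- (alpha_m / 4) * (sqrt(1 + 8 * mt / alpha_m) - 1)
    mt * (1 + mf^2) - 2
  }, 0, 2, tol = 1e-12)
  expect_equal(m_ahdi(10)$m_total, oracle, tolerance = 1e-8)
  expect_equal(oracle, 1.166, tolerance = 1e-3)
})

test_that("EcoRV overlapping-promoter model is bounded by phi*r at both ends", {
  expect_equal(m_ecorv(0, r = 1, phi = 1, p = 5, omega = 1), 1)
  expect_equal(m_ecorv(1e9, r = 1, phi = 1, p = 5, omega = 1), 1,
               tolerance = 1e-6)
  expect_equal(m_ecorv(1, r = 1, phi = 1, p = 5, omega = 1), 1.4 / 2.4)
  # repression is maximal at intermediate C, where activation peaks
  cf <- exp(seq(log(1e-3), log(1e3), length.out = 500))
  m <- m_ecorv(cf, r = 1, phi = 1, p = 5, omega = 1)
  i <- which.min(m)
  expect_gt(i, 1)
  expect_lt(i, length(cf))
  expect_true(all(m <= 1 + 1e-12))
})

test_that("M-to-R ratio declines with expression strength on stable branches", {
  rg <- exp(seq(log(0.5), log(60), length.out = 80))
  # monostable regime: single branch, strictly decreasing ratio
  mono <- mr_curve(rm_preset("esp1396i"), s = 0.2, rg)
  expect_setequal(unique(mono$branch), "stable")
  expect_true(all(diff(mono$m_over_r) < 0))

  # AhdI at its inferred leakage: bistable with two stable branches
  bi <- mr_curve(rm_preset("ahdi"), s = 0.0043, rg)
  fi <- attr(bi, "fold_interval")
  expect_false(is.null(fi))
  inside <- dplyr::filter(bi, r > fi[1], r < fi[2], stability == "stable")
  expect_setequal(unique(inside$branch), c("low", "high"))
  # R and the ratio are two-valued over the fold interval
  expect_true(all(dplyr::count(inside, r)$n == 2))

  # the robustness claim: as expression strength rises, the ratio declines
  # along the path the system follows. Pointwise on the establishment (low /
  # monostable) branch over the fold-scale window, pointwise on the high
  # branch within the fold interval, and downward across the hysteresis
  # jump. (Far beyond the fold region the leakage-dominated plateau makes
  # the high-branch ratio creep back toward phi/s; the declining trend is a
  # property of the regulated regime.)
  for (cs in list(list("esp1396i", 0.2), list("esp1396i", 0.02),
                  list("ahdi", 0.0043), list("ecorv", 0.2),
                  list("ecorv", 0.03))) {
    pr <- rm_preset(cs[[1]])
    s <- cs[[2]]
    b <- stability_boundary(pr)
    fi <- fold_interval(b, s)
    r_top <- if (is.null(fi)) 2 * attr(b, "cusp")$r else 2 * fi[2]
    rg2 <- exp(seq(log(0.5), log(r_top), length.out = 60))
    mc <- dplyr::filter(mr_curve(pr, s, rg2), stability == "stable",
                        !is.na(m_over_r))
    if (is.null(fi)) {
      # pointwise decline through the fold-scale range, net decline beyond
      core <- dplyr::filter(mc, r <= attr(b, "cusp")$r)
      expect_true(all(diff(core$m_over_r) <= 1e-9))
      expect_lt(dplyr::last(mc$m_over_r), dplyr::first(mc$m_over_r))
    } else {
      low <- dplyr::filter(mc, branch == "low")
      expect_true(all(diff(low$m_over_r) <= 1e-9))
      high_fold <- dplyr::filter(mc, branch == "high", r <= fi[2])
      expect_true(all(diff(high_fold$m_over_r) <= 1e-9))
      # jump at the upper fold lands on a lower ratio
      high_after <- dplyr::filter(mc, branch == "high", r > fi[2])
      expect_lt(high_after$m_over_r[1], dplyr::last(low$m_over_r))
    }
  }
})

test_that("the proportionality constant rescales the ratio, nothing else", {
  rg <- c(1, 5, 25)
  base <- mr_curve(rm_preset("esp1396i"), s = 0.2, rg)
  scaled_preset <- rm_preset("esp1396i")
  scaled_preset$k_rc <- 2.5
  scaled <- mr_curve(scaled_preset, s = 0.2, rg)
  expect_equal(scaled$m_over_r, base$m_over_r / 2.5, tolerance = 1e-12)
  expect_equal(scaled$m_total, base$m_total, tolerance = 1e-12)
  expect_equal(scaled$c_total, base$c_total, tolerance = 1e-12)
})

test_that("ratio is undefined at vanishing R", {
  mc <- mr_curve(rm_preset("esp1396i"), s = 0, r_grid = c(0.5, 1))
  expect_true(all(is.na(mc$m_over_r[mc$r_total == 0])))
})
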