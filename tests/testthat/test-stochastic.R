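small_cfg <- function(mode, seed, n_cells = 300, ...) {
  rm_stochastic_config(mode, seed = seed, n_cells = n_cells, ...)
}

test_that("identical seed and config give bit-identical ensembles", {
  e1 <- rm_simulate(small_cfg("regulated", seed = 3, n_cells = 50))
  e2 <- rm_simulate(small_cfg("regulated", seed = 3, n_cells = 50))
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  e3 <- rm_simulate(small_cfg("regulated", seed = 4, n_cells = 50))
  expect_false(identical(e1$c, e3$c))
})

test_that("zero production from zero molecules stays at zero", {
  cfg <- small_cfg("regulated", seed = 1, n_cells = 20,
                   phi_m_abs = 0, phi_M_abs = 0, s = 0)
  ens <- rm_simulate(cfg)
  expect_true(all(ens$c == 0 & ens$r_mol == 0 & ens$m_mol == 0))
  expect_true(all(ens$n >= 0))
})

test_that("division conserves molecules and doubles plasmids before partition", {
  ens <- rm_simulate(small_cfg("regulated", seed = 12, n_cells = 80))
  wide <- tidyr::pivot_wider(ens, names_from = phase,
                             values_from = c(n, c, r_mol, m_mol))
  paired <- dplyr::filter(wide, !is.na(n_pre), division > 0)
  # the followed daughter never holds more than the parent (plasmids: than
  # the duplicated parent)
  expect_true(all(paired$c_post <= paired$c_pre))
  expect_true(all(paired$r_mol_post <= paired$r_mol_pre))
  expect_true(all(paired$m_mol_post <= paired$m_mol_pre))
  expect_true(all(paired$n_post <= 2 * paired$n_pre))
})

test_that("constitutive ensemble means match the birth/halving fixed point", {
  cfg <- small_cfg("constitutive", seed = 21, n_cells = 600)
  ens <- rm_simulate(cfg)
  # per-cycle production at stationarity equals the post-division state of
  # the deterministic cycle map, so pre-division means approach twice it
  fp <- attr(rm_deterministic_reference(cfg, n_divisions = 1,
                                        converge = TRUE),
             "fixed_point")$post
  pre10 <- dplyr::filter(ens, phase == "pre", division == 10)
  for (sp in c("c", "r_mol", "m_mol")) {
    x <- pre10[[sp]]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 2 * fp[[sp]]), 3 * se + 0.02 * 2 * fp[[sp]])
  }
})

test_that("summary statistics use interpolated quartiles and exclusions", {
  const <- tibble::tibble(cell_id = 1:10, division = 0, phase = "post",
                          n = 30, c = 5L, r_mol = 40L, m_mol = 80L)
  s <- summarize_ensemble(const)
  expect_equal(s$cv_mr, 0)
  expect_equal(s$iqr_mr, 0)
  expect_equal(s$median_mr, 2)

  known <- tibble::tibble(cell_id = 1:5, division = 0, phase = "post",
                          n = 1, c = 0L, r_mol = 1L, m_mol = 1:5)
  s <- summarize_ensemble(known)
  expect_equal(s$median_mr, 3)
  expect_equal(s$iqr_mr, 2) # type-7 quartiles: Q1 = 2, Q3 = 4

  excl <- tibble::tibble(cell_id = 1:4, division = 0, phase = "post",
                         n = 1, c = 0L, r_mol = c(0L, 0L, 2L, 2L),
                         m_mol = c(5L, 5L, 4L, 6L))
  s <- summarize_ensemble(excl)
  expect_equal(s$n_excluded, 2L)
  expect_equal(s$median_mr, 2.5)

  all_gone <- dplyr::mutate(excl, r_mol = 0L)
  s <- summarize_ensemble(all_gone)
  expect_true(s$undefined)
  expect_true(is.na(s$cv_mr))
})

test_that("regulation broadens the M-to-R distribution at matched levels", {
  reg <- rm_simulate(small_cfg("regulated", seed = 31, n_cells = 600))
  con <- rm_simulate(small_cfg("constitutive", seed = 32, n_cells = 600))
  s_reg <- summarize_ensemble(reg, at_division = 10)
  s_con <- summarize_ensemble(con, at_division = 10)
  # calibration matched the equilibrium levels
  expect_lt(abs(s_reg$median_r - s_con$median_r) / s_con$median_r, 0.15)
  expect_lt(abs(s_reg$median_mr - s_con$median_mr) / s_con$median_mr, 0.25)
  # regulation increases noise
  expect_gt(s_reg$cv_mr, s_con$cv_mr)
  expect_gt(s_reg$robust_cv_mr, s_con$robust_cv_mr)
  expect_gt(s_reg$iqr_mr, s_con$iqr_mr)
})

test_that("stochastic equilibrium matches the deterministic reference", {
  cfg <- small_cfg("regulated", seed = 41, n_cells = 400)
  ens <- rm_simulate(cfg)
  ref <- rm_deterministic_reference(cfg)
  expect_true(equilibrium_check(ref, ref)$ok)
  expect_true(equilibrium_check(ens, ref)$ok)
  short <- rm_simulate(small_cfg("regulated", seed = 42, n_cells = 400,
                                 n_divisions = 2))
  expect_false(equilibrium_check(short, rm_deterministic_reference(cfg))$ok)
})

test_that("post-segregational decay halves R and delays the noise increase", {
  reg <- rm_simulate(small_cfg("regulated", seed = 51, n_cells = 800))
  expect_error(rm_simulate(small_cfg("post_segregational", seed = 52)),
               "initial")
  post <- rm_simulate(small_cfg("post_segregational", seed = 52,
                                n_cells = 800), initial = reg)
  expect_true(all(post$n == 0))
  s <- summarize_ensemble(post)
  # median R halves at each division while counts are large
  big <- which(s$median_r[-nrow(s)] > 100)
  halving <- s$median_r[big + 1] / s$median_r[big]
  expect_true(all(halving > 0.4 & halving < 0.6))
  # robust CV: flat through division 4, rising sharply by division 7
  expect_lt(abs(s$robust_cv_mr[5] / s$robust_cv_mr[1] - 1), 0.25)
  expect_gt(s$robust_cv_mr[8], 1.5 * s$robust_cv_mr[1])
})

test_that("co-transcription option couples R production to C events", {
  cfg <- small_cfg("regulated", seed = 61, n_cells = 100, cotranscribe = TRUE)
  ens <- rm_simulate(cfg)
  s <- summarize_ensemble(ens, at_division = 10)
  # equilibrium levels are preserved; only the noise decomposition changes
  ref <- rm_deterministic_reference(cfg)
  expect_lt(abs(s$median_r - ref$r_mol[11]) / ref$r_mol[11], 0.2)
})
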