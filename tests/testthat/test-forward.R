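test_that("MoM solve matches the analytic cylinder series at default discretization", {
  # homogeneous muscle cylinder, 3 cm radius, centered in the default domain
  cfg <- phantom_config()     # 128 x 128, 1.875 mm cells
  ph <- build_neck_phantom(cfg)
  d2 <- outer(ph$xc^2, ph$yc^2, "+")
  lab <- matrix(0L, 128, 128)
  lab[d2 <= 0.03^2] <- 3L
  ph$labels <- lab
  ph$rois <- list()           # no ROI windows for this scene
  f <- 1.35e9
  lay <- antenna_layout()
  fr <- solve_total_field(ph, lay, f)
  eps_b <- background_permittivity(cfg$background_eps, cfg$background_sigma, f)
  eps_m <- cole_cole(ph$tissue_table$muscle$params, f)
  ref <- analytic_cylinder_reference(0.03, eps_m, eps_b, lay, f)
  err <- sqrt(sum(Mod(fr$es - ref)^2) / sum(Mod(ref)^2))
  expect_lt(err, 0.02)
  # reciprocity of the co-located multistatic matrix
  expect_lt(max(Mod(fr$es - t(fr$es))) / max(Mod(fr$es)), 1e-6)
})

test_that("zero contrast produces exactly zero scattering and the incident field", {
  ph <- small_phantom()
  ph$labels[] <- 0L
  ph$rois <- list()
  fr <- solve_total_field(ph, antenna_layout(), 1.35e9)
  expect_true(all(fr$es == 0))
  expect_identical(dim(fr$es), c(12L, 12L))
})

test_that("scattering is linear in the source amplitude", {
  ws <- small_workspace()
  kb <- ws$per_freq[[2]]$kb
  lay <- ws$layout
  pts <- ws$points
  e1 <- incident_field(lay, kb, 3, pts, amplitude = 1)
  e5 <- incident_field(lay, kb, 3, pts, amplitude = 5 - 2i)
  expect_equal(e5, (5 - 2i) * e1, tolerance = 1e-14)
})

test_that("the analytic cylinder reference has the right degenerate limits", {
  lay <- antenna_layout()
  f <- 1.35e9
  eb <- 23 - 13i
  expect_true(all(analytic_cylinder_reference(0.03, eb, eb, lay, f) == 0))
  expect_true(all(analytic_cylinder_reference(0, 50 - 10i, eb, lay, f) == 0))
  tiny <- analytic_cylinder_reference(1e-4, 50 - 10i, eb, lay, f)
  big <- analytic_cylinder_reference(0.03, 50 - 10i, eb, lay, f)
  expect_lt(max(Mod(tiny)), 1e-3 * max(Mod(big)))
})

test_that("CG-FFT and dense factorization agree", {
  ph <- small_phantom()
  f <- 1.35e9
  lay <- antenna_layout()
  suppressWarnings({
    fd <- solve_total_field(ph, lay, f, solver = "dense")
    fc <- solve_total_field(ph, lay, f, solver = "cgfft", tol = 1e-8)
  })
  expect_lt(sqrt(sum(Mod(fd$es - fc$es)^2) / sum(Mod(fd$es)^2)), 1e-6)
})

test_that("stronger background loss reduces the received scattered field", {
  f <- 1.35e9
  lay <- antenna_layout()
  mags <- vapply(c(0.5, 1.0, 1.5), function(sb) {
    ph <- build_neck_phantom(phantom_config(n = 32L, domain_size = 0.12,
                                            background_sigma = sb))
    fr <- suppressWarnings(solve_total_field(ph, lay, f))
    mean(Mod(fr$es))
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("AWGN calibration: empirical SNR within half a dB of the target", {
  base <- baseline_state()$es
  p_sig <- apply(base, 3, function(s) mean(Mod(s)^2))
  p_noise <- 0
  nrep <- 1000L
  for (r in seq_len(nrep)) {
    noisy <- add_awgn(base, 30, seed = r)
    p_noise <- p_noise + apply(noisy - base, 3,
                               function(s) mean(Mod(s)^2))
  }
  snr_hat <- 10 * log10(p_sig / (p_noise / nrep))
  expect_true(all(abs(snr_hat - 30) < 0.5))
})

test_that("AWGN respects the no-noise limit and the seed contract", {
  base <- baseline_state()$es
  expect_identical(add_awgn(base, Inf, 1), base)
  expect_identical(add_awgn(base, 30, 9), add_awgn(base, 30, 9))
  expect_false(identical(add_awgn(base, 30, 9), add_awgn(base, 30, 10)))
})
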