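test_that("every generator is a pure function of parameters and seed", {
  expect_identical(gen_order_profile(12, 0.21, seed = 7, jitter_sd = 0.01),
                   gen_order_profile(12, 0.21, seed = 7, jitter_sd = 0.01))
  p <- gen_order_profile(12, 0.21, seed = 7)
  expect_identical(gen_2h_spectrum(p, snr = 50, seed = 9)$intensity,
                   gen_2h_spectrum(p, snr = 50, seed = 9)$intensity)
  expect_identical(gen_progress_curve(seed = 4)$intensity,
                   gen_progress_curve(seed = 4)$intensity)
  expect_identical(gen_helfrich_surfaces(grid_n = 16, n_frames = 3,
                                         seed = 2)$surfaces,
                   gen_helfrich_surfaces(grid_n = 16, n_frames = 3,
                                         seed = 2)$surfaces)
  a <- gen_bilayer_frames(n_lipids_per_leaflet = 9, n_frames = 2, seed = 3)
  b <- gen_bilayer_frames(n_lipids_per_leaflet = 9, n_frames = 2, seed = 3)
  expect_identical(a$frames[[2]]$coords, b$frames[[2]]$coords)
})

test_that("order-profile generation is monotone, capped, and clamped", {
  p <- gen_order_profile(12, plateau_s = 0.21, methyl_s = 0.05)
  expect_true(all(diff(abs(p$s_cd)) <= 0))
  expect_equal(max(abs(p$s_cd)), 0.21)
  expect_warning(p2 <- gen_order_profile(12, plateau_s = 0.45, scale = 1.3),
                 "capped")
  expect_equal(max(abs(p2$s_cd)), 0.5)
  expect_error(gen_order_profile(12, plateau_s = 0.2, methyl_s = 0.3), "plateau")
  expect_error(gen_order_profile(12, plateau_s = 0.6), "plateau_s")
})

test_that("simulated spectra carry their truth and honour the requested SNR", {
  p <- gen_order_profile(12, 0.21, seed = 1)
  s <- gen_2h_spectrum(p, snr = 50, broadening = 0.5, seed = 2)
  expect_identical(s$meta$truth_profile$s_cd, p$s_cd)
  # wing-variance estimate of the noise level
  wings <- abs(s$axis) > 45
  snr_est <- max(s$intensity) / sd(s$intensity[wings])
  expect_lt(abs(snr_est / 50 - 1), 0.2)
  # noiseless limit equals the forward model
  s_inf <- gen_2h_spectrum(p, snr = Inf, broadening = 0.5)
  fwd <- simulate_quadrupolar_powder(p, broadening = 0.5)
  expect_equal(s_inf$intensity, fwd$intensity)
})

test_that("progress-curve generation matches its model and the CLT oracle", {
  c0 <- gen_progress_curve(1000, 800, 600, window = 1800, n_points = 10,
                           noise_frac = 0)
  expect_equal(c0$intensity, 1000 - 800 * exp(-c0$time / 600))
  expect_error(gen_progress_curve(n_points = 5), "n_points")
  expect_error(gen_progress_curve(tau = -5), "tau")

  # mean at t = tau over replicates: I_max - I_0 / e within 3 sigma
  vals <- vapply(1:1000, function(i) {
    cur <- gen_progress_curve(1000, 800, 600, window = 1200, n_points = 9,
                              noise_frac = 0.05, seed = i)
    cur$intensity[which.min(abs(cur$time - 600))]
  }, numeric(1))
  truth <- 1000 - 800 / exp(1)
  noise_sd <- 0.05 * diff(range(1000 - 800 * exp(-seq(0, 1200, length.out = 9) / 600)))
  expect_lt(abs(mean(vals) - truth), 3 * noise_sd / sqrt(1000))
})

test_that("Helfrich sampling matches the per-mode variance formula", {
  kc <- 12; box_l <- 20; n <- 16L
  surf <- gen_helfrich_surfaces(box_l = box_l, grid_n = n, kc = kc,
                                n_frames = 2000, seed = 6)
  # all surfaces are exactly real by Hermitian construction
  expect_true(all(vapply(surf$surfaces[1:5], is.numeric, logical(1))))
  # lowest mode (1, 0): variance = 1 / (A kc q^4)
  q1 <- 2 * pi / box_l
  amp2 <- vapply(surf$surfaces, function(h) Mod(fft(h)[2, 1] / n^2)^2, numeric(1))
  expected <- 1 / (box_l^2 * kc * q1^4)
  se <- sd(amp2) / sqrt(length(amp2))
  expect_lt(abs(mean(amp2) - expected), 3 * se)

  # rigidity limit: kc up, variance down
  stiff <- gen_helfrich_surfaces(box_l = box_l, grid_n = n, kc = 1e6,
                                 n_frames = 5, seed = 7)
  expect_lt(max(abs(stiff$surfaces[[1]])), 0.05)
  expect_error(gen_helfrich_surfaces(grid_n = 6), "grid_n")
  expect_error(gen_helfrich_surfaces(grid_n = 24), "power of two")
  expect_error(gen_helfrich_surfaces(kc = -1), "kc")
})

test_that("bilayer frames encode their stated ground truth", {
  tr <- gen_bilayer_frames(n_lipids_per_leaflet = 16, wobble_kappa = Inf,
                           n_frames = 1, seed = 1)
  prof <- acyl_order_parameters(tr, synthetic_chain_selector(12))
  expect_equal(prof$s_cd[!prof$is_methyl], rep(-0.5, 10), tolerance = 1e-9)
  expect_equal(tr$meta$truth$expected_scd_methylene, -0.5)

  # no protein: no annular lipids
  cl <- classify_annular(tr$frames[[1]], list(resname = "GLPG"), cutoff = 6)
  expect_true(all(cl$label == "bulk"))

  expect_error(gen_bilayer_frames(chol_fraction = 1.2), "chol_fraction")
  expect_error(gen_bilayer_frames(n_lipids_per_leaflet = 0), "lipid")
})

test_that("the ideal helix fixture folds mirror tilts onto one angle", {
  for (tilt in c(0, 30)) {
    got <- helix_tilt(gen_ideal_helix(18, tilt),
                      list(tm = c(1L, 18L)))$summary$mean_tilt_deg
    expect_lt(abs(got - tilt), 0.5)
  }
  a <- helix_tilt(gen_ideal_helix(18, 40), list(tm = c(1L, 18L)))
  b <- helix_tilt(gen_ideal_helix(18, 140), list(tm = c(1L, 18L)))
  expect_equal(a$summary$mean_tilt_deg, b$summary$mean_tilt_deg, tolerance = 0.5)
  expect_error(gen_ideal_helix(4), "n_res")
})
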