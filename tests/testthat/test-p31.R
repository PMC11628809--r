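ppm_axis <- seq(-60, 40, length.out = 1001L)

test_that("CSA powder kernel places its edges and maximum correctly", {
  # delta_sigma = -45, iso = 0: theta=0 edge at -30 ppm, theta=90 at +15 ppm
  s <- simulate_csa_powder(csa_component(-45, 0, broadening = 0.3), ppm_axis)
  expect_equal(s$axis[which.max(s$intensity)], 15, tolerance = 0.5)
  in_support <- s$axis > -30 & s$axis < 15
  expect_gt(min(s$intensity[in_support]), max(s$intensity[s$axis < -33]))
  expect_equal(spectrum_integral(s), 1, tolerance = 1e-6)

  # sin(theta) weighting: 90-degree edge dominates the 0-degree edge
  for (ds in c(-20, -35, -48)) {
    sp <- simulate_csa_powder(csa_component(ds, 0, broadening = 0.5), ppm_axis)
    i90 <- sp$intensity[which.min(abs(sp$axis - (-ds / 3)))]
    i0 <- sp$intensity[which.min(abs(sp$axis - (2 * ds / 3)))]
    expect_gt(i90, i0)
  }
})

test_that("zero span collapses continuously onto the isotropic kernel", {
  iso <- simulate_csa_powder(csa_component(sigma_iso = 2, broadening = 1,
                                           kind = "isotropic"), ppm_axis)
  expect_equal(iso$axis[which.max(iso$intensity)], 2, tolerance = 0.2)
  dev <- vapply(c(2, 0.5, 0.1), function(ds) {
    p <- simulate_csa_powder(csa_component(-ds, 2, broadening = 1), ppm_axis)
    max(abs(p$intensity - iso$intensity))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.02 * max(iso$intensity))

  expect_error(simulate_csa_powder(csa_component(-45, -50, broadening = 1),
                                   ppm_axis), "span")
})

test_that("composition is linear, seeded, and checks the fraction simplex", {
  c1 <- csa_component(-44, 0, fraction = 0.5, broadening = 1.5)
  c2 <- csa_component(-32, 0, fraction = 0.5, broadening = 1.5)
  both <- compose_spectrum(list(c1, c2), ppm_axis)
  s1 <- simulate_csa_powder(c1, ppm_axis)
  s2 <- simulate_csa_powder(c2, ppm_axis)
  expect_equal(both$intensity, (s1$intensity + s2$intensity) / 2,
               tolerance = 1e-12)

  one <- compose_spectrum(list(csa_component(-44, 0, 1, 1.5)), ppm_axis)
  expect_equal(one$intensity, simulate_csa_powder(csa_component(-44, 0, 1, 1.5),
                                                  ppm_axis)$intensity)

  a <- compose_spectrum(list(c1, c2), ppm_axis, noise_sd = 0.001, seed = 42)
  b <- compose_spectrum(list(c1, c2), ppm_axis, noise_sd = 0.001, seed = 42)
  expect_identical(a$intensity, b$intensity)

  bad <- list(csa_component(-44, 0, 0.6), csa_component(-32, 0, 0.6))
  expect_error(compose_spectrum(bad, ppm_axis), "sum")
})

test_that("a noiseless single component self-fits to numerical precision", {
  truth <- csa_component(-44.3, 0.5, 1, broadening = 1.5)
  spec <- compose_spectrum(list(truth), ppm_axis)
  fit <- fit_multicomponent(spec, n_powder = 1L, has_isotropic = FALSE,
                            init = list(truth))
  expect_lt(fit$residual_norm, 1e-8)
  expect_equal(abs(fit$components[[1]]$delta_sigma), 44.3, tolerance = 1e-4)
  expect_equal(fit$components[[1]]$fraction, 1)

  # perturbed start lands in the same basin
  init2 <- list(csa_component(-44.3 * 1.1, 0.5 * 0.9, 1, broadening = 1.5 * 1.1))
  fit2 <- fit_multicomponent(spec, n_powder = 1L, has_isotropic = FALSE,
                             init = init2)
  expect_equal(abs(fit2$components[[1]]$delta_sigma),
               abs(fit$components[[1]]$delta_sigma), tolerance = 1e-4)
  expect_equal(fit2$components[[1]]$sigma_iso, fit$components[[1]]$sigma_iso,
               tolerance = 1e-3)
})

test_that("the two-powder + isotropic decomposition recovers generator truth", {
  comps <- list(csa_component(-44.3, 0, 0.91, broadening = 1.5),
                csa_component(-32.6, -1, 0.08, broadening = 1.5),
                csa_component(sigma_iso = 0.5, fraction = 0.01,
                              broadening = 0.8, kind = "isotropic"))
  clean <- compose_spectrum(comps, ppm_axis)
  noisy <- compose_spectrum(comps, ppm_axis,
                            noise_sd = max(clean$intensity) / 100, seed = 7)
  fit <- fit_multicomponent(noisy, n_powder = 2L, has_isotropic = TRUE)
  spans <- vapply(fit$components[1:2], function(x) abs(x$delta_sigma), numeric(1))
  fr <- fit$fractions_pct
  expect_lt(abs(spans[1] - 44.3), 0.5)
  expect_lt(abs(spans[2] - 32.6), 0.5)
  expect_lt(abs(fr[1] - 91), 2)
  expect_lt(abs(fr[2] - 8), 2)
  expect_lt(abs(fr[3] - 1), 2)
  # hard simplex: fractions non-negative and summing to one
  fracs <- vapply(fit$components, `[[`, numeric(1), "fraction")
  expect_true(all(fracs >= 0))
  expect_equal(sum(fracs), 1, tolerance = 1e-9)
  expect_false(fit$degenerate)
})
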