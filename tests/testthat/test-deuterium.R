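axis_default <- seq(-60, 60, length.out = 1025L)

single_site_profile <- function(s) {
  order_profile(2L, s, is_methyl = FALSE)
}

test_that("powder forward model places the Pake horns at the 90-degree edges", {
  # d90 = (3/4) * 167 * 0.5 = 62.625 kHz between horns, horns at +-31.3 kHz
  s <- simulate_quadrupolar_powder(single_site_profile(-0.5), chi_q = 167,
                                   broadening = 0.1,
                                   axis = seq(-80, 80, length.out = 4097L))
  horn <- abs(s$axis[which.max(s$intensity)])
  expect_equal(horn, 62.625 / 2, tolerance = 0.15)
  # zero order: single broadened line at 0
  s0 <- simulate_quadrupolar_powder(
    order_profile(2:4, c(0, 0, 0), is_methyl = rep(FALSE, 3)),
    broadening = 1, axis = axis_default)
  expect_equal(s0$axis[which.max(s0$intensity)], 0)
  expect_equal(spectrum_integral(s0), 1, tolerance = 1e-6)
})

test_that("powder spectra are symmetric and superpose linearly", {
  p1 <- single_site_profile(-0.15)
  p2 <- single_site_profile(-0.35)
  both <- order_profile(2:3, c(-0.35, -0.15), is_methyl = c(FALSE, FALSE))
  s1 <- simulate_quadrupolar_powder(p1, broadening = 0.5, axis = axis_default)
  s2 <- simulate_quadrupolar_powder(p2, broadening = 0.5, axis = axis_default)
  s12 <- simulate_quadrupolar_powder(both, broadening = 0.5, axis = axis_default)
  expect_identical(s12$intensity, rev(s12$intensity)) # exact symmetry
  # each site carries 2 deuterons: the combined spectrum is the mean
  expect_equal(s12$intensity, (s1$intensity + s2$intensity) / 2,
               tolerance = 1e-10)
})

test_that("forward model rejects narrow axes and non-finite profiles", {
  expect_error(
    simulate_quadrupolar_powder(single_site_profile(-0.5),
                                axis = seq(-30, 30, length.out = 257L)),
    "C2")
  expect_error(simulate_quadrupolar_powder(single_site_profile(-0.3), chi_q = -1),
               "chi_q")
})

test_that("dePakeing collapses a doublet to twice its horn offset", {
  # site with horn-to-horn splitting 20 kHz: horns at +-10, oriented peaks +-20
  s_cd <- -20 / (0.75 * 167)
  pw <- simulate_quadrupolar_powder(single_site_profile(s_cd), broadening = 0.4,
                                    axis = seq(-40, 40, length.out = 1025L))
  dp <- depake(pw)
  half <- dp$axis > 2
  peak <- dp$axis[half][which.max(dp$intensity[half])]
  expect_equal(peak, 20, tolerance = diff(dp$axis[1:2]) * 1.5)
  # integral preserved
  expect_equal(spectrum_integral(dp), spectrum_integral(pw), tolerance = 1e-6)
})

test_that("dePakeing keeps an isotropic line at zero and rejects bad input", {
  iso <- simulate_quadrupolar_powder(
    order_profile(2L, 0, is_methyl = FALSE), broadening = 1, axis = axis_default)
  dp <- depake(iso)
  expect_equal(dp$axis[which.max(dp$intensity)], 0, tolerance = 0.5)

  zero <- spectrum1d(axis_default, rep(0, length(axis_default)))
  expect_error(depake(zero), "all-zero")

  lop <- spectrum1d(axis_default,
                    dnorm(axis_default, mean = 15, sd = 3))
  expect_warning(dp2 <- depake(lop), "symmetry")
  expect_match(dp2$meta$asymmetry_warning, "symmetry residual")
})

test_that("dePaked peak positions recover a three-site splitting list", {
  d90 <- c(8, 18, 30) # horn-to-horn splittings, kHz
  prof <- order_profile(2:4, -d90 / (0.75 * 167), is_methyl = rep(FALSE, 3))
  pw <- simulate_quadrupolar_powder(prof, broadening = 0.4,
                                    axis = seq(-50, 50, length.out = 1025L))
  dp <- depake(pw)
  dx <- diff(dp$axis[1:2])
  pos <- dp$axis[dp$axis > 0]
  int <- dp$intensity[dp$axis > 0]
  found <- vapply(d90, function(d) {
    win <- abs(pos - d) < 4
    pos[win][which.max(int[win])]
  }, numeric(1))
  expect_equal(found, d90, tolerance = dx * 1.01)
})

test_that("profile extraction round-trips a DLPC-like monotone profile", {
  prof <- gen_order_profile(n_carbons = 12L, plateau_s = 0.21, methyl_s = 0.05,
                            seed = 1)
  pw <- simulate_quadrupolar_powder(prof, broadening = 0.5, axis = axis_default)
  rec <- extract_smoothed_order_profile(depake(pw), n_carbons = 12L)
  expect_equal(rec$s_cd, prof$s_cd, tolerance = 0.01)
  expect_true(all(diff(abs(rec$s_cd)) <= 1e-12)) # monotone toward methyl
})

test_that("a single-splitting chain extracts as a flat profile", {
  prof <- order_profile(2:8, rep(-0.2, 7), is_methyl = rep(FALSE, 7))
  pw <- simulate_quadrupolar_powder(prof, broadening = 0.4, axis = axis_default,
                                    methyl_scale = 1)
  # treat every site as a methylene: n_carbons chosen so areas partition evenly
  rec <- extract_smoothed_order_profile(depake(pw), n_carbons = 8L,
                                        methyl_scale = 1)
  expect_equal(rec$s_cd[!rec$is_methyl], rep(-0.2, 6), tolerance = 0.01)
})

test_that("deuteron-weighted area is conserved by the assignment", {
  prof <- gen_order_profile(12L, plateau_s = 0.25, methyl_s = 0.04, seed = 2)
  pw <- simulate_quadrupolar_powder(prof, broadening = 0.5, axis = axis_default)
  dp <- depake(pw)
  rec <- extract_smoothed_order_profile(dp, n_carbons = 12L)
  # the mean splittings weighted by deuteron counts must reproduce the
  # half-spectrum first moment (area-conserving partition)
  pos <- dp$axis >= 0
  w <- pmax(dp$intensity[pos], 0)
  m1_spectrum <- sum(w * dp$axis[pos]) / sum(w)
  counts <- ifelse(rec$is_methyl, 3, 2)
  m1_sites <- sum(attr(rec, "meta")$mean_splitting_kHz * counts) / sum(counts)
  expect_equal(m1_sites, m1_spectrum, tolerance = 1e-3 * m1_spectrum)
})

test_that("extraction scales equivariantly with a uniform order scaling", {
  base <- gen_order_profile(12L, plateau_s = 0.3, methyl_s = 0.06, seed = 3)
  scaled <- gen_order_profile(12L, plateau_s = 0.3, methyl_s = 0.06, seed = 3,
                              scale = 0.7)
  rec_b <- extract_smoothed_order_profile(
    depake(simulate_quadrupolar_powder(base, broadening = 0.5, axis = axis_default)),
    n_carbons = 12L)
  rec_s <- extract_smoothed_order_profile(
    depake(simulate_quadrupolar_powder(scaled, broadening = 0.5, axis = axis_default)),
    n_carbons = 12L)
  dx <- 120 / 1024
  expect_equal(attr(rec_s, "meta")$mean_splitting_kHz,
               0.7 * attr(rec_b, "meta")$mean_splitting_kHz,
               tolerance = dx * 1.5)
})

test_that("extraction rejects splittings above the physical order bound", {
  prof <- single_site_profile(-0.4)
  pw <- simulate_quadrupolar_powder(prof, broadening = 0.3,
                                    axis = seq(-80, 80, length.out = 1025L))
  dp <- depake(pw)
  # pretending chi_q were much smaller implies |s_cd| > 0.5
  expect_error(extract_smoothed_order_profile(dp, n_carbons = 6L, chi_q = 40),
               "chi_q")
  expect_error(extract_smoothed_order_profile(dp, n_carbons = 3L), "n_carbons")
})
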