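pn_frame <- function(dirs, z = 60) {
  n <- nrow(dirs)
  p_pos <- cbind(runif(n, 10, 90), runif(n, 10, 90), rep(z, n))
  n_pos <- p_pos + 3 * dirs
  coords <- rbind(p_pos, n_pos)
  atoms <- data.frame(resname = "DLPC", resid = c(1:n, 1:n),
                      atomname = c(rep("P", n), rep("N", n)))
  membrane_frame(coords, atoms, box = c(100, 100, 120))
}

test_that("P-N angle histogram resolves constructed orientations", {
  inplane <- with_seed_test(1, {
    phi <- runif(200, 0, 2 * pi)
    pn_frame(cbind(cos(phi), sin(phi), 0))
  })
  h <- pn_angle_histogram(inplane, bins = 9L) # 20-degree bins, 90 interior
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$mids[which.max(h$counts)], 90)
  expect_equal(sum(h$density) * diff(h$breaks)[1], 1, tolerance = 1e-12)

  along_z <- with_seed_test(2, pn_frame(matrix(rep(c(0, 0, 1), 50),
                                               ncol = 3, byrow = TRUE)))
  h2 <- pn_angle_histogram(along_z, bins = 9L)
  expect_equal(h2$mids[which.max(h2$counts)], 10) # first bin [0, 20)
  expect_true(all(h2$angles < 1e-6))

  # missing N atom errors per residue
  broken <- inplane
  broken$atoms$atomname[broken$atoms$atomname == "N"][1] <- "X"
  expect_error(pn_angle_histogram(broken), "missing N")
})

test_that("uniform random orientations follow the sin(theta) density", {
  n <- 10000L
  dirs <- with_seed_test(5, {
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    cbind(r * cos(phi), r * sin(phi), z)
  })
  frame <- with_seed_test(6, pn_frame(dirs))
  h <- pn_angle_histogram(frame, bins = 18L)
  p_expected <- diff(-cos(h$breaks * pi / 180)) / 2
  test <- stats::chisq.test(h$counts, p = p_expected)
  expect_gt(test$p.value, 0.01)
})

test_that("helix tilt recovers constructed tilts and symmetries", {
  t0 <- helix_tilt(gen_ideal_helix(18, 0), list(tm = c(1L, 18L)))
  expect_lt(t0$summary$mean_tilt_deg, 0.5)
  t30 <- helix_tilt(gen_ideal_helix(18, 30), list(tm = c(1L, 18L)))
  expect_lt(abs(t30$summary$mean_tilt_deg - 30), 0.5)

  # translation invariance
  h <- gen_ideal_helix(18, 30)
  h_shift <- membrane_frame(sweep(h$coords, 2, c(7, -4, 12), "+"), h$atoms, h$box)
  expect_equal(helix_tilt(h_shift, list(tm = c(1L, 18L)))$summary$mean_tilt_deg,
               t30$summary$mean_tilt_deg, tolerance = 1e-9)

  # 180-degree flip about x maps tilt to its fold
  flip <- diag(c(1, -1, -1))
  h_flip <- membrane_frame(h$coords %*% flip, h$atoms, h$box)
  expect_equal(helix_tilt(h_flip, list(tm = c(1L, 18L)))$summary$mean_tilt_deg,
               t30$summary$mean_tilt_deg, tolerance = 1e-9)

  expect_error(helix_tilt(h, list(tm = c(1L, 4L))), ">= 6")
})

test_that("the pair distribution matches closed-form and brute-force oracles", {
  # ideal gas: g(r) = 1 within sampling error away from the first bins
  box <- c(40, 40, 40)
  frames <- lapply(1:6, function(s) random_point_frame(150, 10, box, 100 + s))
  traj <- membrane_trajectory(frames)
  g <- residue_pair_rdf(traj, list(resname = "LIP"), list(resname = "LIP"),
                        r_max = 15, bin_width = 0.5)
  tail_bins <- g$r_mid > 3
  expect_lt(abs(mean(g$g[tail_bins]) - 1), 0.05)
  expect_true(all(abs(g$g[tail_bins] - 1) < 3 * sqrt(1 / pmax(g$counts[tail_bins], 1)) + 0.2))

  # fixed 8 A pair: the peak bin contains r = 8
  coords <- rbind(c(10, 10, 10), c(18, 10, 10))
  atoms <- data.frame(resname = c("SER", "HIS"), resid = 1:2,
                      atomname = c("OG", "NE2"))
  pairf <- membrane_frame(coords, atoms, box = c(40, 40, 40))
  g2 <- residue_pair_rdf(membrane_trajectory(rep(list(pairf), 5)),
                         list(resname = "SER"), list(resname = "HIS"),
                         r_max = 12, bin_width = 0.5)
  peak <- g2[which.max(g2$g), ]
  expect_true(peak$r_lo <= 8 && 8 < peak$r_lo + 0.5)
  expect_equal(sum(g2$counts), 5) # one cross-pair per frame

  expect_error(residue_pair_rdf(pairf, list(resname = "SER"),
                                list(resname = "HIS"), r_max = 30), "half")
})

test_that("rdf bin counts equal the brute-force periodic oracle exactly", {
  for (seed in 1:5) {
    box <- c(30, 25, 20)
    fr <- random_point_frame(100, 0, box, 200 + seed)
    edges <- seq(0, 9, by = 0.3)
    g <- residue_pair_rdf(fr, list(resname = "LIP"), list(resname = "LIP"),
                          r_max = 9, bin_width = 0.3)
    idx <- which(fr$atoms$resname == "LIP")
    oc <- oracle_rdf_counts(fr$coords[idx, ], fr$coords[idx, ], idx, idx,
                            box, edges)
    expect_identical(g$counts, oc)
  }
})
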