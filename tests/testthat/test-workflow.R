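demo_config <- function(seed = 42) {
  list(seed = seed,
       nmr = list(snr = 80, samples = list(
         list(label = "DLPC_00", lipid = "DLPC", cholesterol = 0,
              generator = list(plateau_s = 0.21)),
         list(label = "DLPC_10", lipid = "DLPC", cholesterol = 10,
              generator = list(plateau_s = 0.21, scale = 1.15)),
         list(label = "DLPC_20", lipid = "DLPC", cholesterol = 20,
              generator = list(plateau_s = 0.21, scale = 1.3)))),
       kinetics = list(reference = "k00", samples = list(
         list(label = "k00", lipid = "DLPC", cholesterol = 0,
              generator = list(tau = 600)),
         list(label = "k10", lipid = "DLPC", cholesterol = 10,
              generator = list(tau = 1200)),
         list(label = "k20", lipid = "DLPC", cholesterol = 20,
              generator = list(tau = 500)))),
       traj = list(analyses = c("order", "annulus", "pn", "tilt", "rdf", "kc"),
                   generator = list(protein = list(radius = 7), n_frames = 2,
                                    n_lipids_per_leaflet = 36,
                                    chol_fraction = 0.15, wobble_kappa = 8),
                   helfrich = list(n_frames = 60, grid_n = 16)))
}

test_that("config validation catches structural mistakes", {
  cfg <- demo_config()
  cfg$nmr$samples[[2]]$label <- "DLPC_00"
  expect_error(read_study_config(cfg), "duplicate")

  cfg2 <- demo_config()
  cfg2$nmr$samples[[1]]$generator <- NULL
  expect_error(read_study_config(cfg2), "path or a generator")

  cfg3 <- demo_config()
  cfg3$nmr$samples[[1]]$generator <- NULL
  cfg3$nmr$samples[[1]]$path <- "no/such/file.csv"
  expect_error(read_study_config(cfg3), "does not exist")

  expect_error(run_nmr_arm(list(seed = 1, nmr = list(samples = list()))),
               "empty sample table")
  cfg4 <- read_study_config(demo_config())
  cfg4$traj$analyses <- c("order", "wavelets")
  expect_error(run_traj_arm(cfg4), "unknown analysis")
})

test_that("the three arms run end to end, deterministically, from one config", {
  cfg <- read_study_config(demo_config())
  out_dir <- withr::local_tempdir()
  cfg$output_dir <- out_dir
  res <- run_study(cfg)

  # NMR arm: thickness grows with the cholesterol scaling knob
  expect_equal(nrow(res$nmr$table), 3L)
  expect_true(all(diff(res$nmr$table$l_c) > 0))
  expect_gt(res$nmr$models$DLPC_noGlpG$slope, 0)

  # kinetics arm: reference ratio is 1, trends computed, thickness mapped
  ktab <- res$kinetics$table
  expect_equal(ktab$tau_ratio[ktab$label == "k00"], 1)
  expect_equal(ktab$tau_ratio[ktab$label == "k10"], 2, tolerance = 0.1)
  expect_equal(ktab$l_c,
               predict(res$nmr$models$DLPC_noGlpG, ktab$cholesterol))
  expect_true(all(c("linear", "exponential") %in% names(res$kinetics$trends$all)))

  # trajectory arm: all requested observables present with provenance
  expect_s3_class(res$traj$order, "order_profile")
  expect_equal(res$traj$annulus$cutoff, 6)
  expect_equal(res$traj$provenance$cutoff, 6)
  expect_lt(abs(res$traj$kc$kc / res$traj$kc_truth - 1), 0.35)
  expect_lt(abs(res$traj$tilt$summary$mean_tilt_deg - 20), 0.5)

  # artefacts written
  expect_true(file.exists(file.path(out_dir, "nmr_chain_lengths.csv")))
  expect_true(file.exists(file.path(out_dir, "kinetics_tau_table.csv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  expect_true(file.exists(file.path(out_dir, "run.log.jsonl")))
  log_lines <- readLines(file.path(out_dir, "run.log.jsonl"))
  expect_true(all(vapply(log_lines, function(l)
    jsonlite::validate(l) == TRUE, logical(1))))

  # a rerun reproduces every numeric output
  res2 <- run_study(read_study_config(demo_config()))
  expect_identical(res$nmr$table$l_c, res2$nmr$table$l_c)
  expect_identical(res$kinetics$table$tau, res2$kinetics$table$tau)
  expect_identical(res$traj$kc$kc, res2$traj$kc$kc)
})

test_that("the kinetics arm demands its reference and thickness model", {
  cfg <- read_study_config(demo_config())
  cfg$kinetics$reference <- NULL
  expect_error(run_kinetics_arm(cfg, NULL), "reference")
  cfg2 <- read_study_config(demo_config())
  cfg2$nmr <- NULL
  expect_error(run_study(cfg2), "thickness model")
})
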