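#' Read and validate a study configuration
#'
#' A single YAML file describes the three study arms (NMR thickness,
#' cleavage kinetics, trajectory observables): a sample table per arm with
#' labels, lipid species, cholesterol content and either an input path or a
#' generator spec, plus stage parameters (quadrupolar coupling, annular
#' cutoff, q-window, seeds) and an output directory.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated config, class `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  for (arm in c("nmr", "kinetics")) {
    samples <- cfg[[arm]]$samples
    if (is.null(samples)) next
    labels <- vapply(samples, function(s) s$label %||% "", character(1))
    if (any(!nzchar(labels))) {
      stop(sprintf("%s arm: every sample needs a label", arm), call. = FALSE)
    }
    if (anyDuplicated(labels)) {
      stop(sprintf("%s arm: duplicate sample labels: %s", arm,
                   paste(unique(labels[duplicated(labels)]), collapse = ", ")),
           call. = FALSE)
    }
    for (s in samples) {
      if (is.null(s$path) && is.null(s$generator)) {
        stop(sprintf("%s sample '%s': needs a path or a generator spec",
                     arm, s$label), call. = FALSE)
      }
      if (!is.null(s$path) && !file.exists(s$path)) {
        stop(sprintf("%s sample '%s': path '%s' does not exist",
                     arm, s$label, s$path), call. = FALSE)
      }
    }
  }
  structure(cfg, class = c("study_config", "list"))
}

log_event <- function(log_con, stage, event, ...) {
  if (is.null(log_con)) return(invisible(NULL))
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), log_con)
  invisible(NULL)
}

#' Run the NMR thickness arm
#'
#' For every sample: obtain the ²H powder spectrum (from a file or the
#' seeded generator), dePake it, extract the smoothed order profile, and
#' project it onto the acyl chain length via the first-order mean-torque
#' model; then fit the thickness-versus-cholesterol regression per
#' (lipid, protease) group with at least two cholesterol levels. Every
#' output row records the sample parameters and the derived seed.
#'
#' @param config a [read_study_config()] result (or compatible list).
#' @param log_con optional connection for JSON-lines logging.
#' @return list: `table` (label, lipid, cholesterol, glpg, l_c, seed),
#'   `profiles` (named list of [order_profile()]), `models` (named list of
#'   [fit_thickness_model()] per group), `provenance`.
#' @export
run_nmr_arm <- function(config, log_con = NULL) {
  arm <- config$nmr
  if (is.null(arm$samples) || !length(arm$samples)) {
    stop("nmr arm: empty sample table", call. = FALSE)
  }
  chi_q <- arm$chi_q %||% 167
  broadening <- arm$broadening %||% 0.5
  snr <- arm$snr %||% 50
  ax <- arm$axis %||% list(min = -60, max = 60, n = 1025L)
  axis <- seq(ax$min, ax$max, length.out = as.integer(ax$n))
  rows <- list()
  profiles <- list()
  for (i in seq_along(arm$samples)) {
    s <- arm$samples[[i]]
    seed_i <- config$seed + i
    if (!is.null(s$path)) {
      spec <- read_spectrum(s$path)
      input_hash <- unname(tools::md5sum(s$path))
    } else {
      g <- s$generator
      prof <- gen_order_profile(n_carbons = s$n_carbons %||% 12L,
                                plateau_s = g$plateau_s %||% 0.21,
                                methyl_s = g$methyl_s %||% 0.05,
                                plateau_end = g$plateau_end %||% 8L,
                                scale = g$scale %||% 1,
                                seed = seed_i)
      spec <- gen_2h_spectrum(prof, chi_q = chi_q, broadening = broadening,
                              snr = snr, axis = axis, seed = seed_i)
      input_hash <- NA_character_
    }
    dp <- depake(spec)
    prof_out <- extract_smoothed_order_profile(dp, n_carbons = s$n_carbons %||% 12L,
                                               chi_q = chi_q)
    lc <- projected_chain_length(prof_out)
    profiles[[s$label]] <- prof_out
    rows[[i]] <- data.frame(label = s$label, lipid = s$lipid %||% "DLPC",
                            cholesterol = s$cholesterol %||% 0,
                            glpg = isTRUE(s$glpg), l_c = lc$l_c,
                            seed = seed_i, input_hash = input_hash)
    log_event(log_con, "nmr", "sample_done", label = s$label, l_c = lc$l_c,
              seed = seed_i)
  }
  table <- do.call(rbind, rows)
  models <- list()
  for (grp in split(table, paste(table$lipid, table$glpg, sep = "_"))) {
    if (length(unique(grp$cholesterol)) >= 2L) {
      key <- paste(grp$lipid[1], if (grp$glpg[1]) "GlpG" else "noGlpG", sep = "_")
      models[[key]] <- fit_thickness_model(grp$cholesterol, grp$l_c)
      log_event(log_con, "nmr", "thickness_model", group = key,
                slope = models[[key]]$slope, r2 = models[[key]]$r_squared)
    }
  }
  list(table = table, profiles = profiles, models = models,
       provenance = list(seed = config$seed, chi_q = chi_q,
                         broadening = broadening, snr = snr))
}

#' Run the kinetics arm
#'
#' Fits the single-exponential cleavage model to every progress curve,
#' normalises the time constants to the reference sample, maps each
#' sample's cholesterol content onto leaflet thickness via the supplied
#' thickness model, and fits both trend models (linear, exponential decay)
#' of tau/tau0 versus thickness. Exclusion masks are explicit caller input,
#' recorded in the output.
#'
#' @param config a [read_study_config()] result.
#' @param thickness_model a [fit_thickness_model()] result used to map
#'   cholesterol to l_c (or a named list of them keyed by lipid).
#' @param log_con optional JSON-lines connection.
#' @return list: `table` (label, cholesterol, tau, tau_se, tau_ratio,
#'   tau_ratio_se, l_c), `trends`, `provenance`.
#' @export
run_kinetics_arm <- function(config, thickness_model, log_con = NULL) {
  arm <- config$kinetics
  if (is.null(arm$samples) || !length(arm$samples)) {
    stop("kinetics arm: empty sample table", call. = FALSE)
  }
  if (is.null(arm$reference)) stop("kinetics arm: reference label required", call. = FALSE)
  fits <- list()
  meta_rows <- list()
  for (i in seq_along(arm$samples)) {
    s <- arm$samples[[i]]
    seed_i <- config$seed + 1000L + i
    curve <- if (!is.null(s$path)) {
      read_progress_curve(s$path)
    } else {
      g <- s$generator
      gen_progress_curve(i_max = g$i_max %||% 1000, i_0 = g$i_0 %||% 800,
                         tau = g$tau %||% 600, window = g$window %||% 1800,
                         n_points = g$n_points %||% 60L,
                         noise_frac = g$noise_frac %||% 0.02,
                         seed = seed_i,
                         sample_meta = list(label = s$label))
    }
    fits[[s$label]] <- fit_single_exponential(curve)
    meta_rows[[i]] <- data.frame(label = s$label, lipid = s$lipid %||% "DLPC",
                                 cholesterol = s$cholesterol %||% 0,
                                 seed = seed_i)
    log_event(log_con, "kinetics", "fit_done", label = s$label,
              tau = fits[[s$label]]$tau)
  }
  ratio <- normalize_tau(fits, arm$reference)
  meta <- do.call(rbind, meta_rows)
  table <- merge(meta, ratio, by = "label", sort = FALSE)
  predict_lc <- function(lipid, chol) {
    tm <- if (inherits(thickness_model, "thickness_model")) thickness_model
    else thickness_model[[lipid]] %||% thickness_model[[1]]
    predict(tm, chol)
  }
  table$l_c <- mapply(predict_lc, table$lipid, table$cholesterol)
  masks <- arm$masks %||% list(all = rep(TRUE, nrow(table)))
  trends <- lapply(masks, function(m) {
    m <- if (is.character(m)) !(table$label %in% m) else as.logical(m)
    trend_fits(table$l_c, table$tau_ratio, mask = m)
  })
  log_event(log_con, "kinetics", "trends_done", n = nrow(table))
  list(table = table, trends = trends,
       provenance = list(seed = config$seed, reference = arm$reference,
                         thickness_mapping = "ThicknessModel.predict on sample cholesterol"))
}

#' Run the trajectory-observables arm
#'
#' Generates (or reads) bilayer frames and computes the requested analyses:
#' `order` (segmental order parameters), `annulus` (annular/bulk
#' classification and composition), `pn` (P-N angle histogram), `tilt`
#' (helix tilt on an ideal-helix fixture or supplied ranges), `rdf`
#' (residue-pair radial distribution), `kc` (bending modulus from
#' Helfrich-sampled surfaces).
#'
#' @param config a [read_study_config()] result.
#' @param log_con optional JSON-lines connection.
#' @return named list of analysis results plus `provenance`.
#' @export
run_traj_arm <- function(config, log_con = NULL) {
  arm <- config$traj
  if (is.null(arm)) stop("traj arm: missing config section", call. = FALSE)
  analyses <- arm$analyses %||% c("order", "annulus", "pn", "kc")
  known <- c("order", "annulus", "pn", "tilt", "rdf", "kc")
  bad <- setdiff(analyses, known)
  if (length(bad)) {
    stop(sprintf("unknown analysis name(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  seed_t <- config$seed + 5000L
  g <- arm$generator %||% list()
  traj <- if (!is.null(arm$path)) {
    read_frames_pdb(arm$path)
  } else {
    gen_bilayer_frames(
      n_lipids_per_leaflet = g$n_lipids_per_leaflet %||% 49L,
      chol_fraction = g$chol_fraction %||% 0.15,
      wobble_kappa = g$wobble_kappa %||% 8,
      protein = g$protein,
      depletion_radius = g$depletion_radius,
      n_frames = g$n_frames %||% 5L,
      n_carbons = g$n_carbons %||% 12L,
      seed = seed_t)
  }
  cutoff <- arm$cutoff %||% 6
  n_carbons <- g$n_carbons %||% 12L
  out <- list()
  if ("order" %in% analyses) {
    out$order <- acyl_order_parameters(traj, synthetic_chain_selector(n_carbons))
    log_event(log_con, "traj", "order_done",
              plateau = mean(out$order$s_cd[!out$order$is_methyl]))
  }
  if ("annulus" %in% analyses) {
    prot_sel <- list(resname = "GLPG")
    out$annulus <- annulus_composition(traj, prot_sel, cutoff = cutoff)
    log_event(log_con, "traj", "annulus_done",
              annular_chol_pct = out$annulus$annular_chol_pct)
  }
  if ("pn" %in% analyses) {
    out$pn <- pn_angle_histogram(traj, lipid_selector = list(resname = "DLPC"))
    log_event(log_con, "traj", "pn_done", n_angles = length(out$pn$angles))
  }
  if ("tilt" %in% analyses) {
    tilt_deg <- arm$tilt_deg %||% 20
    helix <- gen_ideal_helix(n_res = 18L, tilt_deg = tilt_deg, seed = seed_t)
    out$tilt <- helix_tilt(helix, list(tm = c(1L, 18L)))
    log_event(log_con, "traj", "tilt_done",
              mean_tilt = out$tilt$summary$mean_tilt_deg[1])
  }
  if ("rdf" %in% analyses) {
    out$rdf <- residue_pair_rdf(traj, list(atomname = "P"), list(atomname = "N"),
                                r_max = arm$rdf_rmax %||% 10,
                                bin_width = arm$rdf_bin %||% 0.25)
    log_event(log_con, "traj", "rdf_done")
  }
  if ("kc" %in% analyses) {
    h <- arm$helfrich %||% list()
    surf <- gen_helfrich_surfaces(box_l = h$box_l %||% 25,
                                  grid_n = h$grid_n %||% 32L,
                                  kc = h$kc %||% 20, gamma = h$gamma %||% 0,
                                  n_frames = h$n_frames %||% 300L,
                                  seed = seed_t + 1L)
    spec <- undulation_spectrum(surf)
    out$kc <- fit_bending_modulus(spec, temperature = arm$temperature %||% 310)
    out$kc_truth <- surf$truth$kc
    log_event(log_con, "traj", "kc_done", kc = out$kc$kc)
  }
  out$provenance <- list(seed = seed_t, cutoff = cutoff, analyses = analyses,
                         generator = g)
  out
}

#' Run a full synthetic study from one configuration
#'
#' Orchestrates the three arms end to end: NMR spectra to thickness models,
#' kinetics to the tau/tau0 versus thickness table and trend fits, and the
#' trajectory observable bundle. Deterministic for a fixed config (all
#' stage seeds derive from the config seed). If `output_dir` is set in the
#' config, tidy CSV tables, a JSON run manifest and a JSON-lines log are
#' written there.
#'
#' @param config path to a YAML config, or a [read_study_config()] result.
#' @return list with elements `nmr`, `kinetics`, `traj`, `manifest`.
#' @export
run_study <- function(config) {
  cfg <- if (inherits(config, "study_config")) config else read_study_config(config)
  out_dir <- cfg$output_dir
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "run.log.jsonl"), "w")
    on.exit(close(log_con))
  }
  res <- list()
  if (!is.null(cfg$nmr)) {
    res$nmr <- run_nmr_arm(cfg, log_con)
  }
  if (!is.null(cfg$kinetics)) {
    tm <- res$nmr$models
    if (is.null(tm) || !length(tm)) {
      stop("kinetics arm requires a thickness model from the nmr arm", call. = FALSE)
    }
    names(tm) <- sub("_(GlpG|noGlpG)$", "", names(tm))
    tm <- tm[!duplicated(names(tm))]
    res$kinetics <- run_kinetics_arm(cfg, tm, log_con)
  }
  if (!is.null(cfg$traj)) {
    res$traj <- run_traj_arm(cfg, log_con)
  }
  res$manifest <- list(seed = cfg$seed,
                       arms = names(res),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(out_dir)) {
    if (!is.null(res$nmr)) {
      utils::write.csv(res$nmr$table, file.path(out_dir, "nmr_chain_lengths.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$kinetics)) {
      utils::write.csv(res$kinetics$table, file.path(out_dir, "kinetics_tau_table.csv"),
                       row.names = FALSE)
    }
    manifest <- res$manifest
    manifest$config <- unclass(cfg)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  res
}
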