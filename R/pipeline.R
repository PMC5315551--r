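#' Configuration of a full reproducible run
#'
#' Bundles every knob of the simulate -> behavior -> ERP -> stats -> BMS
#' chain under one master seed. All module seeds are derived from it by
#' stable hashing, so a config reproduces a run bit-for-bit.
#'
#' @param seed master seed.
#' @param n_subjects cohort size.
#' @param task a [task_config()].
#' @param params OFF-stimulation [race_params()].
#' @param on_effects list(rt_shift, ssrt_shift) in ms.
#' @param n_channels,noise_sd EEG generator settings (templates are built
#'   from [erp_templates()] with this channel count).
#' @param eeg_subjects how many subjects get synthesized EEG (the EEG stage
#'   is the expensive one; default all).
#' @param bms list of evidence-generator and sampler settings: true_model,
#'   effect_nats, noise_nats, n_samples.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_subjects = 12,
                       task = task_config(), params = race_params(),
                       on_effects = list(rt_shift = 50, ssrt_shift = 53),
                       n_channels = 96, noise_sd = 1,
                       eeg_subjects = n_subjects,
                       bms = list(true_model = "both_efferent",
                                  effect_nats = 5, noise_nats = 1,
                                  n_samples = 1e5)) {
  structure(list(seed = seed, n_subjects = n_subjects, task = task,
                 params = params, on_effects = on_effects,
                 n_channels = n_channels, noise_sd = noise_sd,
                 eeg_subjects = min(eeg_subjects, n_subjects), bms = bms),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates a paired ON/OFF cohort, writes the trial table, computes the
#' behavioral summary and paired condition statistics, synthesizes EEG for
#' the requested subjects and runs the Go-process correction, GFP and peak
#' measures, then performs RFX-BMS, family inference and BMA on a synthetic
#' evidence matrix over the cortico-BG model space. Every output is a plain
#' CSV/JSON/YAML file and a manifest records paths, md5 hashes and versions.
#'
#' @param cfg a [run_config()].
#' @param out_dir writable output directory (created if absent).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable")
  p <- function(...) file.path(out_dir, ...)

  cohort <- simulate_cohort(cfg$n_subjects, cfg$task, cfg$params,
                            cfg$on_effects, seed = derive_seed(cfg$seed, "cohort"))
  write_trials(cohort, p("trials.csv"))

  behavior <- cohort_behavior(cohort)
  data.table::fwrite(behavior, p("behavior.csv"))

  stats <- compare_conditions(behavior)
  data.table::fwrite(stats, p("stats.csv"))

  templates <- erp_templates(n_channels = cfg$n_channels)
  subjects <- unique(vapply(cohort, function(s) s$subject_id, ""))
  peaks_rows <- list()
  gfp_rows <- list()
  for (s in cohort) {
    if (!s$subject_id %in% subjects[seq_len(cfg$eeg_subjects)]) next
    eeg <- synthesize_eeg(s, templates, noise_sd = cfg$noise_sd,
                          seed = derive_seed(cfg$seed, "eeg"))
    corr <- suppressWarnings(go_correction(eeg$stop, eeg$go, session = s))
    if (is.null(corr$erp_ss)) next
    gfp <- compute_gfp(corr$erp_ss)
    pk <- measure_peaks(gfp)
    pk$subject <- s$subject_id
    pk$condition <- s$condition
    peaks_rows[[length(peaks_rows) + 1L]] <- pk
    gfp_rows[[length(gfp_rows) + 1L]] <- data.frame(
      subject = s$subject_id, condition = s$condition,
      time_ms = gfp$times, gfp = gfp$values)
    if (s$subject_id == subjects[1])
      write_erp_csv(corr$erp_ss, p(sprintf("erp_ss_%s_%s.csv", s$subject_id,
                                           s$condition)))
  }
  data.table::fwrite(do.call(rbind, peaks_rows), p("peaks.csv"))
  data.table::fwrite(do.call(rbind, gfp_rows), p("gfp.csv"))

  space <- build_model_space()
  model_space_to_yaml(space, p("model_space.yaml"))
  lnE <- simulate_evidences(space, cfg$bms$true_model,
                            effect_nats = cfg$bms$effect_nats,
                            noise_nats = cfg$bms$noise_nats,
                            n_subjects = cfg$n_subjects,
                            seed = derive_seed(cfg$seed, "bms"))
  bms_res <- rfx_bms(lnE, n_samples = cfg$bms$n_samples,
                     seed = derive_seed(cfg$seed, "bms_xp"))
  fam_res <- family_bms(lnE, space$families, n_samples = cfg$bms$n_samples,
                        seed = derive_seed(cfg$seed, "fam_xp"))
  win_family <- names(which.max(fam_res$family_exceedance))
  params_df <- simulate_dcm_params(space, n_subjects = cfg$n_subjects,
                                   seed = derive_seed(cfg$seed, "params"))
  bma_res <- bma(params_df, lnE, space$families[[win_family]])
  jsonlite::write_json(
    list(exceedance = as.list(bms_res$exceedance),
         expected_freq = as.list(bms_res$expected_freq),
         family_exceedance = as.list(fam_res$family_exceedance),
         winning_family = win_family,
         bma_group_summary = bma_res$group_summary,
         bma_tests = bma_res$tests),
    p("bms.json"), auto_unbox = TRUE, digits = NA)

  write_run_config(cfg, p("config.yaml"))
  files <- c("trials.csv", "behavior.csv", "stats.csv", "peaks.csv",
             "gfp.csv", "model_space.yaml", "bms.json", "config.yaml")
  manifest <- list(
    seed = cfg$seed,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)),
    package_version = as.character(utils::packageVersion("stopsignal")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
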