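#' Pipeline configuration
#'
#' Assembles (and validates) the configuration of the end-to-end pipeline:
#' schedule -> simulate -> preprocess -> score -> habituation / PPI -> report.
#' A run is reproducible from config + seed alone.
#'
#' @param n_subjects number of simulated subjects.
#' @param fs sampling rate of the synthetic recordings, Hz.
#' @param seed master seed; per-subject and per-stage seeds are derived.
#' @param schedule list of [schedule_config()] overrides.
#' @param noise list of [noise_model()] overrides.
#' @param filter list of [filter_config()] overrides (`fs` and the comb
#'   fundamental default to the simulation's values).
#' @param scoring list of [scoring_config()] overrides.
#' @param profiles list of [sample_profiles()] overrides (cohort ranges).
#' @param stats list: `log_base` (10), `c_mode` ("unstandardised"), `center`
#'   ("subject"), `mode` ("amplitude").
#' @param write_signals write per-run signal CSVs (large; off by default).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 6, fs = 10000, seed = 1,
                            schedule = list(), noise = list(),
                            filter = list(), scoring = list(),
                            profiles = list(), stats = list(),
                            write_signals = FALSE) {
  st <- utils::modifyList(list(log_base = 10, c_mode = "unstandardised",
                               center = "subject", mode = "amplitude"), stats)
  structure(list(n_subjects = as.integer(n_subjects), fs = fs,
                 seed = as.integer(seed), schedule = schedule, noise = noise,
                 filter = filter, scoring = scoring, profiles = profiles,
                 stats = st, write_signals = isTRUE(write_signals)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

build_stage_objects <- function(config) {
  sched_cfg <- do.call(schedule_config, config$schedule)
  noise <- do.call(noise_model, config$noise)
  filt_args <- utils::modifyList(
    list(fs = config$fs, comb_fundamental = noise$gradient_fundamental,
         comb_harmonics = noise$gradient_harmonics), config$filter)
  list(schedule = sched_cfg, noise = noise,
       filter = do.call(filter_config, filt_args),
       scoring = do.call(scoring_config, config$scoring))
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Builds the session schedule, simulates each subject's EMG, runs the
#' conditioning chain, scores every trial, applies the exclusion rules, fits
#' habituation slopes with intercept correction, computes the PPI table, and
#' runs the group statistics battery. All stage outputs are written as
#' tab-delimited text / JSON under `out_dir`, plus a run manifest with config
#' and output hashes.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @param out_dir output directory (created if missing).
#' @param seed optional override of `config$seed`.
#' @return the manifest, invisibly (list: versions, config_hash, stages,
#'   outputs with md5 hashes, warnings).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warn <- character(0)
  note <- function(msg) warn <<- c(warn, msg)
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)

  obj <- build_stage_objects(config)

  # -- schedule ---------------------------------------------------------------
  session <- build_session(seed = derive_seed(config$seed, 1L),
                           config = obj$schedule)
  for (r in 1:3)
    write_events_tsv(session$runs[[r]],
                     file.path(out_dir, sprintf("events_run-%d.tsv", r)))
  done("schedule")

  # -- simulate / preprocess / score ------------------------------------------
  prof_args <- utils::modifyList(list(n = config$n_subjects,
                                      seed = derive_seed(config$seed, 2L)),
                                 config$profiles)
  profiles <- do.call(sample_profiles, prof_args)
  all_scores <- list()
  summaries <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("sub-%02d", s)
    sim <- simulate_subject(profiles[[s]], session, obj$noise,
                            seed = derive_seed(config$seed, 10L + s),
                            fs = config$fs, cfg = obj$filter)
    envs <- lapply(sim$recordings, preprocess_emg, cfg = obj$filter)
    if (config$write_signals)
      for (r in 1:3)
        write_signal_csv(sim$recordings[[r]],
                         file.path(out_dir, sprintf("%s_run-%d_emg.csv", sid, r)))
    sc <- withCallingHandlers(
      score_session(envs, session, obj$scoring),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    ps <- participant_summary(sc, obj$scoring, subject = sid)
    sc$subject <- sid
    all_scores[[s]] <- sc
    summaries[[s]] <- data.frame(subject = sid,
                                 response_probability_pulse =
                                   ps$response_probability_pulse,
                                 included = ps$included)
    write_tsv_units(sc[, c("subject", "run", "index_in_run", "trial_type",
                           "soa_ms", "baseline_mean", "peak_amp",
                           "onset_latency_ms", "responded", "rejected",
                           "reject_reason")],
                    file.path(out_dir, paste0(sid, "_scores.tsv")),
                    "per-trial scores; baseline_mean, peak_amp in mV; onset_latency_ms, soa_ms in ms")
  }
  summary_df <- do.call(rbind, summaries)
  write_tsv_units(summary_df, file.path(out_dir, "summary.tsv"),
                  "participant summary; response probability is a fraction")
  done("simulate+preprocess+score")

  scores <- do.call(rbind, all_scores)
  included <- summary_df$subject[summary_df$included]
  if (length(included) < nrow(summary_df))
    note(paste("excluded non-responders:",
               paste(setdiff(summary_df$subject, included), collapse = ", ")))
  inc_scores <- scores[scores$subject %in% included, ]

  # -- habituation ------------------------------------------------------------
  hab_json <- NULL
  if (length(included) >= 3) {
    fits <- lapply(included, function(sid) tryCatch({
      sc <- inc_scores[inc_scores$subject == sid & inc_scores$trial_type == "pulse" &
                         !inc_scores$rejected, ]
      elicit <- inc_scores[inc_scores$subject == sid &
                             is_eliciting(inc_scores$trial_type), ]
      ords <- seq_len(nrow(elicit))
      key <- paste(elicit$run, elicit$index_in_run)
      amp <- if (config$stats$mode == "amplitude") sc$peak_amp
             else ifelse(sc$responded, sc$peak_amp, 0)
      keep <- if (config$stats$mode == "amplitude") sc$responded else rep(TRUE, nrow(sc))
      fit_habituation(amp[keep],
                      ordinals = ords[match(paste(sc$run, sc$index_in_run)[keep], key)],
                      log_base = config$stats$log_base, subject = sid)
    }, error = function(e) {
      note(paste0(sid, ": habituation fit skipped (", conditionMessage(e), ")"))
      NULL
    }))
    fits <- Filter(Negate(is.null), fits)
    fit_subjects <- vapply(fits, function(f) as.character(f$subject), "")
  } else fits <- list()
  if (length(fits) >= 3) {
    cohort <- correct_slopes(fits, mode = config$stats$c_mode,
                             center = config$stats$center)
    write_tsv_units(data.frame(subject = cohort$subject, a = cohort$a,
                               b = cohort$b, b_prime = cohort$b_prime,
                               n_trials_used = vapply(fits, `[[`, 0L, "n_trials_used")),
                    file.path(out_dir, "habituation.tsv"),
                    "habituation fits; a in mV; b, b_prime in mV/log10(trial)")
    run_mat <- t(vapply(fit_subjects, function(sid) {
      cm <- condition_means(inc_scores[inc_scores$subject == sid, ],
                            mode = config$stats$mode)
      cm$mean_amp[cm$trial_type == "pulse"][match(1:3, cm$run[cm$trial_type == "pulse"])]
    }, numeric(3)))
    tt <- one_sample_t(cohort$b_prime)
    fr <- friedman_test(run_mat)
    prm <- pulse_run_means(run_mat)
    hab_json <- list(
      slope = list(mean_b = mean(cohort$b), mean_b_prime = mean(cohort$b_prime),
                   t = tt$t, df = tt$df, p = tt$p, d = tt$d),
      friedman = list(chi2 = fr$chi2, df = fr$df, p = fr$p),
      run_means = prm)
    jsonlite::write_json(rapply(hab_json, function(z) signif(z, 6), "numeric",
                                how = "replace"),
                         file.path(out_dir, "group_habituation.json"),
                         auto_unbox = TRUE, digits = NA)
    done("habituation")
  } else note("fewer than 3 subjects with usable habituation fits: cohort stage skipped")

  # -- PPI --------------------------------------------------------------------
  ppi_json <- NULL
  if (length(included) >= 3) {
    ptab <- withCallingHandlers(
      ppi_table(inc_scores, mode = config$stats$mode),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    write_tsv_units(ptab, file.path(out_dir, "ppi.tsv"),
                    "PPI table; pulse_mean, ppi_mean in mV; ppi_percent in %")
    m <- ppi_overall_matrix(ptab)
    iccs <- lapply(sort(unique(ptab$soa_ms)), function(soa) {
      per_run <- ptab[ptab$soa_ms == soa & ptab$run != "overall", ]
      w <- matrix(per_run$ppi_percent, ncol = 3, byrow = TRUE,
                  dimnames = list(unique(per_run$subject), paste0("run", 1:3)))
      if (anyNA(w)) return(NULL)
      ic <- icc_consistency_single(w)
      list(soa_ms = soa, icc = ic$icc, ci95 = ic$ci95)
    })
    tests <- soa_nonzero_tests(ptab)
    anova <- if (nrow(m) > ncol(m)) rm_anova_covariates(m) else NULL
    ppi_json <- list(
      soa_tests = tests,
      icc = Filter(Negate(is.null), iccs),
      anova = if (!is.null(anova))
        list(F = anova$F, df1 = anova$df1, df2 = anova$df2, p = anova$p,
             epsilon = anova$epsilon, pairwise = anova$pairwise))
    jsonlite::write_json(rapply(ppi_json, function(z) signif(z, 6), "numeric",
                                how = "replace"),
                         file.path(out_dir, "group_ppi.json"),
                         auto_unbox = TRUE, digits = NA)
    done("ppi")
  } else note("fewer than 3 included subjects: PPI group stage skipped")

  # -- manifest ---------------------------------------------------------------
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "startlekit",
    version = as.character(utils::packageVersion("startlekit")),
    config = unclass(config),
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = stages,
    outputs = as.list(tools::md5sum(file.path(out_dir, outputs))),
    warnings = warn)
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(cfg_file)
  invisible(manifest)
}
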