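#' Pipeline configuration
#'
#' Parameters for the end-to-end synthetic two-arm ("WT" vs "KO") analysis
#' run. Analysis-stage defaults are the study conventions (0.2 fF step
#' threshold, 15 ms pore-kinetics rule, 10 pA / 100-spike amperometry
#' criteria, last-10 / last-5 steady states, and so on); the KO arm of the
#' generator scales fission-pore durations by 1.6, positive-voltage
#' conductance loss by 0.2, the endocytic time constant by 1.75, and the
#' train steady states by 0.44 (IPSC) and 0.64 (iGluSnFR) relative to WT.
#'
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param out_dir output directory.
#' @param n_cells cells per arm for the fission stage.
#' @param n_per_voltage drift measurements per voltage and arm.
#' @param n_boutons boutons per arm for the pHluorin stage.
#' @param n_trains trains per arm and modality.
#' @param min_step capacitance detection threshold, farads.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("sqrun"),
                            n_cells = 6L, n_per_voltage = 8L,
                            n_boutons = 12L, n_trains = 8L,
                            min_step = 0.2e-15) {
  if (min_step <= 0) stop("min_step must be positive")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_cells = n_cells, n_per_voltage = n_per_voltage,
                 n_boutons = n_boutons, n_trains = n_trains,
                 min_step = min_step,
                 ko = list(duration_x = 1.6, pos_drift_x = 0.2,
                           tau_endo_x = 1.75, a_ss_ipsc_x = 0.44,
                           a_ss_iglu_x = 0.64)),
            class = "pipeline_config")
}

stage_seed <- function(config, k, i = 0L) {
  (abs(config$seed) %% 10000L) * 100000L + k * 1000L + i
}

#' Run the full synthetic WT-vs-KO analysis pipeline
#'
#' Generates the two-arm synthetic cohort, runs every analysis stage
#' (fission-pore durations, drift I-V, pHluorin endocytic tau, IPSC and
#' iGluSnFR depression trains), compares arms with the statistics module,
#' and writes per-stage CSV tables, a JSON results summary, and a manifest
#' (package version, parameters, md5 digests of every written file). Runs
#' are deterministic in `config$seed`: two runs with the same seed produce
#' byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with per-stage results, the `effects` table of
#'   KO-vs-WT comparisons, and the manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  arms <- c("WT", "KO")
  ko <- config$ko

  ## stage 1: cell-attached fission-pore durations -------------------------
  fission <- do.call(rbind, lapply(arms, function(arm) {
    mult <- if (arm == "KO") ko$duration_x else 1
    do.call(rbind, lapply(seq_len(config$n_cells), function(ci) {
      cfg <- sim_config(seed = stage_seed(config, 1L,
                                          ci + 100L * (arm == "KO")),
                        sampling_rate = 5000, duration = 8,
                        noise_sd = 2 * pi * 20000 * 1e-15 / 25)
      durs <- with_seed(cfg$seed + 7L,
                        stats::rlnorm(3, log(0.035 * mult), 0.25))
      durs <- pmin(pmax(durs, 0.018), 0.15)
      evs <- lapply(seq_along(durs), function(k)
        pore_event(t_start = 1.5 + 2 * (k - 1), direction = "endocytic",
                   Cv = 1e-15, pore_duration = durs[k]))
      sim <- simulate_fission_trace(evs, cfg)
      det <- detect_capacitance_steps(sim$trace, min_step = config$min_step)
      det <- measure_all_pores(sim$trace, det)
      det <- det[det$direction == "endocytic" & det$kinetics_valid, ,
                 drop = FALSE]
      if (!nrow(det)) return(NULL)
      data.frame(arm = arm, cell = ci,
                 duration_ms = det$fission_pore_duration * 1e3)
    }))
  }))
  utils::write.csv(fission, file.path(config$out_dir, "fission_durations.csv"),
                   row.names = FALSE)
  log_dur <- log_transform(fission$duration_ms)
  fission_test <- ttest_unpaired(log_dur[fission$arm == "KO"],
                                 log_dur[fission$arm == "WT"])

  ## stage 2: drift I-V ----------------------------------------------------
  voltages <- c(-40, -20, 20, 40) * 1e-3
  g_model <- function(arm) {
    posx <- if (arm == "KO") ko$pos_drift_x else 1
    function(V) if (V > 0) 50e-12 * posx else 5e-12
  }
  drift <- do.call(rbind, lapply(arms, function(arm) {
    gm <- g_model(arm)
    do.call(rbind, lapply(seq_along(voltages), function(vi) {
      do.call(rbind, lapply(seq_len(config$n_per_voltage), function(ri) {
        cfg <- sim_config(seed = stage_seed(config, 2L,
                                            1000L * (arm == "KO") +
                                              vi * 50L + ri),
                          sampling_rate = 5000, duration = 1,
                          noise_sd = 0.15)
        sim <- simulate_patch_current(voltages[vi], gm, t_event = 0.5,
                                      baseline_slope = 0.5, cfg = cfg)
        m <- measure_current_drift(sim$trace)
        data.frame(arm = arm, V_patch = m$V_patch, delta_I = m$delta_I)
      }))
    }))
  }))
  utils::write.csv(drift, file.path(config$out_dir, "drift_iv.csv"),
                   row.names = FALSE)
  drift_tests <- lapply(split(drift, drift$V_patch), function(g)
    ttest_unpaired(g$delta_I[g$arm == "KO"], g$delta_I[g$arm == "WT"]))
  iv_wt <- build_iv(drift[drift$arm == "WT", ])
  rect_wt <- rectification_test(iv_wt)

  ## stage 3: pHluorin endocytic tau ---------------------------------------
  phl <- do.call(rbind, lapply(arms, function(arm) {
    tau <- 15 * if (arm == "KO") ko$tau_endo_x else 1
    stim <- stim_protocol(100, 20, onset = 10)
    do.call(rbind, lapply(seq_len(config$n_boutons), function(bi) {
      cfg <- sim_config(seed = stage_seed(config, 3L,
                                          bi + 100L * (arm == "KO")),
                        sampling_rate = 1, duration = 100, noise_sd = 10)
      sim <- simulate_phluorin_series(tau, stim, cfg = cfg, dF_max = 100)
      fit <- fit_endocytic_tau(normalize_response(sim$series,
                                                  "dF_over_dFmax"))
      data.frame(arm = arm, bouton = bi, tau = fit$tau,
                 flagged = fit$flagged)
    }))
  }))
  utils::write.csv(phl, file.path(config$out_dir, "endocytic_tau.csv"),
                   row.names = FALSE)
  tau_test <- ttest_unpaired(phl$tau[phl$arm == "KO"],
                             phl$tau[phl$arm == "WT"])

  ## stage 4: depression trains --------------------------------------------
  train_stage <- function(modality, n_stim, a_ss_wt, ko_x, last_n, koffs) {
    do.call(rbind, lapply(arms, function(arm) {
      a_ss <- a_ss_wt * if (arm == "KO") ko_x else 1
      do.call(rbind, lapply(seq_len(config$n_trains), function(ti) {
        a <- simulate_depressing_train(
          n_stim, a_ss, r = 0.9, noise_sd = 0.02,
          seed = stage_seed(config, 4L,
                            koffs + ti + 100L * (arm == "KO")))
        data.frame(arm = arm, train = ti, modality = modality,
                   steady_state = steady_state(a / a[1], last_n),
                   ppr = paired_pulse_ratio(a))
      }))
    }))
  }
  trains <- rbind(
    train_stage("ipsc", 250, 0.50, ko$a_ss_ipsc_x, 10, 0L),
    train_stage("iglusnfr", 50, 0.45, ko$a_ss_iglu_x, 5, 500L))
  utils::write.csv(trains, file.path(config$out_dir, "train_metrics.csv"),
                   row.names = FALSE)
  ss_tests <- lapply(split(trains, trains$modality), function(g)
    ttest_unpaired(g$steady_state[g$arm == "KO"],
                   g$steady_state[g$arm == "WT"]))

  ## effects table ----------------------------------------------------------
  mean_by <- function(df, col, arm) mean(df[[col]][df$arm == arm])
  pos_p <- vapply(drift_tests[c("20", "40")], `[[`, numeric(1), "p")
  neg_p <- vapply(drift_tests[c("-40", "-20")], `[[`, numeric(1), "p")
  effects <- data.frame(
    effect = c("fission_log_duration", "drift_positive_V",
               "endocytic_tau", "steady_state_ipsc",
               "steady_state_iglusnfr"),
    wt = c(mean(log_dur[fission$arm == "WT"]),
           mean_by(drift[drift$V_patch > 0, ], "delta_I", "WT"),
           mean_by(phl, "tau", "WT"),
           mean_by(trains[trains$modality == "ipsc", ], "steady_state", "WT"),
           mean_by(trains[trains$modality == "iglusnfr", ], "steady_state",
                   "WT")),
    ko = c(mean(log_dur[fission$arm == "KO"]),
           mean_by(drift[drift$V_patch > 0, ], "delta_I", "KO"),
           mean_by(phl, "tau", "KO"),
           mean_by(trains[trains$modality == "ipsc", ], "steady_state", "KO"),
           mean_by(trains[trains$modality == "iglusnfr", ], "steady_state",
                   "KO")),
    expected = c("higher", "lower", "higher", "lower", "lower"),
    p = c(fission_test$p, max(pos_p), tau_test$p,
          ss_tests$ipsc$p, ss_tests$iglusnfr$p))
  effects$observed <- ifelse(effects$ko > effects$wt, "higher", "lower")
  effects$detected <- effects$observed == effects$expected &
    effects$p < 0.05
  utils::write.csv(effects, file.path(config$out_dir, "effects.csv"),
                   row.names = FALSE)

  results <- list(
    fission_test = fission_test, drift_tests = drift_tests,
    drift_negative_p = neg_p, rectification_wt = rect_wt,
    tau_test = tau_test, ss_tests = ss_tests, effects = effects)
  jsonlite::write_json(
    list(effects = effects,
         rectification_wt = rect_wt,
         drift_negative_p = as.list(neg_p)),
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## manifest ----------------------------------------------------------------
  files <- c("fission_durations.csv", "drift_iv.csv", "endocytic_tau.csv",
             "train_metrics.csv", "effects.csv", "summary.json")
  paths <- file.path(config$out_dir, files)
  manifest <- list(
    package = "synaptoquant",
    version = as.character(utils::packageVersion("synaptoquant")),
    seed = config$seed,
    parameters = config[c("n_cells", "n_per_voltage", "n_boutons",
                          "n_trains", "min_step")],
    ko_model = config$ko,
    files = lapply(seq_along(files), function(i)
      list(name = files[i], md5 = unname(tools::md5sum(paths[i])))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$manifest <- manifest_path
  invisible(results)
}
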