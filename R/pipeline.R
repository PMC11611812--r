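#' Process one trial's trace
#'
#' Runs the per-trial chain: blink detection on the raw validity flags,
#' despiking/smoothing of the pupil channel, saccade detection on the gaze
#' channels, SRT computation and latency/direction classification, the
#' pupil-viability screen, and (for viable trials) extraction of the eight
#' pupil measures from the cleaned trace.
#'
#' @param trace Calibrated sample-trace tibble (pupil in mm).
#' @param trial One-row tibble with `condition`, `side`, `fp_on_ms`,
#'   `gap_on_ms`, `stim_on_ms`.
#' @param cfg A [run_config()].
#' @return The trial row augmented with classification, viability and
#'   measure columns.
#' @export
process_trial <- function(trace, trial, cfg = run_config()) {
  if ("is_direction_error" %in% names(trial)) {
    trial$planted_direction_error <- trial$is_direction_error
  }
  blinks <- detect_blinks(trace, pad_ms = cfg$blink_pad_ms)
  clean <- despike_and_smooth(
    trace, spike_threshold = cfg$spike_threshold_mm_per_ms,
    interp_max_ms = cfg$interp_max_ms,
    smooth_halfwidth = cfg$smooth_halfwidth_samples)
  saccades <- detect_saccades(
    clean, velocity_threshold = cfg$saccade_velocity_threshold_dps,
    min_duration_ms = cfg$saccade_min_duration_ms)
  trial <- classify_trial(trial, saccades,
                          min_amplitude = cfg$srt_min_amplitude_deg)
  trial <- flag_pupil_viability(trial, blinks, saccades,
                                max_fix_saccade_deg = cfg$srt_min_amplitude_deg)
  meas <- if (trial$pupil_viable) {
    extract_pupil_measures(clean, fp_on = trial$fp_on_ms,
                           stim_on = trial$stim_on_ms)
  } else {
    empty_measures_row()
  }
  dplyr::bind_cols(trial, meas)
}

empty_measures_row <- function() {
  tibble(baseline_size = NA_real_, onset_latency = NA_real_,
         constriction_size = NA_real_, peak_constriction_time = NA_real_,
         peak_constriction_velocity = NA_real_, dilation_size = NA_real_,
         dilation_velocity = NA_real_, peak_dilation_velocity = NA_real_)
}

#' Process all trials of one participant
#'
#' Renders (or receives) each trial's trace, calibrates it when it carries
#' raw tracker units, and applies [process_trial()].
#'
#' @param trials Tibble of the participant's trial parameters (from
#'   [generate_cohort()]).
#' @param cohort_cfg The [cohort_config()] used to render traces.
#' @param cfg A [run_config()].
#' @param curve Optional [fit_calibration()] curve (required when traces
#'   carry device units).
#' @return Tibble of processed trial rows.
#' @export
process_participant <- function(trials, cohort_cfg, cfg = run_config(),
                                curve = NULL) {
  purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    trial <- trials[i, ]
    trace <- generate_trial_trace(trial, cohort_cfg)
    if (identical(attr(trace, "pupil_units"), "area")) {
      check_that(!is.null(curve),
                 "traces carry device units but no calibration curve given")
      trace <- apply_calibration(curve, trace)
    }
    process_trial(trace, trial, cfg)
  })
}

#' Run the complete IPAST pupil pipeline on a synthetic cohort
#'
#' Chains every stage end to end: cohort simulation, rig-level false-pupil
#' calibration, trace cleaning and event detection, trial classification
#' and exclusion, pupil-measure extraction and per-participant
#' aggregation, ANTI-effect tests, factor analysis of the 14 pupil
#' measures and of the 12 simulated saccade measures, pupil-by-saccade
#' factor correlations, GAM age trajectories of the pupil factor scores
#' with significant-period detection, a baseline-size sex-difference
#' window, and the participant-flow report. All randomness derives from
#' `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @param schedule An [age_schedule()].
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there as CSV.
#' @param progress Print stage messages.
#' @return A list with the stage outputs (see Details in the README).
#' @export
run_pipeline <- function(cfg = run_config(), schedule = age_schedule(),
                         out_dir = NULL, progress = FALSE) {
  say <- function(...) if (progress) inform(sprintf(...))
  cohort_cfg <- cohort_config(
    n_participants = cfg$n_participants,
    sampling_rate = cfg$sampling_rate,
    trials_per_block = cfg$trials_per_block,
    n_blocks = cfg$n_blocks,
    seed = cfg$seed,
    noise_sd = cfg$noise_sd,
    blink_rate = cfg$blink_rate,
    anticipatory_rate = cfg$anticipatory_rate,
    emit_device_units = cfg$emit_device_units)
  say("simulating cohort of %d participants", cfg$n_participants)
  cohort <- generate_cohort(cohort_cfg, schedule)

  calibration <- generate_calibration_recordings(2:12)
  curve <- fit_calibration(calibration)

  say("processing %d trials", nrow(cohort$trials))
  trials <- cohort$trials |>
    dplyr::group_split(.data$id) |>
    purrr::map_dfr(process_participant, cohort_cfg = cohort_cfg,
                   cfg = cfg, curve = curve)

  participants <- filter_participants(cohort$participants, trials,
                                      min_trials = cfg$min_viable_trials,
                                      moca_cutoff = cfg$moca_cutoff)
  report <- pipeline_report(participants)
  say("retained %d / %d participants", report$retained, report$enrolled)

  retained_ids <- participants$id[participants$retained]
  viable <- trials |>
    filter(.data$pupil_viable, .data$id %in% retained_ids)
  agg <- viable |>
    dplyr::group_split(.data$id) |>
    purrr::map(function(d) {
      a <- aggregate_participant(d)
      list(medians = mutate(a$medians, id = d$id[1], .before = 1),
           row = mutate(a$row, id = d$id[1], .before = 1))
    })
  medians <- purrr::map_dfr(agg, "medians")
  measure_rows <- purrr::map_dfr(agg, "row")

  effects <- anti_tbl <- NULL
  if (nrow(medians)) {
    effects <- anti_effect(medians |> filter(
      .data$measure %in% condition_split_measures()))
    if (length(unique(effects$id)) >= 6) {
      anti_tbl <- anti_effect_table(effects, alpha = cfg$alpha)
    }
  }

  complete_rows <- if (nrow(measure_rows)) {
    measure_rows[complete.cases(measure_rows), ]
  } else {
    measure_rows
  }
  pupil_fm <- pupil_scores <- NULL
  if (nrow(complete_rows) >= 20) {
    say("factor analysis on %d complete measure rows", nrow(complete_rows))
    pupil_fm <- fit_factor_model(complete_rows, gamma = cfg$oblimin_gamma)
    pupil_scores <- factor_scores(pupil_fm)
  }

  sacc_tbl <- sacc_fm <- sacc_scores <- NULL
  if (length(retained_ids) >= 20) {
    sacc_tbl <- generate_saccade_measure_table(
      n = length(retained_ids), seed = derive_seed(cfg$seed, 7001L),
      ids = retained_ids)
    sacc_fm <- fit_factor_model(sacc_tbl, n_factors = 4,
                                gamma = cfg$oblimin_gamma)
    sacc_scores <- factor_scores(sacc_fm)
  }

  fcor <- NULL
  if (!is.null(pupil_scores) && !is.null(sacc_scores)) {
    fcor <- factor_factor_correlation(pupil_scores, sacc_scores,
                                      alpha = cfg$alpha)
  }

  ages <- setNames(participants$age, participants$id)
  gams <- NULL
  if (!is.null(pupil_scores) && nrow(pupil_scores) >= 50 &&
      diff(range(ages[rownames(pupil_scores)])) >= 30) {
    say("fitting lifespan GAMs")
    gams <- purrr::imap(
      as.data.frame(pupil_scores),
      function(s, nm) {
        fit_gam(ages[rownames(pupil_scores)], s, k = cfg$gam_basis_dim,
                grid_n = cfg$gam_grid_n) |>
          derivative_significance(eps = cfg$derivative_eps_years,
                                  n_draws = cfg$derivative_draws,
                                  seed = derive_seed(cfg$seed, 8101L))
      })
  }

  sexes <- setNames(participants$sex, participants$id)
  sex_diff <- NULL
  baseline_tbl <- measure_rows |>
    mutate(age = ages[.data$id], sex = sexes[.data$id]) |>
    filter(is.finite(.data$baseline_size))
  if (nrow(baseline_tbl) >= 50 && length(unique(baseline_tbl$sex)) == 2 &&
      diff(range(baseline_tbl$age)) >= 30) {
    sex_diff <- sex_difference_window(
      baseline_tbl$age, baseline_tbl$baseline_size, baseline_tbl$sex,
      k = cfg$gam_basis_dim, grid_n = cfg$gam_grid_n,
      n_draws = cfg$derivative_draws, seed = derive_seed(cfg$seed, 8201L))
  }

  spline_fits <- NULL
  if (nrow(medians)) spline_fits <- medians |>
    mutate(age = ages[.data$id]) |>
    dplyr::rename(measure_value = "value") |>
    group_by(.data$measure) |>
    dplyr::group_modify(function(d, key) {
      smoothing_spline_fit(tibble(age = d$age, value = d$measure_value,
                                  condition = d$condition))
    }) |>
    ungroup()

  result <- list(
    config = cfg,
    config_hash = rlang::hash(unclass(cfg)),
    calibration_curve = curve,
    participants = participants,
    trials = trials,
    report = report,
    medians = medians,
    measure_rows = measure_rows,
    effects = effects,
    anti_effect_table = anti_tbl,
    pupil_factor_model = pupil_fm,
    pupil_scores = pupil_scores,
    saccade_table = sacc_tbl,
    saccade_factor_model = sacc_fm,
    saccade_scores = sacc_scores,
    factor_correlation = fcor,
    gam_fits = gams,
    sex_difference = sex_diff,
    spline_fits = spline_fits
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_csv(x, file.path(out_dir, name),
                                          progress = FALSE)
  w(result$participants, "participants.csv")
  qc <- result$trials |>
    select(dplyr::any_of(c("id", "trial_id", "block", "condition", "side",
                           "srt_ms", "latency_class", "is_direction_error",
                           "pupil_viable", "exclusion_reasons")))
  w(qc, "trial_qc.csv")
  meas_cols <- c("id", "trial_id", "condition",
                 pooled_measures(), condition_split_measures())
  w(result$trials |> filter(.data$pupil_viable) |>
      select(dplyr::any_of(meas_cols)), "trial_measures.csv")
  w(result$measure_rows, "measure_rows.csv")
  if (!is.null(result$effects)) w(result$effects, "anti_effects.csv")
  if (!is.null(result$anti_effect_table)) {
    w(result$anti_effect_table, "anti_effect_tests.csv")
  }
  if (!is.null(result$pupil_factor_model)) {
    fm <- result$pupil_factor_model
    w(as_tibble(fm$pattern, rownames = "measure"), "pupil_loadings.csv")
    w(tibble(measure = names(fm$communalities),
             communality = fm$communalities), "pupil_communalities.csv")
    w(as_tibble(result$pupil_scores, rownames = "id"), "pupil_scores.csv")
  }
  if (!is.null(result$saccade_factor_model)) {
    w(as_tibble(result$saccade_factor_model$pattern, rownames = "measure"),
      "saccade_loadings.csv")
  }
  if (!is.null(result$factor_correlation)) {
    fc <- result$factor_correlation
    long <- as_tibble(fc$rho, rownames = "pupil_factor") |>
      tidyr::pivot_longer(-"pupil_factor", names_to = "saccade_factor",
                          values_to = "rho")
    long$p_value <- as.vector(t(fc$p_value))
    long$significant <- as.vector(t(fc$significant))
    w(long, "factor_correlations.csv")
  }
  if (!is.null(result$gam_fits)) {
    g <- purrr::imap_dfr(result$gam_fits,
                         function(f, nm) mutate(f$grid, factor = nm,
                                                .before = 1))
    w(g, "gam_fits.csv")
    win <- purrr::imap_dfr(result$gam_fits,
                           function(f, nm) mutate(f$windows, factor = nm,
                                                  .before = 1))
    w(win, "gam_windows.csv")
  }
  if (!is.null(result$sex_difference)) {
    w(result$sex_difference$grid, "sex_difference.csv")
    w(result$sex_difference$windows, "sex_difference_windows.csv")
  }
  if (!is.null(result$spline_fits)) w(result$spline_fits, "spline_fits.csv")
  rep <- result$report
  yaml::write_yaml(c(list(config_hash = result$config_hash,
                          seed = result$config$seed),
                     unclass(rep)),
                   file.path(out_dir, "report.yaml"))
  invisible(out_dir)
}
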