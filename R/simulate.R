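#' Configuration for a synthetic IPAST cohort
#'
#' Bundles the knobs of the synthetic-data generator. Defaults reproduce the
#' IPAST acquisition setup: 500 Hz monocular sampling, two blocks of 120
#' trials, a 3.2 s trial with 1,000 ms fixation, a 200 ms gap and a stimulus
#' at 10 degrees eccentricity, ages spanning 5-93 years.
#'
#' @param n_participants Number of participants to simulate.
#' @param age_range Two-element numeric, years (default `c(5, 93)`).
#' @param sampling_rate Samples per second (default 500).
#' @param trials_per_block Trials per block, must be even so that conditions
#'   and stimulus sides can be balanced (default 120).
#' @param n_blocks Number of blocks (default 2).
#' @param seed Integer seed; every random draw in the generator flows from it.
#' @param noise_sd Gaussian noise added to the pupil trace, mm (default 0.02).
#' @param blink_rate Per-trial probability of a blink (default 0.2).
#' @param anticipatory_rate Per-trial probability that the saccade is
#'   anticipatory (launched before the stimulus can be processed).
#' @param gaze_noise_sd Gaussian noise on the gaze channels, degrees.
#' @param prop_female Probability that a participant is female.
#' @param baseline_between_sd Between-participant SD of the resting pupil
#'   diameter at fixed age and sex, mm (default 0.35).
#' @param emit_device_units If `TRUE`, traces carry raw tracker area units
#'   (via [device_area_map()]) instead of mm, so the calibration stage has
#'   work to do.
#' @param trial_duration_ms Trial length; the fixation epoch under analysis
#'   occupies the first 1,200 ms (default 3,200 ms).
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 50,
                          age_range = c(5, 93),
                          sampling_rate = 500,
                          trials_per_block = 120,
                          n_blocks = 2,
                          seed = 1L,
                          noise_sd = 0.02,
                          blink_rate = 0.2,
                          anticipatory_rate = 0.05,
                          gaze_noise_sd = 0.05,
                          prop_female = 0.5,
                          baseline_between_sd = 0.35,
                          emit_device_units = FALSE,
                          trial_duration_ms = 3200) {
  check_that(is.numeric(n_participants) && n_participants >= 1,
             "`n_participants` must be >= 1")
  check_that(length(age_range) == 2 && age_range[1] < age_range[2],
             "`age_range` must be an increasing pair of ages")
  check_that(sampling_rate > 0, "`sampling_rate` must be > 0")
  check_that(trials_per_block %% 2 == 0,
             "`trials_per_block` must be even (conditions and sides balanced)")
  check_that(n_blocks >= 1, "`n_blocks` must be >= 1")
  check_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  check_that(blink_rate >= 0 && blink_rate <= 1,
             "`blink_rate` must be a probability")
  structure(list(
    n_participants = as.integer(n_participants),
    age_range = as.numeric(age_range),
    sampling_rate = sampling_rate,
    trials_per_block = as.integer(trials_per_block),
    n_blocks = as.integer(n_blocks),
    seed = as.integer(seed),
    noise_sd = noise_sd,
    blink_rate = blink_rate,
    anticipatory_rate = anticipatory_rate,
    gaze_noise_sd = gaze_noise_sd,
    prop_female = prop_female,
    baseline_between_sd = baseline_between_sd,
    emit_device_units = isTRUE(emit_device_units),
    trial_duration_ms = trial_duration_ms,
    fp_on_ms = 0, gap_on_ms = 1000, stim_on_ms = 1200,
    stimulus_eccentricity_deg = 10
  ), class = "cohort_config")
}

#' Age schedule of the generative parameters
#'
#' Defines how the trial-generating parameters vary with age, sex and task
#' condition. The defaults emulate the trends the lifespan pupil literature
#' reports: baseline pupil diameter shrinking with age (steeply through
#' childhood, gradually after), a dilation component that is larger and
#' faster on ANTI than PRO trials with a task-modulation gap that shrinks
#' with age, saccadic reaction times following a U-shape over the lifespan
#' with ANTI slower than PRO, anti-saccade direction errors elevated in the
#' young and the old, and (by default) smaller pupils in girls than boys
#' before age 18.
#'
#' All functions are vectorised over `age`. Units: mm, mm/s, ms.
#'
#' @param baseline_mm,constriction_latency_ms,constriction_amplitude_mm,
#'   constriction_peak_ms,dilation_rate,anti_effect_gap,srt_mean,error_rate,
#'   sex_baseline_offset Replacement functions; see the function source for
#'   the default forms and signatures.
#' @return A list of class `age_schedule`.
#' @export
age_schedule <- function(baseline_mm = NULL,
                         constriction_latency_ms = NULL,
                         constriction_amplitude_mm = NULL,
                         constriction_peak_ms = NULL,
                         dilation_rate = NULL,
                         anti_effect_gap = NULL,
                         srt_mean = NULL,
                         error_rate = NULL,
                         sex_baseline_offset = NULL) {
  gap_fn <- anti_effect_gap %||% default_anti_gap
  sched <- list(
    # mm; steep childhood decline then gradual adult decline (senile miosis)
    baseline_mm = baseline_mm %||% function(age) {
      7.0 - 0.06 * (pmin(age, 20) - 5) - 0.012 * pmax(age - 20, 0)
    },
    # F - M difference in baseline, mm: -0.5 before 18, 0 after
    sex_baseline_offset = sex_baseline_offset %||% function(age, sex) {
      ifelse(sex == "F", -0.25, 0.25) * (age < 18)
    },
    constriction_latency_ms = constriction_latency_ms %||% function(age) {
      250 + 1.2 * pmax(age - 60, 0)
    },
    # mm; ANTI constricts slightly less than PRO, gap fading with age
    constriction_amplitude_mm = constriction_amplitude_mm %||%
      function(age, condition) {
        base <- 0.50 - 0.0015 * age
        gap <- 0.06 * pmax(1 - age / 60, 0)
        base - ifelse(condition == "ANTI", gap, 0)
      },
    # ms after FP onset; ANTI peaks slightly earlier; slow increase with age
    constriction_peak_ms = constriction_peak_ms %||% function(age, condition) {
      850 + 0.8 * age - ifelse(condition == "ANTI", 40, 0) * pmax(1 - age / 60, 0)
    },
    # mm/s dilation ramp; declines with age; ANTI = PRO + anti_effect_gap
    dilation_rate = dilation_rate %||% function(age, condition) {
      pro <- pmax(0.40 - 0.003 * age, 0.08)
      pro + ifelse(condition == "ANTI", gap_fn(age), 0)
    },
    anti_effect_gap = gap_fn,
    # ms; U-shape across the lifespan, ANTI slower
    srt_mean = srt_mean %||% function(age, condition) {
      base <- 180 + 3 * pmax(20 - age, 0) + 1.2 * pmax(age - 25, 0)
      base + ifelse(condition == "ANTI", 60, 0)
    },
    error_rate = error_rate %||% function(age, condition) {
      anti <- 0.10 + 0.25 * pmax(1 - age / 20, 0) + 0.004 * pmax(age - 60, 0)
      ifelse(condition == "ANTI", pmin(anti, 0.6), 0.03)
    }
  )
  validate_age_schedule(sched)
  structure(sched, class = "age_schedule")
}

default_anti_gap <- function(age) 0.12 * pmax(1 - age / 70, 0)

validate_age_schedule <- function(s) {
  ages <- seq(5, 93, by = 1)
  b <- s$baseline_mm(ages)
  check_that(all(diff(b) <= 1e-12), "baseline_mm must be nonincreasing in age")
  check_that(all(b >= 2 & b <= 12), "baseline_mm must stay within 2-12 mm")
  gap <- s$anti_effect_gap(ages)
  check_that(all(diff(gap) <= 1e-12),
             "anti_effect_gap must be nonincreasing in age")
  d_anti <- s$dilation_rate(ages, "ANTI")
  d_pro <- s$dilation_rate(ages, "PRO")
  check_that(all(d_anti - d_pro >= -1e-12),
             "ANTI dilation rate must be >= PRO at every age")
  invisible(s)
}

#' Generate a synthetic IPAST cohort
#'
#' Draws participants (age, sex, MoCA) and, for each, a balanced table of
#' trial-generating parameters: per block, half the trials are PRO and half
#' ANTI, with left/right stimulus sides balanced within condition, in
#' pseudo-random interleaved order. Trial parameters (baseline, constriction
#' latency/amplitude/peak time, dilation rate, SRT, direction errors, blinks)
#' are drawn from `schedule` evaluated at the participant's age.
#'
#' Traces are not materialised here; [generate_trial_trace()] renders any
#' trial row on demand, deterministically via its `trace_seed`.
#'
#' @param config A [cohort_config()].
#' @param schedule An [age_schedule()].
#' @param ages Optional explicit vector of ages (length `n_participants`);
#'   by default ages are drawn uniformly over `config$age_range`.
#' @return A list with `participants` (tibble: id, age, sex, moca) and
#'   `trials` (tibble of per-trial parameters for all participants).
#' @export
generate_cohort <- function(config, schedule = age_schedule(), ages = NULL) {
  check_that(inherits(config, "cohort_config"), "`config` must be a cohort_config")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  n <- config$n_participants
  if (is.null(ages)) {
    ages <- runif(n, config$age_range[1], config$age_range[2])
  } else {
    check_that(length(ages) == n, "`ages` must have length n_participants")
  }
  sex <- ifelse(runif(n) < config$prop_female, "F", "M")
  moca <- ifelse(ages > 18, pmin(pmax(round(rnorm(n, 27, 2.2)), 12), 30),
                 NA_real_)
  participants <- tibble(
    id = sprintf("P%04d", seq_len(n)),
    age = ages, sex = sex, moca = moca
  )
  trials <- purrr::map2_dfr(participants$id, seq_len(n), function(pid, i) {
    generate_participant_trials(pid, participants$age[i], participants$sex[i],
                                i, config, schedule)
  })
  list(participants = participants, trials = trials)
}

generate_participant_trials <- function(pid, age, sex, idx, config, schedule) {
  npb <- config$trials_per_block
  per_cell <- npb / 2L
  blocks <- purrr::map_dfr(seq_len(config$n_blocks), function(b) {
    cond <- rep(c("PRO", "ANTI"), each = per_cell)
    side <- c(rep(c("left", "right"), length.out = per_cell),
              rep(c("left", "right"), length.out = per_cell))
    ord <- sample.int(npb)
    tibble(block = b, condition = cond[ord], side = side[ord])
  })
  m <- nrow(blocks)
  cond <- blocks$condition
  base <- schedule$baseline_mm(age) +
    schedule$sex_baseline_offset(age, sex) +
    rnorm(1, 0, config$baseline_between_sd) + rnorm(m, 0, 0.08)
  base <- pmin(pmax(base, 2.2), 11.8)
  lat <- pmax(schedule$constriction_latency_ms(age) + rnorm(m, 0, 15), 150)
  amp <- pmax(schedule$constriction_amplitude_mm(age, cond) +
                rnorm(m, 0, 0.03), 0.05)
  peak <- pmin(pmax(schedule$constriction_peak_ms(age, cond) +
                      rnorm(m, 0, 30), lat + 200), 1150)
  dil <- pmax(schedule$dilation_rate(age, cond) + rnorm(m, 0, 0.04), 0)
  anticipatory <- runif(m) < config$anticipatory_rate
  srt <- ifelse(anticipatory, runif(m, -100, 85),
                pmin(pmax(rnorm(m, schedule$srt_mean(age, cond), 55), 95), 780))
  err <- runif(m) < schedule$error_rate(age, cond)
  has_blink <- runif(m) < config$blink_rate
  blink_on <- ifelse(has_blink, runif(m, 100, 2600), NA_real_)
  blink_dur <- ifelse(has_blink, runif(m, 80, 250), NA_real_)
  tibble(
    id = pid, trial_id = seq_len(m), block = blocks$block,
    condition = cond, side = blocks$side,
    fp_on_ms = config$fp_on_ms, gap_on_ms = config$gap_on_ms,
    stim_on_ms = config$stim_on_ms,
    baseline_mm = base, constriction_latency_ms = lat,
    constriction_amplitude_mm = amp, constriction_peak_ms = peak,
    dilation_rate_mm_per_s = dil, srt_ms = srt,
    is_direction_error = err,
    blink_on_ms = blink_on, blink_dur_ms = blink_dur,
    trace_seed = derive_seed(config$seed, idx * 100000L + seq_len(m))
  )
}

#' Render one trial's eye-tracking trace
#'
#' Builds the 500 Hz sample stream for a trial parameter row: the pupil
#' holds at baseline, constricts along a smooth half-cosine pulse from the
#' constriction latency to the peak time (reaching `baseline - amplitude`
#' exactly at the peak), then dilates as a linear ramp until stimulus onset;
#' Gaussian noise is added on top. Gaze sits at fixation and steps 10 degrees
#' left or right at `stim_on + srt` with a cosine velocity profile whose peak
#' velocity follows the saccadic main sequence
#' `v_peak = 500 (1 - exp(-amplitude/15))` deg/s. Blinks are runs of invalid
#' samples flanked by +/-0.5 mm artifact spikes.
#'
#' @param params One row of the cohort `trials` tibble (or a named list with
#'   the same fields).
#' @param config A [cohort_config()].
#' @return A sample-trace tibble (`t_ms`, `gaze_x`, `gaze_y`, `pupil`,
#'   `valid`) with attributes `rate`, `pupil_units` and `events`.
#' @export
generate_trial_trace <- function(params, config) {
  p <- as.list(params)
  check_that(is.null(p$constriction_amplitude_mm) ||
               p$constriction_amplitude_mm >= 0,
             "constriction amplitude must be >= 0")
  check_that(p$constriction_peak_ms > p$constriction_latency_ms,
             "constriction peak must come after constriction latency")
  check_that(p$baseline_mm >= 2 && p$baseline_mm <= 12,
             "baseline_mm must lie within 2-12 mm")
  dt <- 1000 / config$sampling_rate
  t <- seq(0, config$trial_duration_ms - dt, by = dt)
  n <- length(t)
  if (!is.null(p$trace_seed) && !is.na(p$trace_seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(p$trace_seed)
  }

  stim_on <- p$stim_on_ms %||% 1200
  lat <- p$constriction_latency_ms; peak <- p$constriction_peak_ms
  amp <- p$constriction_amplitude_mm; rate <- p$dilation_rate_mm_per_s
  pupil <- rep(p$baseline_mm, n)
  in_pulse <- t >= lat & t <= peak
  pupil[in_pulse] <- p$baseline_mm -
    amp * 0.5 * (1 - cos(pi * (t[in_pulse] - lat) / (peak - lat)))
  # dilation ramp runs a short way past stimulus onset (the preparatory
  # dilation does not stop instantly), then holds
  ramp_end <- min(stim_on + 260, max(t))
  post <- t > peak & t <= ramp_end
  pupil[post] <- p$baseline_mm - amp + rate * (t[post] - peak) / 1000
  after <- t > ramp_end
  pupil[after] <- p$baseline_mm - amp + rate * (ramp_end - peak) / 1000
  if (config$noise_sd > 0) pupil <- pupil + rnorm(n, 0, config$noise_sd)

  # gaze: fixation, then a saccade with a cosine velocity profile
  gx <- rnorm(n, 0, config$gaze_noise_sd)
  gy <- rnorm(n, 0, config$gaze_noise_sd)
  sacc_on <- stim_on + p$srt_ms
  amp_deg <- config$stimulus_eccentricity_deg
  instructed <- if (identical(p$condition, "ANTI")) {
    if (identical(p$side, "left")) 1 else -1
  } else {
    if (identical(p$side, "left")) -1 else 1
  }
  dir_sign <- if (isTRUE(p$is_direction_error)) -instructed else instructed
  vpk <- 500 * (1 - exp(-amp_deg / 15))          # deg/s, main sequence
  dur_ms <- amp_deg * pi / (2 * vpk) * 1000      # cosine profile duration
  moving <- t >= sacc_on & t <= sacc_on + dur_ms
  phase <- (t[moving] - sacc_on) / dur_ms
  gx[moving] <- gx[moving] + dir_sign * amp_deg * 0.5 * (1 - cos(pi * phase))
  gx[t > sacc_on + dur_ms] <- gx[t > sacc_on + dur_ms] + dir_sign * amp_deg

  valid <- rep(TRUE, n)
  if (!is.null(p$blink_on_ms) && !is.na(p$blink_on_ms)) {
    b0 <- p$blink_on_ms; b1 <- p$blink_on_ms + p$blink_dur_ms
    check_that(b0 >= 0 && b1 <= max(t),
               "blink_times must lie within the trace span")
    idx <- which(t >= b0 & t <= b1)
    valid[idx] <- FALSE
    edge <- c(min(idx) - 1L, max(idx) + 1L)
    edge <- edge[edge >= 1 & edge <= n]
    pupil[edge] <- pupil[edge] + c(0.5, -0.5)[seq_along(edge)]
  }

  units <- "mm"
  if (isTRUE(config$emit_device_units)) {
    pupil <- device_area_map(pi * (pupil / 2)^2)
    units <- "area"
  }
  new_trace(t_ms = t, gaze_x = gx, gaze_y = gy, pupil = pupil, valid = valid,
            rate = config$sampling_rate, pupil_units = units,
            events = list(fp_on = p$fp_on_ms %||% 0,
                          gap_on = p$gap_on_ms %||% 1000,
                          stim_on = stim_on))
}

new_trace <- function(t_ms, gaze_x, gaze_y, pupil, valid, rate,
                      pupil_units = "mm", events = NULL) {
  out <- new_tibble(list(t_ms = t_ms, gaze_x = gaze_x, gaze_y = gaze_y,
                         pupil = pupil, valid = valid),
                    nrow = length(t_ms))
  attr(out, "rate") <- rate
  attr(out, "pupil_units") <- pupil_units
  attr(out, "events") <- events
  class(out) <- c("sample_trace", class(out))
  out
}

#' Default map from true pupil area to tracker units
#'
#' Linear in area (so the recorded value is quadratic in diameter and its
#' square root is exactly linear in mm, which the calibration stage exploits).
#'
#' @param area_mm2 True pupil area, mm^2.
#' @return Recorded tracker units.
#' @export
device_area_map <- function(area_mm2) 135 * area_mm2

#' Simulate false-pupil calibration recordings
#'
#' Emulates placing a series of artificial pupils of known diameter (2-12 mm)
#' in front of the tracker and recording the reported pupil-area values.
#'
#' @param sizes_mm Diameters of the false pupils, mm (default `2:12`).
#' @param device_map Monotone function from true area (mm^2) to recorded
#'   units; default [device_area_map()].
#' @param noise_sd Gaussian noise on the recorded units (default 0).
#' @param n_reps Recordings per size.
#' @param seed Optional seed.
#' @return Tibble with columns `true_mm`, `recorded_area`.
#' @export
generate_calibration_recordings <- function(sizes_mm = 2:12,
                                            device_map = device_area_map,
                                            noise_sd = 0, n_reps = 1,
                                            seed = NULL) {
  check_that(all(sizes_mm >= 2 & sizes_mm <= 12),
             "`sizes_mm` must lie within 2-12 mm")
  areas <- pi * (sort(unique(sizes_mm)) / 2)^2
  check_that(all(diff(device_map(areas)) > 0),
             "`device_map` must be strictly increasing in area")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  sizes <- rep(sizes_mm, each = n_reps)
  rec <- device_map(pi * (sizes / 2)^2)
  if (noise_sd > 0) rec <- rec + rnorm(length(rec), 0, noise_sd)
  tibble(true_mm = sizes, recorded_area = rec)
}

# ---- common-factor-model tables -------------------------------------------

simulate_factor_table <- function(n, loadings, seed = NULL, score_sd = 1) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (any(L != 0)) {
    check_that(qr(L)$rank == k, "loading matrix must have full column rank")
  }
  h2 <- rowSums(L^2)
  check_that(all(h2 < 1), "row communalities of the loading matrix must be < 1")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  Z <- matrix(rnorm(n * k, 0, score_sd), n, k)
  E <- matrix(rnorm(n * nrow(L)), n, nrow(L)) %*% diag(sqrt(1 - h2))
  X <- Z %*% t(L) + E
  colnames(X) <- rownames(L)
  list(scores = Z, data = X)
}

#' Default 4-factor loading pattern for the 12 saccade measures
#'
#' Block structure over the four behavioural factors: task disengagement,
#' visual transient, frontal inhibition / voluntary saccade generation, and
#' brainstem saccade generation.
#'
#' @return A 12 x 4 numeric matrix with measure names as row names.
#' @export
saccade_factor_loadings <- function() {
  vars <- c("pro_task_disengagement_pct", "anti_task_disengagement_pct",
            "anticipatory_pro_pct", "anticipatory_anti_pct",
            "mean_pro_srt_ms", "express_correct_pro_pct",
            "express_anti_error_pct", "regular_anti_error_pct",
            "vot_ms", "mean_anti_srt_ms",
            "mean_pro_velocity_dps", "mean_pro_amplitude_deg")
  L <- matrix(0, 12, 4, dimnames = list(vars, paste0("F", 1:4)))
  L[c("pro_task_disengagement_pct", "anti_task_disengagement_pct",
      "anticipatory_pro_pct", "anticipatory_anti_pct"), 1] <-
    c(0.85, 0.82, 0.70, 0.65)
  L[c("mean_pro_srt_ms", "express_correct_pro_pct",
      "express_anti_error_pct"), 2] <- c(-0.70, 0.82, 0.75)
  L[c("regular_anti_error_pct", "vot_ms", "mean_anti_srt_ms"), 3] <-
    c(0.80, 0.75, 0.65)
  L[c("mean_pro_velocity_dps", "mean_pro_amplitude_deg"), 4] <- c(0.85, 0.72)
  L
}

saccade_measure_ranges <- function() {
  tibble::tribble(
    ~measure,                       ~center, ~scale, ~lo,  ~hi,
    "pro_task_disengagement_pct",    15,      6,      0,    100,
    "anti_task_disengagement_pct",   18,      7,      0,    100,
    "anticipatory_pro_pct",          12,      5,      0,    100,
    "anticipatory_anti_pct",         10,      4,      0,    100,
    "mean_pro_srt_ms",               230,     35,     90,   800,
    "express_correct_pro_pct",       20,      8,      0,    100,
    "express_anti_error_pct",        30,      10,     0,    100,
    "regular_anti_error_pct",        25,      9,     0,    100,
    "vot_ms",                        150,     30,     0,    600,
    "mean_anti_srt_ms",              290,     40,     90,   800,
    "mean_pro_velocity_dps",         420,     55,     100,  900,
    "mean_pro_amplitude_deg",        9,       1.2,    2,    15
  )
}

#' Simulate a per-participant saccade-measure table
#'
#' Generates the 12 saccade behaviour measures (task-disengagement and
#' anticipatory-saccade percentages, mean SRTs, express/regular error
#' percentages, voluntary override time, and correct pro-saccade velocity
#' and amplitude) from a common-factor model: standard-normal latent scores
#' times the loading matrix plus unique noise, then an affine map onto each
#' measure's natural range (percentages clamped to \\[0, 100\\], SRTs to
#' \\[90, 800\\] ms). The latent scores used are retained in the
#' `"latent_scores"` attribute for recovery tests.
#'
#' @param n Number of participants.
#' @param loadings 12 x 4 loading matrix (default [saccade_factor_loadings()]).
#' @param seed Optional seed.
#' @param ids Optional participant ids.
#' @return Tibble of 12 measures (plus `id`), with attribute `latent_scores`.
#' @export
generate_saccade_measure_table <- function(n, loadings = saccade_factor_loadings(),
                                           seed = NULL, ids = NULL) {
  L <- as.matrix(loadings)
  check_that(nrow(L) == 12 && ncol(L) == 4, "`loadings` must be 12 x 4")
  if (is.null(rownames(L))) rownames(L) <- saccade_measure_ranges()$measure
  sim <- simulate_factor_table(n, L, seed = seed)
  rng <- saccade_measure_ranges()
  X <- sim$data
  for (j in seq_len(ncol(X))) {
    r <- rng[rng$measure == colnames(X)[j], ]
    X[, j] <- pmin(pmax(r$center + r$scale * X[, j], r$lo), r$hi)
  }
  out <- as_tibble(as.data.frame(X))
  out <- tibble(id = ids %||% sprintf("P%04d", seq_len(n)), !!!out)
  attr(out, "latent_scores") <- sim$scores
  out
}

#' Default 3-factor loading pattern for the 14 pupil measures
#'
#' Mimics the empirical grouping of the pupil measures: a visual/luminance
#' factor carried by the constriction measures (with dilation cross-loading),
#' a top-down factor carried by the dilation measures and peak constriction
#' time, and an arousal factor carried by baseline size and onset latency.
#'
#' @return A 14 x 3 numeric matrix with measure names as row names.
#' @export
pupil_factor_loadings <- function() {
  vars <- c("constriction_size_pro", "constriction_size_anti",
            "peak_constriction_velocity_pro", "peak_constriction_velocity_anti",
            "dilation_velocity_pro", "dilation_velocity_anti",
            "dilation_size_pro", "dilation_size_anti",
            "peak_dilation_velocity_pro", "peak_dilation_velocity_anti",
            "peak_constriction_time_pro", "peak_constriction_time_anti",
            "baseline_size", "onset_latency")
  L <- matrix(0, 14, 3, dimnames = list(vars, paste0("F", 1:3)))
  L[1:2, 1] <- 0.85
  L[3:4, 1] <- -0.80
  L[5:6, 1] <- 0.72; L[5:6, 2] <- 0.35
  L[7:8, 1] <- 0.50; L[7:8, 2] <- 0.60
  L[9:10, 1] <- 0.45; L[9:10, 2] <- 0.70
  L[11:12, 2] <- 0.80
  L[13, 3] <- 0.85
  L[14, 3] <- 0.70
  L
}

#' Simulate per-participant 14-variable pupil measure rows
#'
#' Common-factor-model analogue of [generate_saccade_measure_table()] for the
#' 14 pupil measures (6 measures split by condition + pooled baseline size
#' and onset latency), used to test factor recovery.
#'
#' @inheritParams generate_saccade_measure_table
#' @param loadings 14 x k loading matrix (default [pupil_factor_loadings()]).
#' @return Tibble of 14 measures (plus `id`), with attribute `latent_scores`.
#' @export
simulate_measure_rows <- function(n, loadings = pupil_factor_loadings(),
                                  seed = NULL, ids = NULL) {
  L <- as.matrix(loadings)
  check_that(nrow(L) == 14, "`loadings` must have 14 rows")
  if (is.null(rownames(L))) rownames(L) <- rownames(pupil_factor_loadings())
  sim <- simulate_factor_table(n, L, seed = seed)
  out <- as_tibble(as.data.frame(sim$data))
  out <- tibble(id = ids %||% sprintf("P%04d", seq_len(n)), !!!out)
  attr(out, "latent_scores") <- sim$scores
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
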