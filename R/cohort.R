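#' Configuration for a synthetic PPG/ABP cohort
#'
#' Builds the parameter set from which [generate_cohort()] simulates a
#' timestamped multi-subject cohort of paired photoplethysmogram (PPG) and
#' arterial blood pressure (ABP) recordings. The defaults emulate the shape of
#' the study cohort this package is designed around: 69 subjects (45
#' normotensive, 24 hypertensive), 974 recordings of 120 s at 125 Hz, with
#' per-subject systolic pressure held on one side of the 130 mmHg screening
#' threshold and pulse morphology that differs systematically between classes.
#'
#' @param n_nts_subjects,n_hts_subjects Number of normotensive (NTS) and
#'   hypertensive (HTS) subjects.
#' @param recordings_per_subject Either `NULL` (distribute
#'   `total_recordings` as evenly as possible, remainder to the earliest
#'   subjects), a single count, or a vector with one count per subject.
#' @param total_recordings Total recording count used when
#'   `recordings_per_subject` is `NULL`.
#' @param recording_duration_s Duration of each recording in seconds.
#' @param fs_hz Sampling frequency in Hz (both channels).
#' @param timestamp_schedule Recording schedule per subject. Either a numeric
#'   vector of non-negative offsets in seconds (used directly, recycled rule
#'   not applied), or a list with `rule` one of `"uniform"` (`delta_s` between
#'   consecutive recordings), `"gaps"` (`gaps_s` cycled to produce consecutive
#'   gaps), or `"paired"` (pairs `delta_s` apart, consecutive pairs separated
#'   by `pair_gap_s`). The default gap cycle populates all four
#'   calibration-interval bins (30 min, 2 h, 8 h and 30 h gaps).
#' @param sbp_range_nts,sbp_range_hts Baseline systolic pressure ranges
#'   (mmHg) for the two classes. They must not straddle the 130 mmHg
#'   threshold unless drift is enabled or `allow_straddle = TRUE`.
#' @param hr_bpm_range Per-subject resting heart-rate range (beats/min).
#' @param morphology_effect Dimensionless scale of the class-dependent pulse
#'   shape change (1 = default effect; 0 = classes share morphology).
#' @param morphology_subject_sd Scale of per-subject idiosyncratic morphology
#'   variation (1 = default).
#' @param drift_mmHg_per_hour Magnitude of the slow linear systolic drift;
#'   each subject drifts with a random sign. 0 disables drift.
#' @param morphology_drift_frac Fraction (0-1) by which pulse morphology
#'   tracks the *current* (drifted) pressure rather than the subject's
#'   baseline class. The default 0 models shape as a chronic subject trait.
#' @param noise_sd Additive white-noise standard deviation on the PPG channel
#'   (arbitrary units; pulse amplitude is ~1).
#' @param sbp_beat_sd_mmHg Per-beat systolic peak variability (mmHg).
#' @param hr_jitter_bpm Per-beat heart-rate jitter standard deviation.
#' @param amp_jitter_sd Multiplicative per-beat PPG amplitude jitter sd.
#' @param allow_straddle Permit class pressure ranges that cross 130 mmHg.
#' @param seed Integer seed; the cohort is fully determined by the
#'   configuration including this seed.
#'
#' @return An object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()], [schedule_timestamps()], [synth_recording()]
#' @export
#' @examples
#' cfg <- cohort_config(n_nts_subjects = 3, n_hts_subjects = 2,
#'                      recordings_per_subject = 2)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$recordings)
cohort_config <- function(n_nts_subjects = 45,
                          n_hts_subjects = 24,
                          recordings_per_subject = NULL,
                          total_recordings = 974,
                          recording_duration_s = 120,
                          fs_hz = 125,
                          timestamp_schedule = list(
                            rule = "gaps",
                            gaps_s = c(1800, 1800, 1800, 7200, 7200,
                                       28800, 28800, 108000)
                          ),
                          sbp_range_nts = c(100, 125),
                          sbp_range_hts = c(135, 165),
                          hr_bpm_range = c(55, 95),
                          morphology_effect = 1,
                          morphology_subject_sd = 1,
                          drift_mmHg_per_hour = 0,
                          morphology_drift_frac = 0,
                          noise_sd = 0.02,
                          sbp_beat_sd_mmHg = 1.5,
                          hr_jitter_bpm = 2,
                          amp_jitter_sd = 0.02,
                          allow_straddle = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_nts_subjects = as.integer(n_nts_subjects),
    n_hts_subjects = as.integer(n_hts_subjects),
    recordings_per_subject = recordings_per_subject,
    total_recordings = as.integer(total_recordings),
    recording_duration_s = recording_duration_s,
    fs_hz = fs_hz,
    timestamp_schedule = timestamp_schedule,
    sbp_range_nts = sbp_range_nts,
    sbp_range_hts = sbp_range_hts,
    hr_bpm_range = hr_bpm_range,
    morphology_effect = morphology_effect,
    morphology_subject_sd = morphology_subject_sd,
    drift_mmHg_per_hour = drift_mmHg_per_hour,
    morphology_drift_frac = morphology_drift_frac,
    noise_sd = noise_sd,
    sbp_beat_sd_mmHg = sbp_beat_sd_mmHg,
    hr_jitter_bpm = hr_jitter_bpm,
    amp_jitter_sd = amp_jitter_sd,
    allow_straddle = allow_straddle,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_nts_subjects >= 0, cfg$n_hts_subjects >= 0)
  if (cfg$recording_duration_s <= 0) stop("recording_duration_s must be > 0")
  if (cfg$fs_hz <= 20) {
    stop("fs_hz must exceed twice the 10 Hz analysis band upper edge")
  }
  for (r in list(cfg$sbp_range_nts, cfg$sbp_range_hts)) {
    if (length(r) != 2L || r[1] > r[2]) stop("pressure ranges must be [lo, hi]")
  }
  straddles <- function(r) r[1] <= 130 && r[2] >= 130
  if (!cfg$allow_straddle && cfg$drift_mmHg_per_hour == 0 &&
      (straddles(cfg$sbp_range_nts) || straddles(cfg$sbp_range_hts))) {
    stop("a class pressure range straddles 130 mmHg; enable drift or set ",
         "allow_straddle = TRUE if this is intended")
  }
  if (!cfg$allow_straddle && cfg$drift_mmHg_per_hour == 0 &&
      (cfg$sbp_range_nts[2] > 130 || cfg$sbp_range_hts[1] < 130)) {
    stop("sbp_range_nts must lie below 130 mmHg and sbp_range_hts above it ",
         "(set allow_straddle = TRUE to override)")
  }
  if (any(cfg$hr_bpm_range <= 0)) stop("hr_bpm_range must be positive")
  if (!is.null(cfg$recordings_per_subject) &&
      any(cfg$recordings_per_subject < 0)) {
    stop("recordings_per_subject must be >= 0")
  }
  invisible(cfg)
}

# Recordings per subject, honouring an explicit count/vector or distributing
# total_recordings as evenly as possible with the remainder given to the
# earliest subjects.
recordings_allocation <- function(cfg) {
  n_sub <- cfg$n_nts_subjects + cfg$n_hts_subjects
  if (n_sub == 0L) return(integer(0))
  rps <- cfg$recordings_per_subject
  if (is.null(rps)) {
    base <- cfg$total_recordings %/% n_sub
    extra <- cfg$total_recordings %% n_sub
    return(rep(base, n_sub) + c(rep(1L, extra), rep(0L, n_sub - extra)))
  }
  if (length(rps) == 1L) return(rep(as.integer(rps), n_sub))
  if (length(rps) != n_sub) {
    stop("recordings_per_subject must have length 1 or one entry per subject")
  }
  as.integer(rps)
}

#' Recording timestamps for one subject
#'
#' Expands the configured schedule rule into the acquisition timestamps
#' (seconds since the cohort epoch) of one subject's recordings.
#'
#' @param config A [cohort_config()].
#' @param subject A one-row subject tibble (or list) carrying at least
#'   `n_recordings`; subjects produced by [generate_cohort()] qualify.
#' @return Strictly increasing numeric vector of `t0` values, one per
#'   scheduled recording.
#' @export
#' @examples
#' cfg <- cohort_config(timestamp_schedule = list(rule = "uniform", delta_s = 1800))
#' schedule_timestamps(cfg, list(n_recordings = 4))
schedule_timestamps <- function(config, subject) {
  n <- as.integer(subject$n_recordings)
  if (n < 0L) stop("recordings_per_subject must be >= 0")
  if (n == 0L) return(numeric(0))
  sch <- config$timestamp_schedule
  if (is.numeric(sch)) {
    if (any(sch < 0)) stop("explicit schedule offsets must be non-negative")
    if (length(sch) < n) {
      stop("explicit schedule provides fewer offsets than recordings")
    }
    t0 <- sort(sch)[seq_len(n)]
  } else {
    rule <- sch$rule
    gaps <- switch(rule,
      uniform = rep(sch$delta_s, max(n - 1L, 0L)),
      gaps = rep_len(sch$gaps_s, max(n - 1L, 0L)),
      paired = {
        g <- rep(c(sch$delta_s,
                   if (is.null(sch$pair_gap_s)) 172800 else sch$pair_gap_s),
                 length.out = max(n - 1L, 0L))
        g
      },
      stop("unknown schedule rule: ", rule)
    )
    if (any(gaps < 0)) stop("schedule gaps must be non-negative")
    t0 <- cumsum(c(0, gaps))
  }
  if (n > 1L && any(diff(t0) <= 0)) {
    stop("schedule timestamps must be strictly increasing")
  }
  t0
}

# Class-template pulse parameters. h is the hypertensive intensity in [0, 1]
# (0 = normotensive template, 1 = hypertensive template at full effect) and m
# the morphology_effect scale. Hypertension narrows the systolic upstroke,
# raises and advances the reflected wave, and damps the dicrotic wave --
# standard two/three-component PPG pulse phenomenology.
class_pulse_params <- function(h, m = 1) {
  e <- h * m
  c(sys_amp  = 1.0,
    sys_mu   = 0.16,
    sys_sig  = 0.085 - 0.020 * e,
    refl_amp = 0.32 + 0.38 * e,
    refl_mu  = 0.45 - 0.080 * e,
    refl_sig = 0.105,
    dicr_amp = 0.18 - 0.12 * e,
    dicr_mu  = 0.60,
    dicr_sig = 0.050)
}

# Per-subject idiosyncratic perturbation of the class template. Draws from
# the current RNG stream.
subject_pulse_params <- function(base, subject_sd = 1) {
  s <- subject_sd
  p <- base
  p["sys_mu"]   <- p["sys_mu"] + stats::rnorm(1, 0, 0.010 * s)
  p["sys_sig"]  <- p["sys_sig"] * exp(stats::rnorm(1, 0, 0.08 * s))
  p["refl_amp"] <- p["refl_amp"] * exp(stats::rnorm(1, 0, 0.10 * s))
  p["refl_mu"]  <- p["refl_mu"] + stats::rnorm(1, 0, 0.015 * s)
  p["dicr_amp"] <- max(p["dicr_amp"] * exp(stats::rnorm(1, 0, 0.15 * s)), 0.01)
  p["dicr_mu"]  <- p["dicr_mu"] + stats::rnorm(1, 0, 0.012 * s)
  p
}

# Periodic pulse shape on phase u in [0, 1): three positive lobes, wrapped so
# the waveform is continuous across beat boundaries.
pulse_shape <- function(u, p) {
  lobe <- function(amp, mu, sig) {
    amp * (exp(-((u - mu)^2) / (2 * sig^2)) +
           exp(-((u - mu - 1)^2) / (2 * sig^2)) +
           exp(-((u - mu + 1)^2) / (2 * sig^2)))
  }
  lobe(p["sys_amp"], p["sys_mu"], p["sys_sig"]) +
    lobe(p["refl_amp"], p["refl_mu"], p["refl_sig"]) +
    lobe(p["dicr_amp"], p["dicr_mu"], p["dicr_sig"])
}

# ABP beat shape (unit-normalised later): systolic crest plus reflected and
# dicrotic components. Class morphology is not encoded here -- labels use
# peak pressure only.
abp_shape_params <- c(sys_amp = 1, sys_mu = 0.18, sys_sig = 0.10,
                      refl_amp = 0.42, refl_mu = 0.44, refl_sig = 0.14,
                      dicr_amp = 0.12, dicr_mu = 0.64, dicr_sig = 0.05)

# Diastolic pressure from systolic: pulse pressure widens with pressure.
dbp_from_sbp <- function(sbp) sbp - (35 + 0.3 * (sbp - 100))

#' Synthesise one paired PPG/ABP recording
#'
#' Simulates a single timestamped recording for one subject: a beat train with
#' heart-rate and amplitude jitter, PPG pulse morphology from the subject's
#' template, and ABP beats whose systolic peaks track
#' `baseline_sbp + drift(t) + per-beat noise`. Full beats are rescaled so the
#' sampled systolic peak equals the per-beat target exactly; with
#' `sbp_beat_sd_mmHg = 0` and drift disabled every ABP peak equals
#' `baseline_sbp`.
#'
#' @param subject One-row subject tibble from [generate_cohort()]'s `subjects`
#'   table (or an equivalent list with `baseline_sbp`, `hr_bpm`, `drift_dir`,
#'   `pulse_params`).
#' @param t0 Acquisition timestamp, seconds since the cohort epoch.
#' @param config A [cohort_config()].
#' @return A tibble with one row: `subject_id`, `t0`, `fs_hz`, `duration_s`,
#'   and list-columns `ppg` (zero-mean, arbitrary units) and `abp` (mmHg).
#' @export
synth_recording <- function(subject, t0, config) {
  fs <- config$fs_hz
  dur <- config$recording_duration_s
  n <- round(dur * fs)
  hr <- subject$hr_bpm
  params <- if (is.list(subject$pulse_params) && !is.numeric(subject$pulse_params)) {
    subject$pulse_params[[1]]
  } else {
    subject$pulse_params
  }

  drift_now <- config$drift_mmHg_per_hour * subject$drift_dir * (t0 / 3600)
  sbp_now <- subject$baseline_sbp + drift_now

  # Optional coupling of morphology to current (drifted) pressure.
  if (config$morphology_drift_frac > 0) {
    h_now <- stats::plogis((sbp_now - 130) / 5)
    target <- class_pulse_params(h_now, config$morphology_effect)
    f <- config$morphology_drift_frac
    params <- (1 - f) * params + f * target
  }

  # Beat onsets covering the recording.
  n_est <- ceiling(dur * hr / 60) + 8L
  periods <- 60 / pmax(hr + stats::rnorm(n_est, 0, config$hr_jitter_bpm), 20)
  onsets <- cumsum(c(0, periods))
  n_beats <- which(onsets >= dur)[1]
  onsets <- onsets[seq_len(n_beats)]
  periods <- periods[seq_len(n_beats)]

  t <- (seq_len(n) - 1) / fs
  beat <- findInterval(t, onsets)
  u <- (t - onsets[beat]) / periods[beat]

  # PPG: subject template, per-beat multiplicative amplitude jitter,
  # additive measurement noise, zero-mean.
  amp <- 1 + stats::rnorm(n_beats, 0, config$amp_jitter_sd)
  ppg <- amp[beat] * pulse_shape(u, params)
  if (config$noise_sd > 0) ppg <- ppg + stats::rnorm(n, 0, config$noise_sd)
  ppg <- ppg - mean(ppg)

  # ABP: per-beat systolic targets along the drift line, exact sampled peaks
  # for full beats.
  beat_mid_t <- t0 + onsets + periods / 2
  sbp_beats <- subject$baseline_sbp +
    config$drift_mmHg_per_hour * subject$drift_dir * (beat_mid_t / 3600)
  if (config$sbp_beat_sd_mmHg > 0) {
    sbp_beats <- sbp_beats + stats::rnorm(n_beats, 0, config$sbp_beat_sd_mmHg)
  }
  sbp_beats <- pmin(pmax(sbp_beats, 40), 290)
  dbp_beats <- pmax(dbp_from_sbp(sbp_beats), 21)

  shape <- pulse_shape(u, abp_shape_params)
  # Per-beat normalisation: sampled max for beats fully inside the recording,
  # dense-grid max for the trailing partial beat (so a truncated rise is not
  # blown up to full systolic height).
  dense_grid <- pulse_shape(seq(0, 1, length.out = 2048), abp_shape_params)
  dense_max <- max(dense_grid)
  u_crest <- (which.max(dense_grid) - 1) / 2047
  beat_max <- vapply(split(shape, beat), max, numeric(1))
  # a truncated final beat still has its true crest sampled if the recording
  # covers the crest phase (plus one sample of slack)
  full <- (onsets + u_crest * periods + 1 / fs) <= dur + 1e-9
  bm <- ifelse(full[as.integer(names(beat_max))], beat_max, dense_max)
  denom <- bm[match(beat, as.integer(names(beat_max)))]
  abp <- dbp_beats[beat] + (sbp_beats[beat] - dbp_beats[beat]) * shape / denom

  tibble::tibble(
    subject_id = subject$subject_id,
    t0 = t0, fs_hz = fs, duration_s = dur,
    ppg = list(ppg), abp = list(abp)
  )
}

#' Generate a synthetic timestamped PPG/ABP cohort
#'
#' Draws subjects (class, baseline systolic pressure, heart rate, pulse-shape
#' template), schedules each subject's recordings, and synthesises every
#' paired PPG/ABP recording. The result is fully determined by the
#' configuration, including its seed.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ppg_cohort`: a list with `subjects` (tibble:
#'   `subject_id`, `true_class`, `baseline_sbp`, `hr_bpm`, `drift_dir`,
#'   `n_recordings`, `pulse_params` list-column), `recordings` (tibble:
#'   `recording_id`, `subject_id`, `t0`, `fs_hz`, `duration_s`, list-columns
#'   `ppg` and `abp`), and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_nts_subjects = 2,
#'                                         n_hts_subjects = 1,
#'                                         recordings_per_subject = 2))
#' cohort$subjects$true_class
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n_sub <- config$n_nts_subjects + config$n_hts_subjects
  alloc <- recordings_allocation(config)

  if (n_sub == 0L) {
    cohort <- list(
      subjects = tibble::tibble(
        subject_id = character(0), true_class = factor(character(0), c("NTS", "HTS")),
        baseline_sbp = numeric(0), hr_bpm = numeric(0), drift_dir = numeric(0),
        n_recordings = integer(0), pulse_params = list()
      ),
      recordings = tibble::tibble(
        recording_id = character(0), subject_id = character(0), t0 = numeric(0),
        fs_hz = numeric(0), duration_s = numeric(0), ppg = list(), abp = list()
      ),
      config = config
    )
    class(cohort) <- "ppg_cohort"
    return(cohort)
  }

  classes <- factor(rep(c("NTS", "HTS"),
                        c(config$n_nts_subjects, config$n_hts_subjects)),
                    levels = c("NTS", "HTS"))
  sbp_lo <- ifelse(classes == "NTS", config$sbp_range_nts[1], config$sbp_range_hts[1])
  sbp_hi <- ifelse(classes == "NTS", config$sbp_range_nts[2], config$sbp_range_hts[2])

  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n_sub)),
    true_class = classes,
    baseline_sbp = stats::runif(n_sub, sbp_lo, sbp_hi),
    hr_bpm = stats::runif(n_sub, config$hr_bpm_range[1], config$hr_bpm_range[2]),
    drift_dir = sample(c(-1, 1), n_sub, replace = TRUE),
    n_recordings = alloc,
    pulse_params = purrr::map(seq_len(n_sub), function(i) {
      base <- class_pulse_params(as.numeric(classes[i] == "HTS"),
                                 config$morphology_effect)
      subject_pulse_params(base, config$morphology_subject_sd)
    })
  )

  recordings <- purrr::map_dfr(seq_len(n_sub), function(i) {
    subj <- subjects[i, ]
    t0s <- schedule_timestamps(config, subj)
    purrr::map_dfr(t0s, function(t0) synth_recording(subj, t0, config))
  })
  if (nrow(recordings) > 0) {
    recordings <- dplyr::mutate(
      recordings,
      recording_id = sprintf("%s_R%03d", .data$subject_id,
                             stats::ave(seq_len(nrow(recordings)),
                                        recordings$subject_id,
                                        FUN = seq_along)),
      .before = 1
    )
  } else {
    recordings <- dplyr::mutate(recordings, recording_id = character(0), .before = 1)
  }

  cohort <- list(subjects = subjects, recordings = recordings, config = config)
  class(cohort) <- "ppg_cohort"
  cohort
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat("<ppg_cohort> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$true_class == "NTS"), " NTS / ",
      sum(x$subjects$true_class == "HTS"), " HTS), ",
      nrow(x$recordings), " recordings of ",
      x$config$recording_duration_s, " s @ ", x$config$fs_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one directory per cohort: a manifest CSV (`subject_id`, `class`,
#' `recording_path`, `t0`, `fs_hz`), a two-column CSV
#' (`sample_index`, `value`) per channel per recording, and the generating
#' configuration (seed included) as YAML.
#'
#' @param cohort A `ppg_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "waveforms"), showWarnings = FALSE)
  rec <- cohort$recordings
  paths <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    base <- file.path("waveforms", rec$recording_id[i])
    for (ch in c("ppg", "abp")) {
      utils::write.csv(
        data.frame(sample_index = seq_along(rec[[ch]][[i]]) - 1L,
                   value = rec[[ch]][[i]]),
        file.path(dir, paste0(base, "_", ch, ".csv")), row.names = FALSE
      )
    }
    paths[i] <- base
  }
  manifest <- tibble::tibble(
    subject_id = rec$subject_id,
    class = as.character(cohort$subjects$true_class[
      match(rec$subject_id, cohort$subjects$subject_id)]),
    recording_id = rec$recording_id,
    recording_path = paths,
    t0 = rec$t0, fs_hz = rec$fs_hz, duration_s = rec$duration_s
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$timestamp_schedule <- as.list(cfg$timestamp_schedule)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `ppg_cohort` with waveforms and manifest metadata (subject
#'   templates are not stored on disk; `subjects` carries id/class/schedule
#'   fields only).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  read_ch <- function(path, ch) {
    utils::read.csv(file.path(dir, paste0(path, "_", ch, ".csv")))$value
  }
  recordings <- tibble::tibble(
    recording_id = manifest$recording_id,
    subject_id = manifest$subject_id,
    t0 = manifest$t0, fs_hz = manifest$fs_hz, duration_s = manifest$duration_s,
    ppg = purrr::map(manifest$recording_path, read_ch, ch = "ppg"),
    abp = purrr::map(manifest$recording_path, read_ch, ch = "abp")
  )
  subjects <- dplyr::distinct(
    tibble::tibble(subject_id = manifest$subject_id,
                   true_class = factor(manifest$class, c("NTS", "HTS")))
  )
  cohort <- list(subjects = subjects, recordings = recordings, config = cfg)
  class(cohort) <- "ppg_cohort"
  cohort
}
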