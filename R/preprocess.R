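#' Band-pass filter configuration
#'
#' Chebyshev type II band-pass design used to clean the PPG channel before
#' scalogram conversion: pass band 0.5-10 Hz, 40 dB stop-band attenuation,
#' applied forward-backward (zero phase) so the pulse waveform is not skewed.
#' `order` is the order passed to the band-pass designer (4, i.e. 4 poles per
#' band edge, the convention of the common DSP toolboxes).
#'
#' @param order Design order.
#' @param low_cut_hz,high_cut_hz Band edges in Hz.
#' @param stopband_atten_db Stop-band attenuation in dB.
#' @param zero_phase Apply forward-backward filtering.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(order = 4, low_cut_hz = 0.5, high_cut_hz = 10,
                          stopband_atten_db = 40, zero_phase = TRUE) {
  if (!(0 < low_cut_hz && low_cut_hz < high_cut_hz)) {
    stop("need 0 < low_cut_hz < high_cut_hz")
  }
  structure(list(order = order, low_cut_hz = low_cut_hz,
                 high_cut_hz = high_cut_hz,
                 stopband_atten_db = stopband_atten_db,
                 zero_phase = zero_phase),
            class = "filter_config")
}

# Local-maximum systolic peak detection: minimum inter-peak distance 0.33 s
# (<= 180 bpm) and prominence >= 10 mmHg relative to the deeper of the two
# flanking valleys.
detect_systolic_peaks <- function(abp, fs_hz, min_dist_s = 0.33,
                                  min_prominence = 10) {
  # zero = "+" keeps peaks with flat tops (quantised pressure traces)
  pk <- pracma::findpeaks(abp, zero = "+",
                          minpeakdistance = max(1L, round(min_dist_s * fs_hz)))
  if (is.null(pk)) return(integer(0))
  idx <- sort(pk[, 2])
  keep <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    left_lo <- min(abp[(if (k == 1) 1L else idx[k - 1]):i])
    right_lo <- min(abp[i:(if (k == length(idx)) length(abp) else idx[k + 1])])
    (abp[i] - max(left_lo, right_lo)) >= min_prominence
  }, logical(1))
  idx[keep]
}

#' Extract systolic blood pressure from an ABP waveform
#'
#' The recording-level SBP is the arithmetic mean of the detected systolic
#' peak values of the arterial pressure waveform.
#'
#' @param abp Numeric ABP series (mmHg).
#' @param fs_hz Sampling frequency.
#' @param recording_id Optional identifier used in error messages.
#' @return Mean systolic peak pressure in mmHg.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1 / 125)
#' abp <- 80 + 60 * pmax(sin(2 * pi * t), 0)^2
#' extract_sbp(abp, 125)
extract_sbp <- function(abp, fs_hz, recording_id = NULL) {
  if (!all(is.finite(abp))) stop("ABP contains non-finite samples")
  idx <- detect_systolic_peaks(abp, fs_hz)
  if (length(idx) == 0L) {
    stop("no systolic peaks detected",
         if (!is.null(recording_id)) paste0(" in recording ", recording_id))
  }
  mean(abp[idx])
}

#' Label a pressure value against the hypertension threshold
#'
#' Hypertensive (`HTS`) iff `sbp > threshold`; a value exactly at the
#' threshold is labeled normotensive (`NTS`). The boundary decision is
#' documented here and the threshold is configurable.
#'
#' @param sbp Systolic pressure(s), mmHg.
#' @param threshold Decision threshold, mmHg.
#' @return Factor with levels `NTS`, `HTS`.
#' @export
#' @examples
#' assign_label(c(129.9, 130, 131))
assign_label <- function(sbp, threshold = 130) {
  if (!all(is.finite(sbp))) stop("sbp must be finite")
  factor(ifelse(sbp > threshold, "HTS", "NTS"), levels = c("NTS", "HTS"))
}

#' Band-pass filter a PPG series
#'
#' Chebyshev type II band-pass (defaults 0.5-10 Hz, 40 dB stop band) applied
#' after mean removal. With `zero_phase` the filter runs forward-backward
#' over a reflective extension of the series, so the output has no phase
#' distortion and edge transients stay outside the returned window. Output
#' length equals input length; DC is removed.
#'
#' @param ppg Numeric series.
#' @param fs_hz Sampling frequency; must exceed `2 * high_cut_hz`.
#' @param cfg A [filter_config()].
#' @return Filtered series, same length as the input.
#' @export
filter_ppg <- function(ppg, fs_hz, cfg = filter_config()) {
  if (fs_hz <= 2 * cfg$high_cut_hz) {
    stop("high_cut_hz must be below the Nyquist frequency")
  }
  if (!all(is.finite(ppg))) stop("PPG contains non-finite samples")
  flt <- ppg_bandpass(fs_hz, cfg)
  y <- ppg - mean(ppg)
  n <- length(y)
  if (!cfg$zero_phase) return(as.numeric(signal::filter(flt, y)))
  # Odd (point-reflected) extension, as is standard for zero-phase filtering,
  # long enough for the 0.5 Hz edge transient to die out.
  pad <- min(n - 1L, round(3 * fs_hz / cfg$low_cut_hz))
  ext <- c(2 * y[1] - y[(pad + 1L):2L], y, 2 * y[n] - y[(n - 1L):(n - pad)])
  out <- signal::filtfilt(flt, ext)
  out[(pad + 1L):(pad + n)]
}

# Filter design, memoised per (fs, cfg).
ppg_bandpass <- local({
  cache <- new.env(parent = emptyenv())
  function(fs_hz, cfg) {
    key <- paste(fs_hz, cfg$order, cfg$low_cut_hz, cfg$high_cut_hz,
                 cfg$stopband_atten_db, sep = "|")
    if (is.null(cache[[key]])) {
      w <- c(cfg$low_cut_hz, cfg$high_cut_hz) / (fs_hz / 2)
      cache[[key]] <- signal::cheby2(cfg$order, cfg$stopband_atten_db, w,
                                     type = "pass")
    }
    cache[[key]]
  }
})

#' Decimate a band-limited PPG series
#'
#' Plain decimation by an integer factor. The series is assumed already
#' band-limited below the output Nyquist frequency by [filter_ppg()] (10 Hz
#' pass band against a 12.5 Hz output Nyquist), so no additional
#' anti-aliasing filter is applied.
#'
#' @param ppg Numeric series sampled at `fs_in`.
#' @param fs_in,fs_out Input and output sampling frequencies; `fs_in` must be
#'   an integer multiple of `fs_out`.
#' @return Decimated series of length `length(ppg) * fs_out / fs_in`
#'   (rounded up for lengths not divisible by the factor).
#' @export
#' @examples
#' length(downsample_ppg(sin(2 * pi * (0:14999) / 125), 125, 25))
downsample_ppg <- function(ppg, fs_in = 125, fs_out = 25) {
  fac <- fs_in / fs_out
  if (abs(fac - round(fac)) > 1e-9) {
    stop("fs_in must be an integer multiple of fs_out")
  }
  ppg[seq(1L, length(ppg), by = round(fac))]
}

#' Cut a recording into fixed-length labeled sub-segments
#'
#' Splits the (filtered, downsampled) PPG of one recording into consecutive
#' `seg_len_s`-second windows. Each window inherits the recording's SBP and
#' class label and carries a 1-based `parity_index` giving its position in
#' the recording. A non-multiple remainder shorter than `seg_len_s` is
#' dropped with a warning.
#'
#' @param rec One-row tibble (or list) with `recording_id`, `subject_id`,
#'   `t0`, `sbp`, `label`, and list-column/element `ppg` sampled at `fs_hz`.
#' @param fs_hz Sampling frequency of `rec`'s PPG (after downsampling; 25 Hz
#'   in the standard pipeline).
#' @param seg_len_s Window length in seconds.
#' @return Tibble of sub-segments: `subject_id`, `recording_id`,
#'   `parity_index`, `t0` (window start, cohort time), `sbp`, `label`, and a
#'   250-sample (at 25 Hz) `ppg` list-column.
#' @export
segment_recording <- function(rec, fs_hz = 25, seg_len_s = 10) {
  ppg <- if (is.list(rec$ppg) && !is.numeric(rec$ppg)) rec$ppg[[1]] else rec$ppg
  seg_n <- round(seg_len_s * fs_hz)
  n <- length(ppg)
  if (n < seg_n) stop("recording shorter than one segment")
  k <- n %/% seg_n
  if (n %% seg_n != 0L) {
    warning(sprintf("recording %s: dropping %.3g s remainder",
                    rec$recording_id, (n - k * seg_n) / fs_hz))
  }
  tibble::tibble(
    subject_id = rec$subject_id,
    recording_id = rec$recording_id,
    parity_index = seq_len(k),
    t0 = rec$t0 + (seq_len(k) - 1) * seg_len_s,
    sbp = rec$sbp,
    label = rec$label,
    ppg = purrr::map(seq_len(k), function(i) ppg[((i - 1) * seg_n + 1):(i * seg_n)])
  )
}

#' Drop subjects whose recordings fluctuate across the threshold
#'
#' A subject whose recordings carry mixed labels (some NTS, some HTS) is
#' removed; survivors have a homogeneous label across all their recordings.
#' This operationalises the exclusion of subjects with significant
#' between-measurement SBP fluctuation.
#'
#' @param recordings Tibble with at least `subject_id` and `label`.
#' @return The recordings of surviving subjects, plus attribute
#'   `excluded_subjects`.
#' @export
exclude_fluctuating <- function(recordings) {
  if (nrow(recordings) == 0L) {
    attr(recordings, "excluded_subjects") <- character(0)
    return(recordings)
  }
  mixed <- recordings |>
    dplyr::summarise(mixed = dplyr::n_distinct(.data$label) > 1L,
                     .by = "subject_id")
  excl <- mixed$subject_id[mixed$mixed]
  out <- dplyr::filter(recordings, !.data$subject_id %in% excl)
  attr(out, "excluded_subjects") <- excl
  out
}

#' Preprocess a cohort end to end
#'
#' For every recording: extract SBP from the ABP channel, assign the
#' NTS/HTS label, band-pass filter the PPG at the native rate, decimate to
#' `fs_out`, and segment into `seg_len_s`-second labeled windows. Optionally
#' excludes subjects with label fluctuation across recordings.
#'
#' @param cohort A `ppg_cohort` (from [generate_cohort()] or [read_cohort()]).
#' @param threshold Hypertension threshold in mmHg.
#' @param filter_cfg A [filter_config()].
#' @param fs_out Output sampling frequency after decimation.
#' @param seg_len_s Sub-segment length, seconds.
#' @param exclude Apply [exclude_fluctuating()].
#' @return List of class `ppg_preprocessed`: `recordings` (labeled recording
#'   table with downsampled `ppg`), `segments` (sub-segment tibble), and
#'   `excluded_subjects`.
#' @export
preprocess_cohort <- function(cohort, threshold = 130,
                              filter_cfg = filter_config(),
                              fs_out = 25, seg_len_s = 10,
                              exclude = TRUE) {
  rec <- cohort$recordings
  if (nrow(rec) == 0L) {
    out <- list(recordings = dplyr::mutate(rec, sbp = numeric(0),
                                           label = factor(character(0), c("NTS", "HTS"))),
                segments = tibble::tibble(),
                excluded_subjects = character(0))
    class(out) <- "ppg_preprocessed"
    return(out)
  }
  rec$sbp <- purrr::map2_dbl(rec$abp, rec$recording_id,
                             function(a, id) extract_sbp(a, rec$fs_hz[1], id))
  rec$label <- assign_label(rec$sbp, threshold)
  rec$ppg <- purrr::map(rec$ppg, function(x) {
    downsample_ppg(filter_ppg(x, rec$fs_hz[1], filter_cfg),
                   rec$fs_hz[1], fs_out)
  })
  rec$fs_hz <- fs_out
  rec$abp <- NULL

  if (exclude) {
    rec <- exclude_fluctuating(rec)
    excluded <- attr(rec, "excluded_subjects")
  } else {
    excluded <- character(0)
  }

  segments <- purrr::map_dfr(seq_len(nrow(rec)), function(i) {
    segment_recording(rec[i, ], fs_hz = fs_out, seg_len_s = seg_len_s)
  })
  out <- list(recordings = rec, segments = segments,
              excluded_subjects = excluded)
  class(out) <- "ppg_preprocessed"
  out
}

#' @export
print.ppg_preprocessed <- function(x, ...) {
  cat("<ppg_preprocessed> ", nrow(x$recordings), " recordings, ",
      nrow(x$segments), " sub-segments, ",
      length(x$excluded_subjects), " subject(s) excluded\n", sep = "")
  invisible(x)
}

#' Write a sub-segment manifest and waveforms
#'
#' @param pre A `ppg_preprocessed`.
#' @param dir Output directory.
#' @return Invisibly, the manifest tibble (`subject_id`, `recording_id`,
#'   `parity_index`, `t0`, `sbp`, `label`, `path`).
#' @export
write_segments <- function(pre, dir) {
  dir.create(file.path(dir, "segments"), recursive = TRUE, showWarnings = FALSE)
  seg <- pre$segments
  paths <- sprintf("segments/%s_seg%02d.csv", seg$recording_id, seg$parity_index)
  for (i in seq_len(nrow(seg))) {
    utils::write.csv(data.frame(sample_index = seq_along(seg$ppg[[i]]) - 1L,
                                value = seg$ppg[[i]]),
                     file.path(dir, paths[i]), row.names = FALSE)
  }
  manifest <- dplyr::mutate(dplyr::select(seg, -"ppg"), path = paths)
  utils::write.csv(manifest, file.path(dir, "segments.csv"), row.names = FALSE)
  invisible(manifest)
}
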