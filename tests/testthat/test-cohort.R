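test_that("cohort composition matches the configured class counts", {
  co <- small_cohort(n_nts = 4, n_hts = 3, recs = 2)
  expect_equal(nrow(co$subjects), 7)
  expect_equal(sum(co$subjects$true_class == "NTS"), 4)
  expect_equal(sum(co$subjects$true_class == "HTS"), 3)
  expect_equal(nrow(co$recordings), 14)

  empty <- generate_cohort(cohort_config(n_nts_subjects = 0, n_hts_subjects = 0))
  expect_equal(nrow(empty$subjects), 0)
  expect_equal(nrow(empty$recordings), 0)
})

test_that("identical configuration and seed reproduce the cohort exactly", {
  a <- small_cohort(seed = 42)
  b <- small_cohort(seed = 42)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$recordings, b$recordings)
  c <- small_cohort(seed = 43)
  expect_false(identical(a$recordings$ppg[[1]], c$recordings$ppg[[1]]))
})

test_that("the default study-shaped configuration schedules 974 recordings", {
  cfg <- cohort_config()
  alloc <- ppgcalib:::recordings_allocation(cfg)
  expect_length(alloc, 69)
  expect_equal(sum(alloc), 974)
  t0s <- lapply(alloc, function(n) schedule_timestamps(cfg, list(n_recordings = n)))
  expect_equal(sum(lengths(t0s)), 974)
  expect_true(all(vapply(t0s, function(x) all(diff(x) > 0), logical(1))))
})

test_that("schedule rules expand to the expected timestamps", {
  cfg <- cohort_config(timestamp_schedule = list(rule = "uniform", delta_s = 1800))
  expect_equal(schedule_timestamps(cfg, list(n_recordings = 4)),
               c(0, 1800, 3600, 5400))
  expect_equal(schedule_timestamps(cfg, list(n_recordings = 1)), 0)
  expect_equal(schedule_timestamps(cfg, list(n_recordings = 0)), numeric(0))

  cfg2 <- cohort_config(timestamp_schedule = c(0, 600, 60))
  expect_equal(schedule_timestamps(cfg2, list(n_recordings = 3)), c(0, 60, 600))
  cfg3 <- cohort_config(timestamp_schedule = c(-5, 0, 60))
  expect_error(schedule_timestamps(cfg3, list(n_recordings = 2)), "non-negative")

  cfg4 <- cohort_config(timestamp_schedule = list(rule = "paired", delta_s = 1800,
                                                  pair_gap_s = 86400 * 2))
  expect_equal(schedule_timestamps(cfg4, list(n_recordings = 4)),
               c(0, 1800, 174600, 176400))
})

test_that("a recording has the configured sample count and exact ABP peaks", {
  cfg <- cohort_config(n_nts_subjects = 0, n_hts_subjects = 1,
                       recordings_per_subject = 1,
                       sbp_range_hts = c(140, 140),
                       sbp_beat_sd_mmHg = 0, noise_sd = 0, seed = 5)
  co <- generate_cohort(cfg)
  ppg <- co$recordings$ppg[[1]]
  abp <- co$recordings$abp[[1]]
  expect_length(ppg, 15000)  # 120 s x 125 Hz
  expect_length(abp, 15000)
  expect_true(all(abp >= 20 & abp <= 300))
  pk <- oracle_peaks(abp, 125)
  expect_gt(length(pk), 80)
  expect_equal(max(abs(abp[pk] - 140)), 0)
})

test_that("beat count matches the configured heart rate", {
  cfg <- cohort_config(n_nts_subjects = 1, n_hts_subjects = 0,
                       recordings_per_subject = 1,
                       hr_bpm_range = c(60, 60), hr_jitter_bpm = 0,
                       sbp_beat_sd_mmHg = 0, noise_sd = 0, seed = 2)
  co <- generate_cohort(cfg)
  pk <- oracle_peaks(co$recordings$abp[[1]], 125)
  expect_true(abs(length(pk) - 120) <= 1)
})

test_that("with drift disabled every recording's peak pressure sits on its class side", {
  co <- small_cohort(n_nts = 3, n_hts = 3, recs = 3, seed = 9)
  cls <- co$subjects$true_class[match(co$recordings$subject_id,
                                      co$subjects$subject_id)]
  mean_peak <- vapply(co$recordings$abp, function(a) {
    mean(a[oracle_peaks(a, 125)])
  }, numeric(1))
  expect_true(all(mean_peak[cls == "NTS"] < 130))
  expect_true(all(mean_peak[cls == "HTS"] > 130))
})

test_that("classes are separable from beat-averaged PPG pulses", {
  co <- generate_cohort(cohort_config(
    n_nts_subjects = 10, n_hts_subjects = 10, recordings_per_subject = 1,
    seed = 11))
  M <- t(mapply(oracle_avg_pulse, co$recordings$ppg, co$recordings$abp,
                MoreArgs = list(fs = 125)))
  cls <- as.character(co$subjects$true_class[
    match(co$recordings$subject_id, co$subjects$subject_id)])
  correct <- vapply(seq_len(nrow(M)), function(i) {
    cn <- colMeans(M[-i, , drop = FALSE][cls[-i] == "NTS", , drop = FALSE])
    ch <- colMeans(M[-i, , drop = FALSE][cls[-i] == "HTS", , drop = FALSE])
    pred <- if (sum((M[i, ] - cn)^2) < sum((M[i, ] - ch)^2)) "NTS" else "HTS"
    pred == cls[i]
  }, logical(1))
  expect_gt(mean(correct), 0.9)
})

test_that("enabled drift moves mean peak pressure linearly at the configured rate", {
  cfg <- cohort_config(n_nts_subjects = 1, n_hts_subjects = 0,
                       recordings_per_subject = 4,
                       timestamp_schedule = c(0, 6, 12, 24) * 3600,
                       drift_mmHg_per_hour = 1.5,
                       sbp_beat_sd_mmHg = 0.2, noise_sd = 0, seed = 4)
  co <- generate_cohort(cfg)
  mean_peak <- vapply(co$recordings$abp, function(a) {
    mean(a[oracle_peaks(a, 125)])
  }, numeric(1))
  dev <- mean_peak - co$subjects$baseline_sbp[1]
  hours <- co$recordings$t0 / 3600
  fit <- stats::lm(dev ~ hours)
  expect_equal(abs(unname(stats::coef(fit)[2])), 1.5, tolerance = 0.02)
  expect_true(all(abs(abs(dev[-1]) - 1.5 * hours[-1]) < 1))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(sbp_range_nts = c(100, 135)), "straddles")
  expect_error(cohort_config(sbp_range_nts = c(135, 140)), "below 130")
  expect_error(cohort_config(recording_duration_s = 0), "recording_duration_s")
  expect_error(cohort_config(fs_hz = 15), "fs_hz")
  # straddling is allowed when drift is the object of study
  expect_s3_class(cohort_config(sbp_range_nts = c(100, 135),
                                allow_straddle = TRUE), "cohort_config")
})

test_that("a cohort written to disk reads back with identical waveforms", {
  co <- small_cohort(n_nts = 1, n_hts = 1, recs = 2, seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read_cohort(dir)
  expect_equal(back$recordings$ppg, co$recordings$ppg, tolerance = 1e-12)
  expect_equal(back$recordings$abp, co$recordings$abp, tolerance = 1e-12)
  expect_equal(as.character(back$subjects$true_class),
               as.character(co$subjects$true_class))
})
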