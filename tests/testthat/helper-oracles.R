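# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own implementations.

# Local-maximum scan with a refractory window: a sample is a peak if it is
# the strict maximum of its +/- refractory neighbourhood and above the
# signal midrange.
oracle_peaks <- function(x, fs, refractory_s = 0.4) {
  w <- round(refractory_s * fs)
  thr <- min(x) + 0.5 * (max(x) - min(x))
  peaks <- integer(0)
  i <- w + 1
  n <- length(x)
  while (i <= n - w) {
    win <- x[(i - w):(i + w)]
    if (x[i] >= thr && x[i] == max(win) && sum(win == x[i]) == 1L) {
      peaks <- c(peaks, i)
      i <- i + w
    } else {
      i <- i + 1
    }
  }
  peaks
}

# Exhaustive enumeration of all chronological chains whose consecutive gaps
# lie in [lo, up); returns the maximum chain length.
oracle_longest_chain_len <- function(t0, lo, up) {
  n <- length(t0)
  if (n == 0) return(0L)
  best <- 1L
  extend <- function(chain) {
    cur <- chain[length(chain)]
    cand <- which(seq_len(n) > cur &
                    (t0 - t0[cur]) >= lo & (t0 - t0[cur]) < up)
    if (length(cand) == 0L) {
      best <<- max(best, length(chain))
      return(invisible())
    }
    for (j in cand) extend(c(chain, j))
  }
  for (s in seq_len(n)) extend(s)
  best
}

# Element-wise confusion tally (HTS positive).
oracle_confusion <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  out <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in seq_along(y_true)) {
    if (y_true[i] == "HTS" && y_pred[i] == "HTS") out["TP"] <- out["TP"] + 1
    if (y_true[i] == "NTS" && y_pred[i] == "NTS") out["TN"] <- out["TN"] + 1
    if (y_true[i] == "NTS" && y_pred[i] == "HTS") out["FP"] <- out["FP"] + 1
    if (y_true[i] == "HTS" && y_pred[i] == "NTS") out["FN"] <- out["FN"] + 1
  }
  out
}

# Single-frequency complex gain of a rational digital filter (direct
# evaluation of the transfer function, independent of any filtering code).
oracle_filter_gain <- function(b, a, f_hz, fs_hz) {
  z <- exp(-1i * 2 * pi * f_hz / fs_hz * (seq_along(b) - 1))
  num <- sum(b * z)
  z <- exp(-1i * 2 * pi * f_hz / fs_hz * (seq_along(a) - 1))
  num / sum(a * z)
}

# Beat-averaged PPG pulse (resampled to 100 points between consecutive ABP
# peaks found by the oracle detector).
oracle_avg_pulse <- function(ppg, abp, fs) {
  pk <- oracle_peaks(abp, fs)
  beats <- lapply(seq_len(length(pk) - 1), function(k) {
    seg <- ppg[pk[k]:(pk[k + 1] - 1)]
    stats::approx(seq_along(seg) / length(seg), seg,
                  xout = seq(0.01, 1, 0.01), rule = 2)$y
  })
  colMeans(do.call(rbind, beats))
}

# A small drift-free cohort with recordings every 30 min.
small_cohort <- function(n_nts = 3, n_hts = 2, recs = 4, seed = 1, ...) {
  generate_cohort(cohort_config(
    n_nts_subjects = n_nts, n_hts_subjects = n_hts,
    recordings_per_subject = recs,
    timestamp_schedule = list(rule = "uniform", delta_s = 1800),
    seed = seed, ...))
}

# Synthetic 224 x 224 x 3 images with a bright horizontal band whose
# vertical position encodes the class; used to test the classifier without
# the waveform pipeline.
band_image <- function(class, rng) {
  px <- array(30L, c(224, 224, 3))
  rows <- if (class == "NTS") 40:80 else 150:190
  px[rows, , 1] <- 220L
  px[rows, , 2] <- 200L
  noise <- array(as.integer(rng(224 * 224 * 3) * 20), c(224, 224, 3))
  structure(pmin(pmax(px + noise, 0L), 255L), class = "scalogram_image")
}

band_manifest <- function(n_per_class, seed) {
  set.seed(seed)
  rng <- function(n) stats::runif(n)
  labels <- rep(c("NTS", "HTS"), each = n_per_class)
  tibble::tibble(
    image_id = sprintf("img%03d", seq_along(labels)),
    subject_id = sprintf("B%03d", seq_along(labels)),
    label = factor(labels, c("NTS", "HTS")),
    image = lapply(labels, band_image, rng = rng)
  )
}
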