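#' Analytic Morse wavelet configuration
#'
#' Parameters of the continuous wavelet transform used to turn 10-s PPG
#' sub-segments into scalograms: the analytic Morse wavelet with symmetry
#' parameter `gamma = 3` and time-bandwidth product `time_bandwidth = 60`
#' (so the wavelet's frequency-domain exponent is `beta = 60 / 3 = 20`),
#' sampled at 12 voices per octave. Frequency limits default to the segment
#' length's cone-of-influence-constrained minimum (`2 / duration` Hz) up to
#' the Nyquist frequency.
#'
#' @param gamma Symmetry parameter (> 0).
#' @param time_bandwidth Time-bandwidth product (> `gamma`).
#' @param voices_per_octave Scales per frequency doubling (>= 1).
#' @param freq_min_hz,freq_max_hz Optional frequency limits; `NULL` means
#'   automatic from signal length and sampling rate.
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(gamma = 3, time_bandwidth = 60,
                           voices_per_octave = 12,
                           freq_min_hz = NULL, freq_max_hz = NULL) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (time_bandwidth <= gamma) stop("time_bandwidth must exceed gamma")
  if (voices_per_octave < 1) stop("voices_per_octave must be >= 1")
  structure(list(gamma = gamma, time_bandwidth = time_bandwidth,
                 voices_per_octave = voices_per_octave,
                 freq_min_hz = freq_min_hz, freq_max_hz = freq_max_hz),
            class = "wavelet_config")
}

# Frequency-domain Morse wavelet on angular frequencies omega (rad/sample),
# peak-normalised to 2 on the positive axis (analytic convention).
morse_psi_hat <- function(omega, gamma, beta) {
  wp <- (beta / gamma)^(1 / gamma)
  la <- 2 * exp(-(beta * log(wp) - wp^gamma))
  out <- numeric(length(omega))
  pos <- omega > 0
  w <- omega[pos]
  out[pos] <- la * exp(beta * log(w) - w^gamma)
  out
}

# Peak angular frequency of the Morse wavelet.
morse_peak_omega <- function(gamma, beta) (beta / gamma)^(1 / gamma)

# e-folding time of the mother wavelet's envelope (|psi(t)| down to
# |psi(0)|/e), computed numerically from the frequency-domain form and
# memoised. Units: natural time (omega in rad per unit time).
morse_efold_time <- local({
  cache <- new.env(parent = emptyenv())
  function(gamma, beta) {
    key <- paste(gamma, beta, sep = "|")
    if (is.null(cache[[key]])) {
      dw <- 0.005
      w <- seq(dw, 8, by = dw)
      ph <- morse_psi_hat(w, gamma, beta)
      tt <- seq(0, 40, by = 0.01)
      env <- abs(exp(1i * outer(tt, w)) %*% ph) * dw / (2 * pi)
      target <- env[1] / exp(1)
      i <- which(env < target)[1]
      # linear interpolation between the straddling samples
      cache[[key]] <- tt[i - 1] + 0.01 * (env[i - 1] - target) /
        (env[i - 1] - env[i])
    }
    cache[[key]]
  }
})

#' Continuous wavelet transform of a PPG sub-segment
#'
#' Computes the magnitude scalogram of a real series with the analytic Morse
#' wavelet as an FFT filter bank: one band per voice on a logarithmic
#' frequency grid, magnitudes `|W(f, t)|`, plus the cone-of-influence (COI)
#' boundary. The COI frequency at each column is the lowest frequency whose
#' wavelet e-folding time still fits between the column and the nearer
#' segment edge; coefficients below it are edge-affected.
#'
#' @param ppg Numeric series (finite, length >= 2).
#' @param fs_hz Sampling frequency in Hz.
#' @param cfg A [wavelet_config()].
#' @return Object of class `ppg_scalogram`: list with `magnitudes`
#'   (`n_scales x n` matrix, rows ordered from `freqs_hz[1]` =
#'   highest frequency downward), `freqs_hz` (descending), `coi_hz` (per
#'   column, capped at the top analysis frequency), `fs_hz`.
#' @export
#' @examples
#' x <- sin(2 * pi * 2 * (0:249) / 25)
#' s <- compute_cwt(x, 25)
#' dim(s$magnitudes)
compute_cwt <- function(ppg, fs_hz, cfg = wavelet_config()) {
  if (length(ppg) < 2L) stop("input must have length >= 2")
  if (!all(is.finite(ppg))) stop("input contains non-finite samples")
  n <- length(ppg)
  beta <- cfg$time_bandwidth / cfg$gamma
  wp <- morse_peak_omega(cfg$gamma, beta)

  f_max <- if (is.null(cfg$freq_max_hz)) fs_hz / 2 else cfg$freq_max_hz
  f_min <- if (is.null(cfg$freq_min_hz)) 2 * fs_hz / n else cfg$freq_min_hz
  if (f_min >= f_max) stop("freq_min_hz must be below freq_max_hz")
  n_scales <- floor(log2(f_max / f_min) * cfg$voices_per_octave) + 1L
  freqs <- f_max * 2^(-(seq_len(n_scales) - 1L) / cfg$voices_per_octave)
  scales <- wp / (2 * pi * freqs / fs_hz)  # samples

  xf <- stats::fft(ppg)
  omega <- 2 * pi * (seq_len(n) - 1L) / n
  # keep only the positive-frequency half-axis (analytic wavelet)
  omega[omega > pi] <- 0
  mags <- matrix(0, n_scales, n)
  for (k in seq_len(n_scales)) {
    filt <- morse_psi_hat(scales[k] * omega, cfg$gamma, beta)
    mags[k, ] <- Mod(stats::fft(xf * filt, inverse = TRUE)) / n
  }

  # COI: a wavelet at frequency f (scale s) has e-folding duration s*te/fs
  # seconds; the boundary at a column is the frequency whose e-folding
  # duration equals the distance d to the nearer edge.
  te <- morse_efold_time(cfg$gamma, beta)
  d <- pmin(seq_len(n) - 1L, n - seq_len(n)) / fs_hz  # s to nearer edge
  coi <- wp * te / (2 * pi * pmax(d, .Machine$double.eps))
  structure(list(magnitudes = mags, freqs_hz = freqs,
                 coi_hz = pmin(coi, f_max), fs_hz = fs_hz),
            class = "ppg_scalogram")
}

#' @export
print.ppg_scalogram <- function(x, ...) {
  cat("<ppg_scalogram> ", nrow(x$magnitudes), " scales x ",
      ncol(x$magnitudes), " samples, ",
      sprintf("%.3g-%.3g Hz", min(x$freqs_hz), max(x$freqs_hz)), "\n", sep = "")
  invisible(x)
}

# Vectorised bilinear resampling of a matrix to out_h x out_w, pixel-centre
# aligned.
resize_bilinear <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  src <- function(out_n, in_n) {
    x <- (seq_len(out_n) - 0.5) * in_n / out_n + 0.5
    pmin(pmax(x, 1), in_n)
  }
  y <- src(out_h, in_h); x <- src(out_w, in_w)
  y0 <- pmin(floor(y), in_h - 1L); x0 <- pmin(floor(x), in_w - 1L)
  wy <- y - y0; wx <- x - x0
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x0 + 1, drop = FALSE]
  m10 <- m[y0 + 1, x0, drop = FALSE]; m11 <- m[y0 + 1, x0 + 1, drop = FALSE]
  WY <- matrix(wy, out_h, out_w); WX <- matrix(wx, out_h, out_w, byrow = TRUE)
  (1 - WY) * ((1 - WX) * m00 + WX * m01) + WY * ((1 - WX) * m10 + WX * m11)
}

# 256-entry RGB lookup table for a named perceptually uniform palette.
colormap_lut <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (is.null(cache[[name]])) {
      cols <- viridisLite::viridis(256, option = name)
      cache[[name]] <- t(grDevices::col2rgb(cols)) / 255
    }
    cache[[name]]
  }
})

#' Render a scalogram as a 224 x 224 x 3 image
#'
#' Normalises the magnitudes per image to `[0, 1]`, maps them through a
#' perceptually uniform colormap, bilinearly resizes the coloured raster
#' from its native `n_scales x n_samples` size to the target size, and
#' finally traces the cone of influence as a 1-pixel-wide exactly white line
#' in output coordinates (after colormap and resize, so interpolation cannot
#' dilute it). Low frequencies sit at the image bottom. No
#' axes, ticks, or margins are drawn. The rendering is deterministic and
#' scale-invariant: doubling the input magnitudes yields identical pixels.
#'
#' @param s A `ppg_scalogram`.
#' @param width,height Output size in pixels.
#' @param colormap Palette name understood by viridisLite (default
#'   `"viridis"`).
#' @param mark_coi Trace the cone of influence in white.
#' @param log_scale Map `log1p` of the normalised magnitudes instead.
#' @param provenance Optional sub-segment identifier stored with the image.
#' @return Object of class `scalogram_image`: integer array
#'   `height x width x 3` in `[0, 255]` with attribute `provenance`.
#' @export
render_scalogram <- function(s, width = 224, height = 224,
                             colormap = "viridis", mark_coi = TRUE,
                             log_scale = FALSE, provenance = NULL) {
  mags <- s$magnitudes
  if (length(mags) == 0L) stop("empty scalogram")
  rng <- range(mags)
  norm <- if (rng[2] > rng[1]) (mags - rng[1]) / (rng[2] - rng[1]) else mags * 0
  if (log_scale) norm <- log1p(norm * (exp(1) - 1))
  lut <- colormap_lut(colormap)
  idx <- matrix(pmin(pmax(as.integer(norm * 255) + 1L, 1L), 256L),
                nrow(mags), ncol(mags))
  native <- array(0, c(nrow(mags), ncol(mags), 3))
  for (ch in 1:3) native[, , ch] <- matrix(lut[idx, ch], nrow(mags))

  px <- array(0L, c(height, width, 3))
  for (ch in 1:3) {
    px[, , ch] <- as.integer(round(
      pmin(pmax(resize_bilinear(native[, , ch], height, width), 0), 1) * 255))
  }
  if (mark_coi) {
    # redraw the boundary in output coordinates so the trace stays exactly
    # white after interpolation
    f_top <- max(s$freqs_hz)
    nj <- ncol(mags); ni <- nrow(mags)
    for (j in seq_len(width)) {
      jn <- min(max(round((j - 0.5) * nj / width + 0.5), 1L), nj)
      if (s$coi_hz[jn] < f_top) {
        rn <- which.min(abs(s$freqs_hz - s$coi_hz[jn]))
        r <- min(max(round((rn - 0.5) * height / ni + 0.5), 1L), height)
        px[r, j, ] <- 255L
      }
    }
  }
  structure(px, class = "scalogram_image", provenance = provenance)
}

#' Write a rendered scalogram image as an 8-bit RGB PNG
#'
#' @param img A `scalogram_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scalogram_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Read a scalogram PNG back as a pixel array
#'
#' @param path PNG path.
#' @return Integer array `height x width x 3` in `[0, 255]`.
#' @export
read_scalogram_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  structure(array(as.integer(round(px[, , 1:3] * 255)), dim = c(dim(px)[1:2], 3)),
            class = "scalogram_image", provenance = basename(path))
}

#' Render scalogram images for a table of sub-segments
#'
#' Runs [compute_cwt()] and [render_scalogram()] on every sub-segment and
#' returns the image manifest. With `dir` set, images are written as PNGs
#' named by sub-segment id and the manifest carries `image_path`; otherwise
#' pixel arrays are kept in an `image` list-column (intended for small
#' batches only).
#'
#' @param segments Sub-segment tibble from [preprocess_cohort()] (columns
#'   `subject_id`, `recording_id`, `parity_index`, `t0`, `label`, `ppg`).
#' @param fs_hz Sampling frequency of the segment PPG.
#' @param wavelet_cfg A [wavelet_config()].
#' @param dir Optional output directory for PNGs.
#' @param ... Passed to [render_scalogram()].
#' @return Image manifest tibble: `image_id`, `subject_id`, `recording_id`,
#'   `parity_index`, `t0`, `label`, and `image_path` or `image`.
#' @export
segment_scalograms <- function(segments, fs_hz = 25,
                               wavelet_cfg = wavelet_config(),
                               dir = NULL, ...) {
  ids <- sprintf("%s_seg%02d", segments$recording_id, segments$parity_index)
  manifest <- tibble::tibble(
    image_id = ids,
    subject_id = segments$subject_id,
    recording_id = segments$recording_id,
    parity_index = segments$parity_index,
    t0 = segments$t0,
    label = segments$label
  )
  imgs <- purrr::map2(segments$ppg, ids, function(x, id) {
    render_scalogram(compute_cwt(x, fs_hz, wavelet_cfg), provenance = id, ...)
  })
  if (is.null(dir)) {
    manifest$image <- imgs
  } else {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$image_path <- file.path(dir, paste0(ids, ".png"))
    purrr::walk2(imgs, manifest$image_path, write_scalogram_png)
    utils::write.csv(dplyr::select(manifest, -dplyr::any_of("image")),
                     file.path(dir, "images.csv"), row.names = FALSE)
  }
  manifest
}

#' Plot a scalogram
#'
#' @param object A `ppg_scalogram`.
#' @param ... Ignored.
#' @return A ggplot: time on x, log-spaced frequency on y, magnitude fill,
#'   with the cone of influence as a white line.
#' @export
autoplot.ppg_scalogram <- function(object, ...) {
  df <- tibble::tibble(
    t_s = rep((seq_len(ncol(object$magnitudes)) - 1L) / object$fs_hz,
              each = nrow(object$magnitudes)),
    freq_hz = rep(object$freqs_hz, ncol(object$magnitudes)),
    magnitude = as.vector(object$magnitudes)
  )
  coi <- tibble::tibble(
    t_s = (seq_len(ncol(object$magnitudes)) - 1L) / object$fs_hz,
    freq_hz = object$coi_hz
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t_s, .data$freq_hz)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$magnitude)) +
    ggplot2::geom_line(data = coi, colour = "white") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "|CWT|") +
    ggplot2::theme_minimal()
}
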