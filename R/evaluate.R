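#' Confusion counts with HTS as the positive class
#'
#' `TP` counts correctly classified hypertensive segments, `TN` correctly
#' classified normotensive segments, `FN` hypertensive segments predicted
#' normotensive, and `FP` normotensive segments predicted hypertensive.
#'
#' @param y_true,y_pred Label vectors (factor or character, values `NTS` /
#'   `HTS`), equal length.
#' @return Object of class `confusion_counts`: list `TP`, `TN`, `FP`, `FN`.
#' @export
#' @examples
#' confusion_counts(c("HTS", "NTS", "HTS"), c("HTS", "NTS", "NTS"))
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  ok <- c("NTS", "HTS")
  if (!all(y_true %in% ok) || !all(y_pred %in% ok)) {
    stop("labels must be 'NTS' or 'HTS'")
  }
  structure(list(
    TP = sum(y_true == "HTS" & y_pred == "HTS"),
    TN = sum(y_true == "NTS" & y_pred == "NTS"),
    FP = sum(y_true == "NTS" & y_pred == "HTS"),
    FN = sum(y_true == "HTS" & y_pred == "NTS")
  ), class = "confusion_counts")
}

#' Classification statistics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and F1 score `2TP/(2TP+FP+FN)` (the count form, equal to
#' the harmonic mean of precision and recall). A zero denominator yields
#' `NaN` with a warning. With `verbose`, the harmonic mean of sensitivity
#' and accuracy is reported alongside for comparison.
#'
#' @param cc A [confusion_counts()] object (or list with TP/TN/FP/FN).
#' @param verbose Add the `f1_harmonic_se_acc` column.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `n` — fractions in `[0, 1]`.
#' @export
#' @examples
#' compute_metrics(confusion_counts(rep(c("HTS", "NTS"), 5),
#'                                  rep(c("HTS", "NTS"), c(4, 6))))
compute_metrics <- function(cc, verbose = FALSE) {
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  if (total == 0) stop("no evaluated samples")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  out <- tibble::tibble(
    accuracy = (cc$TP + cc$TN) / total,
    sensitivity = safe_div(cc$TP, cc$TP + cc$FN, "sensitivity"),
    specificity = safe_div(cc$TN, cc$TN + cc$FP, "specificity"),
    f1 = safe_div(2 * cc$TP, 2 * cc$TP + cc$FP + cc$FN, "f1"),
    n = total
  )
  if (verbose) {
    se <- out$sensitivity
    out$f1_harmonic_se_acc <- 2 * se * out$accuracy / (se + out$accuracy)
  }
  out
}

#' Write / read a metrics report
#'
#' JSON serialisation that round-trips losslessly.
#'
#' @param report Metrics tibble (e.g. from [run_experiment()]'s `metrics`).
#' @param path File path.
#' @return `path` invisibly; `read_metrics_report()` returns the tibble.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::as_tibble(df)
}

# Deterministic stratified thinning of an image manifest to at most n rows,
# preserving the label mix as closely as possible.
cap_manifest <- function(manifest, n) {
  if (is.null(n) || nrow(manifest) <= n) return(manifest)
  parts <- split(seq_len(nrow(manifest)), manifest$label)
  take <- unlist(purrr::imap(parts, function(ix, lab) {
    k <- max(1L, round(n * length(ix) / nrow(manifest)))
    ix[unique(round(seq(1, length(ix), length.out = min(k, length(ix)))))]
  }))
  manifest[sort(take), ]
}

#' Run the full calibration-interval experiment
#'
#' Orchestrates the pipeline on a cohort: preprocessing (SBP labels,
#' filtering, decimation, segmentation, optional exclusion), scalogram
#' rendering, per-bin calibration splits, classifier training, and metric
#' computation — one report per bin, in bin order. Bins whose validation set
#' is empty are reported as skipped. To keep desk-scale runs affordable the
#' train/validation manifests can be thinned to `max_images_per_set` rows
#' per set (deterministic, label-stratified); only images needed by some
#' split are rendered.
#'
#' @param cohort A `ppg_cohort`.
#' @param bins Bin table, as [interval_bins()] (order is preserved).
#' @param train_cfg A [train_config()].
#' @param threshold Hypertension threshold, mmHg.
#' @param exclude Drop label-fluctuating subjects (disable for drift
#'   experiments, where fluctuation is the object of study).
#' @param image_dir Directory for rendered PNGs (default: a session
#'   temporary directory).
#' @param max_images_per_set Optional cap per train/validation set and bin.
#' @param per_recording_vote Aggregate sub-segment predictions to one
#'   majority-vote label per recording before computing metrics
#'   (ties resolve to NTS).
#' @return Object of class `ppg_experiment`: `metrics` (one row per bin:
#'   bin, skipped, epochs, accuracy, sensitivity, specificity, f1, n),
#'   `accounting` (Table-1-style image counts), `histories`, `fits`, and
#'   `config` echoes.
#' @export
run_experiment <- function(cohort, bins = interval_bins(),
                           train_cfg = train_config(),
                           threshold = 130, exclude = TRUE,
                           image_dir = NULL,
                           max_images_per_set = NULL,
                           per_recording_vote = FALSE) {
  pre <- preprocess_cohort(cohort, threshold = threshold, exclude = exclude)
  seg <- pre$segments
  manifest0 <- tibble::tibble(
    image_id = sprintf("%s_seg%02d", seg$recording_id, seg$parity_index),
    subject_id = seg$subject_id,
    recording_id = seg$recording_id,
    parity_index = seg$parity_index,
    t0 = seg$t0,
    label = seg$label
  )

  splits <- vector("list", nrow(bins))
  for (k in seq_len(nrow(bins))) {
    sp <- build_split(manifest0, pre$recordings, bins[k, ])
    sp$train <- cap_manifest(sp$train, max_images_per_set)
    sp$val <- cap_manifest(sp$val, max_images_per_set)
    splits[[k]] <- sp
  }

  needed <- unique(unlist(lapply(splits, function(sp) {
    c(sp$train$image_id, sp$val$image_id)
  })))
  if (is.null(image_dir)) image_dir <- file.path(tempdir(), "ppgcalib_images")
  rendered <- segment_scalograms(seg[manifest0$image_id %in% needed, ],
                                 fs_hz = pre$recordings$fs_hz[1],
                                 dir = image_dir)
  path_of <- stats::setNames(rendered$image_path, rendered$image_id)

  metrics <- list(); fits <- list(); histories <- list(); accounting <- list()
  for (k in seq_len(nrow(bins))) {
    sp <- splits[[k]]
    accounting[[k]] <- sp$accounting
    if (nrow(sp$val) == 0L || nrow(sp$train) == 0L) {
      metrics[[k]] <- tibble::tibble(
        bin = bins$name[k], skipped = TRUE, epochs = NA_integer_,
        accuracy = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
        f1 = NA_real_, n = 0L)
      next
    }
    sp$train$image_path <- unname(path_of[sp$train$image_id])
    sp$val$image_path <- unname(path_of[sp$val$image_id])
    model <- build_model(train_cfg)
    fit <- train_model(model, sp, train_cfg)
    pred <- predict(fit, sp$val)
    truth <- manifest_labels(sp$val)
    if (per_recording_vote) {
      by_rec <- tibble::tibble(recording_id = sp$val$recording_id,
                               truth = truth, pred = pred$label) |>
        dplyr::summarise(
          truth = names(which.max(table(.data$truth))),
          pred = c("NTS", "HTS")[1 + (mean(.data$pred == "HTS") > 0.5)],
          .by = "recording_id")
      cc <- confusion_counts(by_rec$truth, by_rec$pred)
    } else {
      cc <- confusion_counts(truth, pred$label)
    }
    m <- compute_metrics(cc)
    metrics[[k]] <- tibble::tibble(
      bin = bins$name[k], skipped = FALSE, epochs = fit$epochs_completed,
      accuracy = m$accuracy, sensitivity = m$sensitivity,
      specificity = m$specificity, f1 = m$f1, n = m$n)
    fits[[k]] <- fit
    histories[[k]] <- fit$history
  }

  out <- list(metrics = dplyr::bind_rows(metrics),
              accounting = dplyr::bind_rows(accounting),
              histories = histories,
              fits = fits,
              excluded_subjects = pre$excluded_subjects,
              train_cfg = train_cfg,
              image_dir = image_dir)
  class(out) <- "ppg_experiment"
  out
}

#' @export
print.ppg_experiment <- function(x, ...) {
  cat("<ppg_experiment> per-bin validation performance:\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (m$skipped[i]) {
      cat(sprintf("  %-7s skipped (empty validation set)\n", m$bin[i]))
    } else {
      cat(sprintf(
        "  %-7s epochs %2d  Acc %6.2f%%  Se %6.2f%%  Sp %6.2f%%  F1 %6.2f%%  (n=%d)\n",
        m$bin[i], m$epochs[i], 100 * m$accuracy[i], 100 * m$sensitivity[i],
        100 * m$specificity[i], 100 * m$f1[i], m$n[i]))
    }
  }
  invisible(x)
}

#' Summary table of an experiment
#'
#' @param x A `ppg_experiment`.
#' @param ... Ignored.
#' @return The per-bin metrics tibble (fractions in `[0, 1]`).
#' @export
tidy.ppg_experiment <- function(x, ...) x$metrics

#' Plot per-bin validation metrics
#'
#' @param object A `ppg_experiment`.
#' @param ... Ignored.
#' @return A ggplot of the four statistics across calibration-interval bins.
#' @export
autoplot.ppg_experiment <- function(object, ...) {
  m <- dplyr::filter(object$metrics, !.data$skipped)
  m$bin <- factor(m$bin, levels = object$metrics$bin)
  long <- tidyr::pivot_longer(
    m[, c("bin", "accuracy", "sensitivity", "specificity", "f1")],
    -"bin", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$bin, .data$value,
                                     colour = .data$metric,
                                     group = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "calibration interval", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
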