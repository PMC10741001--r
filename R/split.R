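#' The four calibration-interval bins
#'
#' Gaps between consecutive measurements are binned as: under 1 h, 1-6 h,
#' 6-24 h, and over 24 h. Bounds are inclusive-exclusive `[lower_s, upper_s)`
#' and the four bins partition the positive axis.
#'
#' @return Tibble with `name`, `lower_s`, `upper_s`.
#' @export
#' @examples
#' interval_bins()
interval_bins <- function() {
  tibble::tibble(
    name = c("lt1h", "1to6h", "6to24h", "gt24h"),
    lower_s = c(0, 3600, 21600, 86400),
    upper_s = c(3600, 21600, 86400, Inf)
  )
}

as_bin <- function(bin) {
  if (is.character(bin)) {
    bins <- interval_bins()
    i <- match(bin, bins$name)
    if (is.na(i)) stop("unknown interval bin: ", bin)
    return(bins[i, ])
  }
  bin
}

gap_in_bin <- function(gap, bin) gap >= bin$lower_s & gap < bin$upper_s

#' Longest qualifying recording chain for one subject and bin
#'
#' Returns the longest chronological chain of a subject's recordings in which
#' every consecutive gap falls within the bin's bounds. Chains are grown
#' greedily: from each candidate start, the next link is the earliest later
#' recording whose gap from the current link qualifies; the longest resulting
#' chain wins, ties broken by earliest start. Chains shorter than 2 leave the
#' subject unselected for this bin.
#'
#' @param t0 Numeric vector of the subject's recording timestamps, sorted
#'   ascending (seconds since the cohort epoch).
#' @param bin A bin name (`"lt1h"`, `"1to6h"`, `"6to24h"`, `"gt24h"`) or a
#'   one-row tibble from [interval_bins()].
#' @return Integer indices into `t0` forming the chain; `integer(0)` if the
#'   subject is unselected.
#' @export
#' @examples
#' select_interval_sequence(c(0, 1800, 3600, 5400), "lt1h")
select_interval_sequence <- function(t0, bin) {
  bin <- as_bin(bin)
  if (is.unsorted(t0, strictly = FALSE)) stop("timestamps must be sorted")
  n <- length(t0)
  if (n < 2L) return(integer(0))
  best <- integer(0)
  for (start in seq_len(n)) {
    chain <- start
    repeat {
      cur <- chain[length(chain)]
      nxt <- which(gap_in_bin(t0 - t0[cur], bin) & seq_len(n) > cur)
      if (length(nxt) == 0L) break
      chain <- c(chain, nxt[1])
    }
    if (length(chain) > length(best)) best <- chain
  }
  if (length(best) < 2L) integer(0) else best
}

#' Build the train/validation split for one calibration bin
#'
#' For every subject with a qualifying chain (length >= 2), recordings at odd
#' chain positions (1st, 3rd, ...) contribute all their images to training —
#' these are the calibration measurements — and even positions contribute to
#' validation, so each interior validation recording lies between two
#' training recordings of the same subject. All images of subjects with no
#' qualifying chain are added to training. Images of a selected subject's
#' recordings outside its chain are used in neither set.
#'
#' @param images Image manifest tibble (from [segment_scalograms()]):
#'   `image_id`, `subject_id`, `recording_id`, `parity_index`, `t0`, `label`,
#'   plus `image` or `image_path`.
#' @param recordings Recording-level tibble with `recording_id`,
#'   `subject_id`, `t0` (e.g. `preprocess_cohort()$recordings`).
#' @param bin Bin name or one-row bin tibble.
#' @return Object of class `calibration_split`: list with `bin`, `train`,
#'   `val` (manifest subsets), `selected_subjects`, `unselected_subjects`,
#'   and `accounting` (one row: images from odd segments, from unselected
#'   subjects, and from even segments).
#' @export
build_split <- function(images, recordings, bin) {
  bin <- as_bin(bin)
  subs <- split(recordings[order(recordings$t0), ], recordings$subject_id[order(recordings$t0)])

  train_rec <- character(0)
  val_rec <- character(0)
  selected <- character(0)
  for (sid in names(subs)) {
    rs <- subs[[sid]]
    chain <- select_interval_sequence(rs$t0, bin)
    if (length(chain) >= 2L) {
      selected <- c(selected, sid)
      odd <- chain[seq_along(chain) %% 2L == 1L]
      even <- chain[seq_along(chain) %% 2L == 0L]
      train_rec <- c(train_rec, rs$recording_id[odd])
      val_rec <- c(val_rec, rs$recording_id[even])
    }
  }
  unselected <- setdiff(names(subs), selected)

  train_odd <- dplyr::filter(images, .data$recording_id %in% train_rec)
  train_uns <- dplyr::filter(images, .data$subject_id %in% unselected)
  val <- dplyr::filter(images, .data$recording_id %in% val_rec)
  if (nrow(val) == 0L) {
    warning("bin ", bin$name, ": no subject qualifies; validation set is empty")
  }

  out <- list(
    bin = bin,
    train = dplyr::bind_rows(train_odd, train_uns),
    val = val,
    selected_subjects = selected,
    unselected_subjects = unselected,
    accounting = tibble::tibble(
      bin = bin$name,
      odd_segment_images = nrow(train_odd),
      unselected_subject_images = nrow(train_uns),
      even_segment_images = nrow(val)
    )
  )
  class(out) <- "calibration_split"
  out
}

#' @export
print.calibration_split <- function(x, ...) {
  cat("<calibration_split> bin ", x$bin$name, ": train ",
      nrow(x$train), " (", x$accounting$odd_segment_images, " odd + ",
      x$accounting$unselected_subject_images, " unselected), val ",
      nrow(x$val), " images; ", length(x$selected_subjects),
      " selected subject(s)\n", sep = "")
  invisible(x)
}

#' Write a split's manifests and accounting summary
#'
#' Writes `split_<bin>.csv` (`set`, `image_path`/`image_id`, `subject_id`,
#' `label`) and `accounting_<bin>.json` (the three image counts).
#'
#' @param split A `calibration_split`.
#' @param dir Output directory.
#' @return Invisibly, the combined manifest tibble.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pick <- function(df, set) {
    cols <- intersect(c("image_id", "image_path", "subject_id", "label"),
                      names(df))
    out <- df[, cols]
    out$set <- set
    out
  }
  man <- dplyr::bind_rows(pick(split$train, "train"), pick(split$val, "val"))
  utils::write.csv(man, file.path(dir, paste0("split_", split$bin$name, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(as.list(split$accounting),
                       file.path(dir, paste0("accounting_", split$bin$name, ".json")),
                       auto_unbox = TRUE)
  invisible(man)
}
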