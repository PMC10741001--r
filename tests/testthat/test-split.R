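# Minimal image manifest: 12 images per recording, labels per subject.
fake_manifest <- function(recordings, labels) {
  purrr::map_dfr(seq_len(nrow(recordings)), function(i) {
    tibble::tibble(
      image_id = sprintf("%s_seg%02d", recordings$recording_id[i], 1:12),
      subject_id = recordings$subject_id[i],
      recording_id = recordings$recording_id[i],
      parity_index = 1:12,
      t0 = recordings$t0[i] + 10 * (0:11),
      label = labels[recordings$subject_id[i]]
    )
  })
}

test_that("the four bins partition the positive axis", {
  b <- interval_bins()
  expect_equal(b$name, c("lt1h", "1to6h", "6to24h", "gt24h"))
  expect_equal(b$lower_s[-1], b$upper_s[-4])
  expect_equal(b$lower_s[1], 0)
  expect_true(is.infinite(b$upper_s[4]))
})

test_that("interval chains match the exhaustive enumeration oracle", {
  t0 <- c(0, 30, 60, 90) * 60
  chain <- select_interval_sequence(t0, "lt1h")
  expect_equal(chain, 1:4)
  expect_equal(length(chain), oracle_longest_chain_len(t0, 0, 3600))

  expect_equal(select_interval_sequence(100, "lt1h"), integer(0))
  expect_equal(select_interval_sequence(c(0, 10 * 3600), "lt1h"), integer(0))
  expect_equal(select_interval_sequence(c(0, 10 * 3600), "6to24h"), c(1L, 2L))
})

test_that("chain extraction agrees with a brute-force re-derivation of the greedy rule", {
  set.seed(7)
  bins <- interval_bins()
  for (rep in 1:25) {
    t0 <- sort(stats::runif(sample(2:8, 1), 0, 3 * 86400))
    bin <- bins[sample(4, 1), ]
    chain <- select_interval_sequence(t0, bin)
    # brute force: grow greedily from every start, earliest qualifying next
    grow <- function(s) {
      ch <- s
      repeat {
        g <- t0 - t0[ch[length(ch)]]
        nxt <- which(g >= bin$lower_s & g < bin$upper_s &
                       seq_along(t0) > ch[length(ch)])
        if (!length(nxt)) break
        ch <- c(ch, min(nxt))
      }
      ch
    }
    all_chains <- lapply(seq_along(t0), grow)
    lens <- lengths(all_chains)
    expected <- all_chains[[which.max(lens)]]
    if (max(lens) < 2) expected <- integer(0)
    expect_equal(chain, expected)
    if (length(chain)) {
      gaps <- diff(t0[chain])
      expect_true(all(gaps >= bin$lower_s & gaps < bin$upper_s))
    }
  }
})

test_that("odd chain positions train, even validate, unselected subjects train", {
  recs <- tibble::tibble(
    recording_id = c("A_R1", "A_R2", "A_R3", "A_R4", "B_R1", "B_R2"),
    subject_id = c("A", "A", "A", "A", "B", "B"),
    t0 = c(0, 1800, 3600, 5400, 0, 7 * 3600)
  )
  labels <- c(A = "HTS", B = "NTS")
  man <- fake_manifest(recs, labels)
  sp <- build_split(man, recs, "lt1h")
  expect_equal(nrow(sp$train), 48)  # 2 odd recordings + 2 unselected
  expect_equal(nrow(sp$val), 24)    # 2 even recordings
  expect_setequal(sp$selected_subjects, "A")
  expect_setequal(sp$unselected_subjects, "B")
  expect_equal(sp$accounting$odd_segment_images, 24)
  expect_equal(sp$accounting$unselected_subject_images, 24)
  expect_equal(sp$accounting$even_segment_images, 24)
  expect_length(intersect(sp$train$image_id, sp$val$image_id), 0)
  # no unselected-subject image in validation
  expect_false(any(sp$val$subject_id %in% sp$unselected_subjects))
  # two-recording chain with nobody unselected: 12 train / 12 val
  sp2 <- build_split(man[man$subject_id == "B", ],
                     recs[recs$subject_id == "B", ], "6to24h")
  expect_equal(nrow(sp2$train), 12)
  expect_equal(nrow(sp2$val), 12)
})

test_that("a bin with no qualifying subject warns and yields an empty validation set", {
  recs <- tibble::tibble(recording_id = c("A_R1", "A_R2"),
                         subject_id = "A", t0 = c(0, 1800))
  man <- fake_manifest(recs, c(A = "NTS"))
  expect_warning(sp <- build_split(man, recs, "gt24h"), "empty")
  expect_equal(nrow(sp$val), 0)
  expect_equal(nrow(sp$train), 24)  # both recordings via the unselected route
})

test_that("split invariants hold on a randomised cohort schedule", {
  set.seed(21)
  recs <- purrr::map_dfr(1:8, function(i) {
    n <- sample(2:7, 1)
    tibble::tibble(
      recording_id = sprintf("S%d_R%d", i, seq_len(n)),
      subject_id = sprintf("S%d", i),
      t0 = sort(stats::runif(n, 0, 3 * 86400)))
  })
  labels <- stats::setNames(sample(c("NTS", "HTS"), 8, TRUE),
                            sprintf("S%d", 1:8))
  man <- fake_manifest(recs, labels)
  for (k in 1:4) {
    bin <- interval_bins()[k, ]
    sp <- suppressWarnings(build_split(man, recs, bin))
    # leakage audit
    expect_length(intersect(sp$train$image_id, sp$val$image_id), 0)
    expect_true(all(sp$val$subject_id %in% sp$selected_subjects))
    # accounting bound
    expect_lte(nrow(sp$train) + nrow(sp$val), nrow(man))
    # parity re-derivation per selected subject
    for (sid in sp$selected_subjects) {
      rs <- recs[recs$subject_id == sid, ]
      rs <- rs[order(rs$t0), ]
      chain <- select_interval_sequence(rs$t0, bin)
      odd_ids <- rs$recording_id[chain[seq_along(chain) %% 2 == 1]]
      even_ids <- rs$recording_id[chain[seq_along(chain) %% 2 == 0]]
      expect_setequal(unique(sp$val$recording_id[sp$val$subject_id == sid]),
                      even_ids)
      in_train <- unique(sp$train$recording_id[sp$train$subject_id == sid])
      expect_setequal(in_train, odd_ids)
      # calibration semantics: interior validation recordings sit between
      # two training recordings of the same subject
      tr_t0 <- rs$t0[match(odd_ids, rs$recording_id)]
      for (vid in even_ids) {
        vt <- rs$t0[match(vid, rs$recording_id)]
        if (vt < max(tr_t0)) {
          expect_true(any(tr_t0 < vt) && any(tr_t0 > vt))
        }
      }
    }
  }
})

test_that("split manifests and accounting serialise to disk", {
  recs <- tibble::tibble(recording_id = c("A_R1", "A_R2"),
                         subject_id = "A", t0 = c(0, 1800))
  man <- fake_manifest(recs, c(A = "NTS"))
  sp <- build_split(man, recs, "lt1h")
  dir <- withr::local_tempdir()
  write_split(sp, dir)
  csv <- utils::read.csv(file.path(dir, "split_lt1h.csv"))
  expect_setequal(unique(csv$set), c("train", "val"))
  acc <- jsonlite::read_json(file.path(dir, "accounting_lt1h.json"),
                             simplifyVector = TRUE)
  expect_equal(acc$odd_segment_images, 12)
  expect_equal(acc$even_segment_images, 12)
})
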