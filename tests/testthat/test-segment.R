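test_that("event split reproduces 70/30 event counts and re-bases markers", {
  # training counts for sessions of 183/218/66/27 events at 70%
  for (case in list(c(183L, 128L), c(218L, 153L), c(66L, 46L), c(27L, 19L))) {
    n_ev <- case[1L]
    pos <- as.integer(seq(300, 300 + (n_ev - 1L) * 400, by = 400))
    rec <- eeg_recording(matrix(rnorm(2 * (max(pos) + 300)), 2), fs = 250,
                         channel_labels = c("A", "B"), markers = pos)
    parts <- split_by_events(rec, 0.7)
    expect_equal(nrow(parts$train$markers), case[2L])
    expect_equal(nrow(parts$validation$markers), n_ev - case[2L])
  }
})

test_that("event split keeps every sample and marker accounted for", {
  pos <- as.integer(seq(100, 1900, by = 200))  # 10 equally spaced events
  rec <- noise_recording(n_channels = 1, n = 2000, markers = pos)
  parts <- split_by_events(rec, 0.5)
  expect_equal(nrow(parts$train$markers), 5L)
  expect_equal(nrow(parts$validation$markers), 5L)
  expect_equal(n_samples(parts$train) + n_samples(parts$validation), 2000L)
  # brute-force membership: re-based validation markers point at the same
  # underlying samples
  cut <- n_samples(parts$train)
  expect_equal(parts$validation$markers$sample_index + cut, pos[6:10])
  expect_true(all(parts$validation$markers$sample_index >= 1))
  expect_true(all(parts$train$markers$sample_index <= cut))
  expect_error(split_by_events(noise_recording(markers = integer())),
               "no event markers|no markers")
})

test_that("training segmentation matches brute-force enumeration on known cases", {
  # single centred marker: one positive window, one negative per leftover run
  rec <- noise_recording(n_channels = 1, n = 1000, markers = 501L)
  ds <- make_training_set(rec, size = 250, overlap = 0)
  expect_equal(sum(ds$label == 1L), 1L)
  expect_equal(ds$start[ds$label == 1L], 376L)
  oracle <- enumerate_training_windows(1000, 501L, 250, 0)
  expect_equal(sort(ds$start[ds$label == 0L]), sort(oracle$neg))
  expect_equal(length(oracle$neg), 2L)

  # no markers, 50% overlap: negatives tile with stride 125
  rec0 <- noise_recording(n_channels = 1, n = 1000)
  ds0 <- make_training_set(rec0, size = 250, overlap = 0.5)
  expect_equal(sum(ds0$label), 0L)
  expect_equal(ds0$start, seq(1L, 751L, by = 125L))
  expect_equal(nrow(ds0$X), 7L)

  # marker too close to the edge is skipped with a warning
  rec_edge <- noise_recording(n_channels = 1, n = 1000, markers = 11L)
  expect_warning(ds_e <- make_training_set(rec_edge, size = 250), "skipped")
  expect_equal(sum(ds_e$label == 1L), 0L)

  expect_error(make_training_set(rec0, size = 2000), "exceeds")
})

test_that("sliding segmentation produces the arithmetic window grid", {
  rec <- noise_recording(n_channels = 1, n = 1000, markers = 301L)
  ds <- make_sliding_set(rec, size = 250, overlap = 0.8)
  expect_equal(nrow(ds$X), 16L)  # floor((1000-250)/50)+1
  expect_equal(ds$start, seq(1L, 751L, by = 50L))
  # every window whose half-open range holds the marker is labelled 1
  hit <- ds$start[ds$label == 1L]
  expect_equal(hit, c(101L, 151L, 201L, 251L, 301L))

  ds0 <- make_sliding_set(noise_recording(n = 1000), size = 250, overlap = 0)
  expect_true(all(ds0$label == 0L))
  expect_equal(ds0$start, c(1L, 251L, 501L, 751L))
  expect_error(make_sliding_set(rec, size = 250, overlap = 0.999),
               "stride")
})

test_that("segmentation invariants hold on random fixtures", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(800:3000, 1)
    n_mk <- sample(0:6, 1)
    mk <- if (n_mk) sort(sample(200:(n - 200), n_mk)) else integer()
    size <- sample(c(50L, 100L, 250L), 1)
    ov <- sample(c(0, 0.25, 0.5, 0.8), 1)
    rec <- noise_recording(n_channels = 1, n = n, markers = mk, seed = i)

    ds <- suppressWarnings(make_training_set(rec, size, ov))
    oracle <- enumerate_training_windows(n, mk, size, ov)
    expect_equal(sort(ds$start[ds$label == 1L]), sort(oracle$pos))
    expect_equal(sort(ds$start[ds$label == 0L]), sort(oracle$neg))
    # conservation: positive ranges and negative runs never overlap
    if (length(oracle$pos) && length(oracle$neg)) {
      pos_samples <- unique(unlist(lapply(oracle$pos, function(s) s:(s + size - 1L))))
      expect_false(any(oracle$neg %in% pos_samples))
    }

    sl <- make_sliding_set(rec, size, ov)
    # label soundness against a literal scan
    lab <- vapply(sl$start, function(s) any(mk >= s & mk < s + size), TRUE)
    expect_equal(sl$label, as.integer(lab))
  }
})

test_that("raising the overlap never reduces the sliding window count", {
  rec <- noise_recording(n_channels = 1, n = 2000)
  counts <- vapply(seq(0, 0.9, by = 0.1), function(ov)
    nrow(make_sliding_set(rec, 250, ov)$X), 0L)
  expect_true(all(diff(counts) >= 0L))
})
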