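test_that("derived threshold is the maximum clean-window power", {
  rec <- recording(matrix(0, 1, 100), fs = 100)
  g <- make_windows(rec, 0.1) # 10-sample windows
  expect_equal(derive_threshold(list(rep(2, 30)), g)$values, 4)
  expect_equal(derive_threshold(list(rep(0, 20), rep(c(1, -1), 10)), g)$values, 1)
  set.seed(4)
  epochs <- lapply(1:10, function(i) rnorm(10 * sample(2:5, 1)))
  oracle <- max(unlist(lapply(epochs, function(ep) {
    nw <- length(ep) %/% 10
    vapply(seq_len(nw), function(w) mean(ep[(w - 1) * 10 + 1:10]^2), 0)
  })))
  expect_equal(derive_threshold(epochs, g)$values, oracle)
  expect_error(derive_threshold(list(rnorm(5)), g), "invalid epoch")
})

test_that("labelling uses strict exceedance with ties labelled clean", {
  rec <- recording(matrix(rep(c(1, 2), each = 10), 1), fs = 10)
  g <- make_windows(rec, 1) # two 10-sample windows, powers 1 and 4
  expect_equal(as.vector(label_windows(rec, g, threshold_spec(10))$labels),
               c(0L, 0L))
  # power exactly equal to the threshold stays clean
  expect_equal(as.vector(label_windows(rec, g, threshold_spec(1))$labels),
               c(0L, 1L))
})

test_that("injected artefact windows are exactly the labelled ones", {
  fx <- small_fixture()
  expect_gt(sum(fx$truth$labels), 0)
  expect_identical(fx$labels$labels, fx$truth$labels)
})

test_that("clean-segment extraction follows the greedy non-overlapping scan", {
  lr <- labelled_recording(c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  segs <- extract_clean_segments(lr$recording, lr$labels, 0.2) # 2 windows
  expect_equal(length(segs$clean), 4L)
  expect_equal(segs$clean_meta$start_window, c(1L, 3L, 6L, 8L))

  all_art <- labelled_recording(rep(1, 10))
  expect_equal(length(extract_clean_segments(all_art$recording,
                                             all_art$labels, 0.2)$clean), 0L)

  all_clean <- labelled_recording(rep(0, 10))
  expect_equal(length(extract_clean_segments(all_clean$recording,
                                             all_clean$labels, 0.2)$clean), 5L)
  expect_error(extract_clean_segments(lr$recording, lr$labels, 0.15),
               "geometry error")
})

test_that("artefactual segments require a clean prefix and an artefact", {
  lr <- labelled_recording(c(0, 0, 0, 0, 1, 1, 0, 0))
  segs <- extract_artefactual_segments(lr$recording, lr$labels, 0.8, 0.4)
  expect_equal(length(segs$artefactual), 1L)
  expect_equal(segs$artefactual[[1]]$window_labels,
               c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L))
  expect_equal(which(segs$artefactual[[1]]$window_labels == 1L), c(5L, 6L))

  none <- labelled_recording(rep(0, 8))
  expect_equal(length(extract_artefactual_segments(none$recording,
                                                   none$labels, 0.8, 0.4)$artefactual), 0L)
  # artefact at the very start leaves no clean prefix
  first <- labelled_recording(c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(length(extract_artefactual_segments(first$recording,
                                                   first$labels, 0.8, 0.4)$artefactual), 0L)
})

test_that("the joint scan never lets the two segment families overlap", {
  fx <- small_fixture()
  segs <- fx$segments
  cover <- function(meta, len) {
    unlist(lapply(seq_len(nrow(meta)), function(i) {
      meta$start_sample[i] + seq_len(len) - 1L
    }))
  }
  clean_cov <- cover(segs$clean_meta, segs$segment_len)
  art_cov <- cover(segs$artefactual_meta, segs$segment_len)
  expect_length(intersect(clean_cov, art_cov), 0L)
  # and clean segments truly contain no artefact window
  for (i in seq_len(nrow(segs$clean_meta))) {
    w0 <- segs$clean_meta$start_window[i]
    nw <- segs$segment_len / segs$grid$window_len
    expect_equal(sum(fx$labels$labels[segs$clean_meta$channel[i],
                                      w0:(w0 + nw - 1)]), 0L)
  }
})

test_that("splits follow round(fraction * n) with remainder to train", {
  lr <- labelled_recording(rep(0, 40), window_len = 5L)
  segs <- extract_clean_segments(lr$recording, lr$labels, 0.1) # 20 segments
  segs$clean <- segs$clean[1:10]
  s10 <- split_segments(segs, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(as.vector(table(s10$split)), c(8L, 1L, 1L))
  # determinism and partition
  s10b <- split_segments(segs, c(0.8, 0.1, 0.1), seed = 1)
  expect_identical(s10$split, s10b$split)
  expect_false(anyNA(s10$split))
  segs$clean <- replicate(1000, rnorm(10), simplify = FALSE)
  s1000 <- split_segments(segs, c(0.8, 0.1, 0.1), seed = 2)
  expect_equal(as.vector(table(s1000$split)), c(800L, 100L, 100L))
  segs$clean <- segs$clean[1:2]
  expect_error(split_segments(segs), "insufficient data")
})

test_that("configuration grids have the published sizes and ordering", {
  g1 <- build_config_grid(seq(0.1, 0.9, by = 0.1), c(1, 5, 10, 25, 50, 100))
  expect_equal(nrow(g1), 54L)
  g2 <- build_config_grid(c(1, 2, 3), c(1, 25, 50, 125, 250))
  expect_equal(nrow(g2), 15L)
  expect_equal(nrow(build_config_grid(1, 1)), 1L)
  # input-major ordering: input varies slowest
  expect_equal(g1$input_s[1:6], rep(0.1, 6))
  expect_equal(g1$output_len[1:6], c(1L, 5L, 10L, 25L, 50L, 100L))
  expect_error(build_config_grid(c(1, 1), 1), "duplicate")
  expect_error(build_config_grid(numeric(0), 1), "non-empty")
})
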