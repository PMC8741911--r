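test_that("the baseline generator is seeded, zero-sigma-safe and stationary", {
  spec0 <- synth_spec(duration_s = 10, sigma = 0, events = list(), seed = 1)
  expect_true(all(generate_baseline(spec0)$data == 0))
  spec <- synth_spec(duration_s = 60, events = list(), seed = 2)
  r1 <- generate_baseline(spec)
  r2 <- generate_baseline(spec)
  expect_identical(r1$data, r2$data)
  # first- and second-half variances agree within 20% on long realisations
  long <- generate_baseline(synth_spec(duration_s = 300, events = list(),
                                       seed = 4))
  x <- long$data[1, ]
  v1 <- var(x[seq_len(length(x) / 2)])
  v2 <- var(x[-seq_len(length(x) / 2)])
  expect_lt(abs(v1 - v2) / v1, 0.2)
  # marginal sd close to the requested sigma
  expect_equal(sd(x), 0.05, tolerance = 0.15)
  expect_error(generate_baseline(synth_spec(ar = c(1.2, 0.3), events = list())),
               "stability error")
})

test_that("the AR(2) resonance puts the spectral peak at the requested frequency", {
  spec <- synth_spec(duration_s = 300, ar = ar_resonance(8, 0.97, 250),
                     events = list(), seed = 6)
  x <- generate_baseline(spec)$data[1, ]
  p <- averaged_periodogram(x, 250, chunk_seconds = 2) # 0.5 Hz bins
  peak <- p$freq[which.max(p$power)]
  expect_lte(abs(peak - 8), 0.5)
})

test_that("artefact injection is exact, seeded and separable", {
  spec <- synth_spec(duration_s = 60, events = list(), seed = 8)
  base <- generate_baseline(spec)
  # zero rates: unchanged recording, empty truth
  inj0 <- inject_artefacts(base, spec)
  expect_identical(inj0$recording$data, base$data)
  expect_equal(sum(inj0$truth$labels), 0L)
  # reproducibility of the seeded point process
  spec1 <- synth_spec(duration_s = 60,
                      events = list(list(kind = "amplitude_transient",
                                         amplitude = 10, duration_s = 1,
                                         rate_per_min = 5)),
                      seed = 8)
  injA <- inject_artefacts(base, spec1)
  injB <- inject_artefacts(base, spec1)
  expect_identical(injA$recording$data, injB$recording$data)
  expect_identical(injA$truth$labels, injB$truth$labels)
  expect_gt(sum(injA$truth$labels), 0)
  # every affected window exceeds the threshold of the clean remainder
  grid <- injA$truth$grid
  thr <- derive_threshold(list(base$data[1, ]), grid)
  pw <- window_powers(injA$recording, grid)
  hit <- injA$truth$labels[1, ] == 1L
  expect_true(all(pw[1, hit] > thr$values))
  expect_true(all(pw[1, !hit] <= thr$values))
  # separability floor: at least amplitude^2/4 of the mean background power
  expect_true(all(pw[1, hit] >= 10^2 / 4 * mean(base$data^2)))
})

test_that("event counts match the Bernoulli-per-window rate in expectation", {
  rate <- 6 # per minute, 1-s windows -> p = 0.1 per window
  spec <- synth_spec(duration_s = 600,
                     events = list(list(kind = "baseline_jump",
                                        amplitude = 10, duration_s = 1,
                                        rate_per_min = rate)),
                     seed = 9)
  base <- generate_baseline(spec)
  inj <- inject_artefacts(base, spec)
  n <- sum(inj$truth$labels)
  expected <- rate / 60 * 600
  expect_lt(abs(n - expected) / expected, 0.5) # binomial, seeded
  # the realised draw equals an independently seeded Bernoulli draw
  p_win <- rate / 60
  hits <- withr::with_seed(spec$seed + 7919L,
                           which(runif(inj$truth$grid$n_windows) < p_win))
  expect_equal(which(inj$truth$labels[1, ] == 1L), hits)
})

test_that("labels recall every injected window when the multiplier is >= 10", {
  for (seed in c(11, 12)) {
    fx <- make_fixture_dataset(
      synth_spec(duration_s = 120,
                 events = list(list(kind = "amplitude_transient",
                                    amplitude = 10, duration_s = 1,
                                    rate_per_min = 3)),
                 seed = seed))
    hit <- fx$truth$labels == 1L
    expect_true(all(fx$labels$labels[hit] == 1L)) # recall 1.0
    expect_identical(fx$labels$labels, fx$truth$labels)
  }
})

test_that("the fixture data set splits and reproduces deterministically", {
  fx <- small_fixture()
  n <- length(fx$segments$clean)
  tab <- table(fx$segments$split)
  expect_equal(as.vector(tab["val"]), round(0.1 * n))
  expect_equal(as.vector(tab["test"]), round(0.1 * n))
  expect_equal(sum(tab), n)
  # zero artefact rate leaves the artefactual set empty
  fx0 <- make_fixture_dataset(synth_spec(duration_s = 60, events = list(),
                                         seed = 5))
  expect_length(fx0$segments$artefactual, 0L)
  # byte-identical across runs with one seed
  fx2 <- make_fixture_dataset(fx$spec)
  expect_identical(fx$recording$data, fx2$recording$data)
  expect_identical(fx$segments$split, fx2$segments$split)
})
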