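test_that("recursive forecasting invokes the model ceil(horizon/output_len) times", {
  stub <- recording_stub(input_len = 50, output_len = 10)
  out <- recursive_forecast(stub, rnorm(50), horizon = 200)
  expect_length(out, 200L)
  expect_equal(stub$trace$calls, 20L)
  stub2 <- recording_stub(input_len = 50, output_len = 10)
  out2 <- recursive_forecast(stub2, rnorm(50), horizon = 5)
  expect_length(out2, 5L)
  expect_equal(stub2$trace$calls, 1L)
  expect_equal(recursive_forecast(constant_model(3, 20, 7), rnorm(20), 18),
               rep(3, 18))
})

test_that("each recursion step slides the context over its own forecasts", {
  stub <- recording_stub(input_len = 20, output_len = 10, value = 7)
  ctx <- rnorm(20)
  recursive_forecast(stub, ctx, horizon = 30)
  expect_equal(stub$trace$contexts[[1]], ctx)
  expect_equal(stub$trace$contexts[[2]], c(ctx[11:20], rep(7, 10)))
  expect_equal(stub$trace$contexts[[3]], rep(7, 20))
})

test_that("non-finite predictions name the failing step", {
  bad <- stub_model(function(context) rep(NaN, 5), 10, 5)
  expect_error(recursive_forecast(bad, rnorm(10), 5),
               "propagation error.*step 1")
})

test_that("clean recordings pass through replacement untouched", {
  lr <- labelled_recording(rep(0, 10), window_len = 50L, fs = 100)
  model <- constant_model(0, input_len = 100, output_len = 50)
  res <- replace_artefacts(lr$recording, lr$labels, model)
  expect_identical(res$recording$data, lr$recording$data)
  expect_length(res$log$channels[[1]]$replaced, 0L)
})

test_that("artefact runs are replaced in one recursive pass with forecast context", {
  lr <- labelled_recording(c(0, 0, 0, 0, 1, 1), window_len = 50L, fs = 100)
  stub <- recording_stub(input_len = 200, output_len = 50, value = 0.5)
  res <- replace_artefacts(lr$recording, lr$labels, stub)
  expect_equal(res$log$channels[[1]]$replaced, c(5L, 6L))
  # both windows now hold the stub's forecasts
  expect_equal(res$recording$data[1, 201:300], rep(0.5, 100))
  # first call sees the 200 true samples before the run; the second call's
  # context ends with the 50 forecast samples of the first window
  expect_equal(stub$trace$contexts[[1]], lr$recording$data[1, 1:200])
  expect_equal(stub$trace$contexts[[2]],
               c(lr$recording$data[1, 51:200], rep(0.5, 50)))
  # artefact-free samples are bit-identical
  expect_identical(res$recording$data[1, 1:200], lr$recording$data[1, 1:200])
})

test_that("windows without context are logged unreplaceable and untouched", {
  lr <- labelled_recording(c(1, 0, 0, 0), window_len = 50L, fs = 100)
  model <- constant_model(9, input_len = 100, output_len = 50)
  res <- replace_artefacts(lr$recording, lr$labels, model)
  expect_identical(res$recording$data, lr$recording$data)
  log1 <- res$log$channels[[1]]
  expect_equal(log1$unreplaceable$window, 1L)
  expect_equal(log1$unreplaceable$reason, "insufficient_context")
  # replaced and unreplaceable partition the artefact windows
  art <- which(lr$labels$labels[1, ] == 1L)
  expect_setequal(c(log1$replaced, log1$unreplaceable$window), art)
})

test_that("replacement preserves all artefact-free samples and the length", {
  fx <- small_fixture()
  model <- constant_model(0, input_len = 250, output_len = 250)
  res <- replace_artefacts(fx$recording, fx$labels, model)
  expect_equal(dim(res$recording$data), dim(fx$recording$data))
  keep <- rep(TRUE, n_samples(fx$recording))
  for (w in which(fx$labels$labels[1, ] == 1L)) {
    keep[window_samples(fx$grid, w)] <- FALSE
  }
  expect_identical(res$recording$data[1, keep], fx$recording$data[1, keep])
})

test_that("re-running replacement on the cleaned signal replaces no more windows", {
  fx <- small_fixture()
  model <- constant_model(0, input_len = 250, output_len = 250)
  res1 <- replace_artefacts(fx$recording, fx$labels, model)
  labels2 <- label_windows(res1$recording, fx$grid, fx$threshold)
  res2 <- replace_artefacts(res1$recording, labels2, model)
  n1 <- length(res1$log$channels[[1]]$replaced)
  n2 <- length(res2$log$channels[[1]]$replaced)
  expect_lte(n2, n1)
})

test_that("over-long artefact runs trigger the drift warning", {
  lr <- labelled_recording(c(0, 0, 1, 1, 1), window_len = 50L, fs = 100)
  model <- constant_model(0, input_len = 100, output_len = 50)
  expect_warning(replace_artefacts(lr$recording, lr$labels, model,
                                   max_run = 2),
                 "drift")
})
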