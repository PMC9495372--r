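fs <- 1000
t5 <- seq(0, 5, by = 1 / fs)

test_that("the band-pass filter stops DC, passes 100 Hz and rejects 5 Hz", {
  dc <- bandpass_filter(rep(2, 5001), fs)
  expect_lt(max(abs(dc[1000:4000])), 1e-6 * 2)

  pass <- bandpass_filter(sin(2 * pi * 100 * t5), fs)
  g <- max(abs(pass[1000:4000]))
  expect_gte(g, 0.95)
  expect_lte(g, 1.0)

  stop5 <- bandpass_filter(sin(2 * pi * 5 * t5), fs)
  expect_lt(max(abs(stop5[1000:4000])), 0.3)

  expect_error(bandpass_filter(rnorm(100), fs, low = 20, high = 600),
               class = "emg_parameter_error")
  expect_length(pass, length(t5))
})

test_that("sliding RMS matches closed forms and its bounds", {
  expect_equal(sliding_rms(rep(-3, 600), fs), rep(3, 351))

  # 250 ms window = 25 periods of a 100 Hz sine -> RMS = 1/sqrt(2)
  x <- sin(2 * pi * 100 * t5)
  r <- sliding_rms(x, fs)
  expect_equal(mean(r), 1 / sqrt(2), tolerance = 1e-3)

  y <- gen_colored_noise(2000, beta = 0, seed = 31)
  expect_lte(max(sliding_rms(y, fs)), max(abs(y)))
  expect_equal(sliding_rms(y, fs), sliding_rms(-y, fs))
  expect_error(sliding_rms(rnorm(100), fs, window_ms = 250),
               class = "emg_parameter_error")
})

test_that("the MVC peak finder locates peaks, honors ties and flags flat traces", {
  tr <- gen_emg_trial(seed = 32)
  pk <- find_mvc_peak(tr$data$torque, fs)
  expect_gt(pk$time, 0.5)       # inside the plateau
  expect_lt(pk$time, 4.5)
  expect_equal(pk$value, max(tr$data$torque))

  spike <- c(rep(0, 400), 5, rep(0, 599))
  expect_equal(find_mvc_peak(spike, fs)$index, 401, tolerance = 1)

  two <- c(rep(0, 100), 5, rep(0, 299), 5, rep(0, 500))
  expect_equal(find_mvc_peak(two, fs)$index, 101)

  expect_warning(res <- find_mvc_peak(rep(1, 1000), fs),
                 class = "emg_degenerate_input")
  expect_equal(res$index, 500)
})

test_that("MVC windows are 1 s, centered on the peak, clamped at edges", {
  tr <- gen_emg_trial(seed = 33)
  w <- extract_mvc_window(tr)
  expect_equal(nrow(w$data), 1000)
  pk <- find_mvc_peak(tr$data$torque, fs)
  expect_equal(w$start_time, pk$time - 0.5, tolerance = 2e-3)

  # early peak -> clamped to the trial start
  early <- emg_trial(tibble::tibble(
    time = t5[1:3000], torque = c(rep(0, 150), 10, rep(0, 2849)) ,
    emg_bf = rnorm(3000), emg_st = rnorm(3000)
  ), sampling_rate = fs)
  expect_warning(we <- extract_mvc_window(early), class = "emg_window_clamped")
  expect_equal(we$start_time, 0)
  expect_equal(nrow(we$data), 1000)

  short <- emg_trial(tibble::tibble(time = t5[1:500], torque = rnorm(500),
                                    emg_bf = rnorm(500), emg_st = rnorm(500)),
                     sampling_rate = fs)
  expect_error(extract_mvc_window(short), class = "emg_extraction_error")
})

test_that("the submaximal window is exactly seconds 3 to 4", {
  tr <- gen_emg_trial(contraction = "submaximal", seed = 34)
  w <- extract_submax_window(tr)
  expect_equal(nrow(w$data), 1000)
  expect_equal(w$data$time[1], 3)
  expect_equal(w$data$time[1000], 3.999)
  expect_equal(mean(w$data$torque), 40, tolerance = 2)

  short <- emg_trial(tibble::tibble(time = t5[1:3500], torque = rnorm(3500),
                                    emg_bf = rnorm(3500), emg_st = rnorm(3500)),
                     sampling_rate = fs)
  expect_error(extract_submax_window(short), class = "emg_extraction_error")
})

test_that("window summaries use max for maximal and mean for submaximal", {
  tr <- gen_emg_trial(contraction = "submaximal", seed = 35)
  w <- extract_submax_window(tr)
  w$data$torque <- rep(50, 1000)
  expect_equal(summarize_window(w, "torque", "submaximal"), 50)

  r <- sliding_rms(w$data$emg_bf, fs, 250)
  expect_equal(summarize_window(w, "emg_bf", "maximal"), max(r))
  expect_equal(summarize_window(w, "emg_bf", "submaximal"), mean(r))
  expect_lte(summarize_window(w, "emg_bf", "submaximal"),
             summarize_window(w, "emg_bf", "maximal"))
})
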