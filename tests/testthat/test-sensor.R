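test_that("PVDF output is the scaled displacement rate", {
  const <- new_signal(rep(2, 100), fs = 100, unit = "du")
  expect_equal(pvdf_record(const)$value, rep(0, 100))

  ramp <- new_signal(seq(0, 1, length.out = 101), fs = 100, unit = "du")
  v <- pvdf_record(ramp, sensor_config(sensitivity = 1))
  expect_equal(v$value, rep(1, 101), tolerance = 1e-9) # unit slope in du/s
  expect_equal(signal_unit(v), "volt")

  v2 <- pvdf_record(ramp, sensor_config(sensitivity = 3.5))
  expect_equal(v2$value, rep(3.5, 101), tolerance = 1e-9)
})

test_that("integration inverts recording up to a constant (R^2 > 0.999)", {
  p <- pulse_params(heart_rate = 1.1, beat_jitter = 0, noise_sd = 0, seed = 2)
  w <- generate_pulse(p, 8, 1000)
  back <- integrate_signal(pvdf_record(w))
  expect_equal(signal_unit(back), "du")
  expect_gt(
    r_squared(w$value - mean(w$value), back$value - mean(back$value)),
    0.999
  )
  # the recovered waveform still shows the per-beat features
  ext <- find_extrema(back$value)
  expect_gte(length(ext$maxima), 2 * 8) # at least percussion + one more per beat
})

test_that("cumulative trapezoid integration behaves analytically", {
  z <- new_signal(rep(0, 50), fs = 10, unit = "volt")
  expect_equal(integrate_signal(z)$value, rep(0, 50))
  c3 <- new_signal(rep(3, 50), fs = 10, unit = "volt")
  y <- integrate_signal(c3)$value
  expect_equal(y[1], 0)
  expect_equal(y, 3 * (0:49) / 10, tolerance = 1e-12) # ramp with slope 3
})

test_that("mean-filter downsampling gives 2000 points from 8 s at 1 kHz", {
  s <- new_signal(stats::rnorm(8000), fs = 1000, unit = "volt")
  d <- mean_filter_downsample(s, 250)
  expect_equal(nrow(d), 2000)
  expect_equal(signal_fs(d), 250)
  # window means are exact
  expect_equal(d$value[1], mean(s$value[1:4]))
  expect_equal(d$value[2000], mean(s$value[7997:8000]))

  const <- new_signal(rep(1.7, 100), fs = 1000, unit = "du")
  expect_equal(unique(mean_filter_downsample(const, 250)$value), 1.7)

  alt <- new_signal(rep(c(1, -1), 50), fs = 1000, unit = "du")
  expect_equal(mean_filter_downsample(alt, 250)$value, rep(0, 25))

  expect_error(mean_filter_downsample(s, 300), "integer")
})

test_that("design score is the sum of fit and normalized peak voltage", {
  expect_equal(taguchi_score(0.98, 0.65), 1.63)
  expect_equal(taguchi_score(0.96, 0.85), 1.81)
  expect_equal(taguchi_score(0, 0), 0)
  expect_error(taguchi_score(1.2, 0.5), "0, 1")
  expect_error(taguchi_score(0.5, -0.1), "0, 1")
  # monotone in both arguments
  expect_gt(taguchi_score(0.9, 0.5), taguchi_score(0.8, 0.5))
  expect_gt(taguchi_score(0.9, 0.6), taguchi_score(0.9, 0.5))
})

test_that("noiseless cam verification is an exact round trip", {
  rep1 <- cam_verification(cfg = sensor_config(noise_sd = 0), repeats = 3)
  g <- glance(rep1)
  expect_lt(g$mean_nrmse[g$group == "overall"], 0.01)
  expect_gt(g$mean_r_squared[g$group == "overall"], 0.999)
})

test_that("cam verification with one repeat reports zero dispersion", {
  r <- cam_verification(repeats = 1, seed = 3)
  g <- glance(r)
  expect_equal(nrow(tidy(r)), 1)
  expect_equal(g$sd_nrmse, 0)
  expect_equal(g$sd_r_squared, 0)
})

test_that("eval report CSV mirrors the numbered-trials-plus-summary layout", {
  r <- cam_verification(repeats = 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eval_report_csv(r, path)
  tab <- utils::read.csv(path)
  expect_equal(tab$No., c("1", "2", "3", "4", "5", "Average", "S.D."))
  expect_equal(tab$NRMSE[6], mean(tab$NRMSE[1:5]), tolerance = 1e-9)
})
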