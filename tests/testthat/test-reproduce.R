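test_that("linear limit: identity-like chain replays the waveform almost exactly", {
  pl <- linear_plant(gain = 0.04, drive_gain = 25)
  pulses <- make_recorded_pulses(3, seed = 21)
  tr <- collect_training_data(pulses, 1, plant = pl, sensor = quiet_sensor())
  lin <- fit_linear(tr)
  held <- make_recorded_pulses(1, seed = 77)[[1]]
  rep <- reproduce_pulse(held, 1, lin, plant = pl, sensor = quiet_sensor())
  g <- glance(verify(list(rep$target), list(rep$replayed_ds)))
  expect_lt(g$mean_nrmse[g$group == "overall"], 0.02)
})

test_that("the drive is upsampled 250 -> 1000 Hz (4x the decomposition grid)", {
  pl <- linear_plant()
  pulses <- make_recorded_pulses(2, seed = 23)
  lin <- fit_linear(collect_training_data(pulses, 1,
    plant = pl, sensor = quiet_sensor()
  ))
  rep <- reproduce_pulse(pulses[[1]], 1, lin, plant = pl, sensor = quiet_sensor())
  expect_equal(nrow(rep$drive), 4 * nrow(rep$target))
  expect_equal(signal_fs(rep$drive), 1000)
  expect_equal(signal_fs(rep$replayed), 1000)
  # wrong input rate is rejected
  bad <- mean_filter_downsample(pulses[[1]], 500)
  expect_error(reproduce_pulse(bad, 1, lin, plant = pl), "1000 Hz")
})

test_that("perfect inverse on a linear plant recombines to the exact target", {
  # algebraic identity on the 250 Hz grid: no sensor, linear plant, exact
  # reciprocal-gain inverse; per-IMF drives recombined by their scales
  pl <- linear_plant(gain = 0.05, drive_gain = 1)
  w <- generate_pulse(pulse_params(force_level = "moderate", seed = 31), 8, 250)
  norm <- normalize_imfs(decompose(w))
  combined <- rep(0, 2000)
  for (i in seq_along(norm$imfs)) {
    combined <- combined + norm$scales[i] * (norm$imfs[[i]] / pl$linear_gain)
  }
  replay <- apply_drive(new_signal(combined, fs = 250, unit = "volt"), 1, pl)
  target <- recombine_imfs(norm)$value
  expect_lt(nrmse(target, replay$value), 1e-6)
})

test_that("verify reports per-pair metrics with exact averages", {
  s1 <- sin((1:100) / 5)
  s2 <- cos((1:100) / 7)
  r <- verify(list(s1, s2), list(s1, s2))
  expect_equal(tidy(r)$nrmse, c(0, 0))
  expect_equal(tidy(r)$r_squared, c(1, 1))

  noisy <- withr::with_seed(1, list(s1 + rnorm(100, 0, .05), s2 + rnorm(100, 0, .05)))
  r2 <- verify(list(s1, s2), noisy,
    force_levels = c("light", "heavy"), ids = c(1, 2)
  )
  g <- glance(r2)
  ov <- g[g$group == "overall", ]
  expect_equal(ov$mean_nrmse, mean(tidy(r2)$nrmse), tolerance = 1e-12)
  expect_equal(ov$mean_r_squared, mean(tidy(r2)$r_squared), tolerance = 1e-12)
  expect_setequal(g$group, c("light", "heavy", "overall"))

  # single pair: averages equal that pair
  r3 <- verify(list(s1), noisy[1])
  g3 <- glance(r3)
  expect_equal(g3$mean_nrmse, tidy(r3)$nrmse)

  expect_error(verify(list(s1), list(s1[-1])), "length mismatch")
  expect_error(verify(list(s1, s2), list(s1)), "same length")
})

test_that("model comparison flags obvious and null differences correctly", {
  mk_report <- function(nr, r2, lvl = NULL) {
    tr <- tibble::tibble(subject = seq_along(nr), nrmse = nr, r_squared = r2)
    if (!is.null(lvl)) tr$force_level <- lvl
    pulsereplay:::new_eval_report(tr)
  }
  a <- mk_report(c(.1, .11, .09, .1), c(.9, .91, .89, .9))
  cmp_same <- compare_models(a, a)
  expect_true(all(cmp_same$p_value > 0.99))
  expect_false(any(cmp_same$significant))

  jit <- withr::with_seed(2, rnorm(4, 0, 1e-4))
  b1 <- mk_report(0 + jit, rep(1, 4))
  b2 <- mk_report(1 + jit, rep(1, 4))
  cmp <- compare_models(b1, b2)
  expect_lt(cmp$p_value[cmp$metric == "nrmse" & cmp$group == "all"], 1e-6)

  short <- mk_report(c(.1), c(.9))
  expect_error(compare_models(short, short), "fewer than 2")
})

test_that("linear-model fidelity degrades monotonically with plant nonlinearity", {
  errs <- vapply(c(0.5, 3, 8), function(cc) {
    pl <- plant_config(cubic_coeff = cc)
    pulses <- make_recorded_pulses(3, seed = 41)
    lin <- fit_linear(collect_training_data(pulses, 1.2,
      plant = pl, sensor = quiet_sensor()
    ))
    held <- make_recorded_pulses(2, seed = 88)
    reps <- lapply(held, function(h) {
      reproduce_pulse(h, 1.2, lin, plant = pl, sensor = quiet_sensor())
    })
    r <- verify(lapply(reps, `[[`, "target"), lapply(reps, `[[`, "replayed_ds"))
    glance(r)$mean_nrmse[1]
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})
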