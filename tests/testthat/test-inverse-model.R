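test_that("the training protocol yields max_imfs x 2000 pairs per pulse", {
  pulses <- make_recorded_pulses(1, seed = 1)
  tr1 <- collect_training_data(pulses, 1.2,
    plant = linear_plant(), sensor = quiet_sensor(),
    sift_cfg = sift_config(max_imfs = 1)
  )
  expect_equal(nrow(tr1), 2000)
  expect_equal(unique(tr1$imf_index), 1L)

  tr7 <- collect_training_data(pulses, 1.2,
    plant = linear_plant(), sensor = quiet_sensor()
  )
  expect_equal(nrow(tr7), 7 * 2000)
  expect_equal(attr(tr7, "force_level"), "moderate")
})

test_that("with a noiseless linear chain p tracks u through the plant gain", {
  pulses <- make_recorded_pulses(2, seed = 3)
  pl <- linear_plant(gain = 0.04, drive_gain = 25) # effective gain 1
  tr <- collect_training_data(pulses, 1,
    plant = pl, sensor = quiet_sensor()
  )
  keep <- abs(tr$u) > 1 # away from the zero-padded and near-zero mass
  fit <- stats::lm.fit(cbind(1, tr$u[keep]), tr$p[keep])
  expect_equal(unname(fit$coefficients[2]), pl$linear_gain, tolerance = 0.02)
  expect_gt(r_squared(tr$p[keep], fit$fitted.values), 0.995)
})

test_that("the linear inverse recovers exact synthetic coefficients", {
  p <- seq(-1, 1, length.out = 500)
  train <- tibble::tibble(p = p, u = 2 * p + 1)
  m <- fit_linear(train)
  expect_equal(m$parameters$gain, 2, tolerance = 1e-9)
  expect_equal(m$parameters$offset, 1, tolerance = 1e-9)
  expect_equal(predict(m, c(0, 1)), c(1, 3), tolerance = 1e-9)
  expect_error(fit_linear(tibble::tibble(p = rep(1, 10), u = 1:10)), "constant")
})

test_that("the linear inverse recovers the reciprocal gain of a linear plant", {
  cfg <- plant_config(linear_gain = 0.05, cubic_coeff = 0, force_damping = 0)
  u <- seq(-30, 30, length.out = 1000)
  pvals <- apply_drive(new_signal(u, fs = 250, unit = "volt"), 1, cfg)$value
  m <- fit_linear(tibble::tibble(p = pvals, u = u))
  expect_equal(m$parameters$gain, 1 / 0.05, tolerance = 1e-6)
  expect_equal(m$parameters$offset, 0, tolerance = 1e-8)
})

test_that("data from a cubic plant defeats the linear inverse by a margin", {
  cfg <- plant_config(cubic_coeff = 3, force_damping = 0)
  u <- seq(-30, 30, length.out = 1000)
  pvals <- apply_drive(new_signal(u, fs = 250, unit = "volt"), 1, cfg)$value
  m <- fit_linear(tibble::tibble(p = pvals, u = u))
  expect_gt(m$fit$residual_sd, 0.5) # volts of irreducible linear error
})

test_that("the 1-10-1 network learns the identity map", {
  withr::with_seed(5, {
    p <- stats::runif(4000, -1, 1)
  })
  train <- tibble::tibble(p = p, u = p)
  m <- fit_ann(train, train_config(epochs = 60, seed = 2))
  held <- seq(-0.95, 0.95, length.out = 200)
  pred <- predict(m, held)
  expect_lt(sqrt(mean((pred - held)^2)) / diff(range(held)), 0.05)
})

test_that("ANN training is deterministic under a fixed seed", {
  withr::with_seed(6, {
    p <- stats::runif(1000, -1, 1)
  })
  train <- tibble::tibble(p = p, u = 2 * p + 0.2 * p^3)
  m1 <- fit_ann(train, train_config(epochs = 10, seed = 9))
  m2 <- fit_ann(train, train_config(epochs = 10, seed = 9))
  expect_identical(m1$parameters, m2$parameters)
  m3 <- fit_ann(train, train_config(epochs = 10, seed = 10))
  expect_false(identical(m1$parameters, m3$parameters))
})

test_that("closed loop: ANN drive replays a held-out IMF through its plant", {
  pulses <- make_recorded_pulses(3, seed = 11)
  pl <- plant_config() # default cubic plant
  tr <- collect_training_data(pulses, 1.2, plant = pl, sensor = quiet_sensor())
  ann <- fit_ann(tr, train_config(epochs = 80, subsample = 8000, seed = 1))
  # held-out pulse, first IMF as target
  held <- make_recorded_pulses(1, seed = 99)[[1]]
  w <- integrate_signal(mean_filter_downsample(held, 250), detrend = TRUE)
  norm <- normalize_imfs(decompose(w))
  target <- new_signal(norm$imfs[[1]], fs = 250, unit = "du")
  drive <- predict_drive(ann, target)
  played <- apply_drive(upsample_linear(drive, 1000), 1.2, pl)
  got <- mean_filter_downsample(
    integrate_signal(pvdf_record(played), detrend = TRUE), 250
  )
  expect_lt(
    nrmse(target$value - mean(target$value), got$value - mean(got$value)),
    0.1
  )
})

test_that("prediction is pointwise: it commutes with sample permutation", {
  withr::with_seed(12, {
    p <- stats::runif(500, -1, 1)
  })
  m <- fit_ann(tibble::tibble(p = p, u = 3 * p), train_config(epochs = 5, seed = 1))
  perm <- withr::with_seed(13, sample.int(500))
  expect_equal(predict(m, p[perm]), predict(m, p)[perm], tolerance = 1e-12)
  # a constant input gives a constant output
  pr <- predict(m, rep(0, 10))
  expect_equal(pr, rep(pr[1], 10), tolerance = 1e-12)
})

test_that("model JSON round trip preserves predictions", {
  withr::with_seed(14, {
    p <- stats::runif(500, -1, 1)
  })
  m <- fit_ann(tibble::tibble(p = p, u = 2 * p), train_config(epochs = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  save_inverse_model(m, path)
  m2 <- read_inverse_model(path)
  grid <- seq(-1, 1, length.out = 50)
  expect_equal(predict(m2, grid), predict(m, grid), tolerance = 1e-9)
  expect_equal(m2$kind, "ann")
})

test_that("tidy and glance expose coefficients and fit summaries", {
  train <- tibble::tibble(p = seq(-1, 1, length.out = 100),
                          u = 2 * seq(-1, 1, length.out = 100))
  lin <- fit_linear(train)
  td <- tidy(lin)
  expect_equal(td$term, c("offset", "gain"))
  ann <- fit_ann(train, train_config(epochs = 5, seed = 1))
  expect_equal(nrow(tidy(ann)), 31) # 10 + 10 + 10 weights + output bias
  expect_equal(glance(ann)$kind, "ann")
})
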