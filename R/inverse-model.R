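#' Training configuration for the pointwise neural inverse model
#'
#' The inverse model is a 1-10-1 multilayer perceptron trained by
#' back-propagation: logistic sigmoid hidden units, hyperbolic-tangent
#' sigmoid output, learning rate 0.8, 10^4 epochs (the published training
#' recipe). [fast_train_config()] is a reduced-cost recipe (150 epochs on a
#' 16,000-point subsample) for test runs; the map being learned is a smooth
#' scalar curve, so the reduced recipe reaches the same accuracy regime.
#'
#' @param epochs Training epochs (>= 1; default 1e4).
#' @param learning_rate Initial gradient-descent step size (> 0; default 0.8).
#' @param lr_decay Final-to-initial learning-rate ratio reached by
#'   exponential decay over the epochs (in (0, 1]; 1 = constant rate).
#'   Decaying the step lets stochastic gradient descent settle into the
#'   minimum instead of orbiting it.
#' @param hidden_neurons Hidden-layer width (default 10).
#' @param batch_size Mini-batch size (default 64).
#' @param subsample Train on at most this many randomly drawn pairs
#'   (`NULL` = all).
#' @param seed RNG seed for weight init, shuffling and subsampling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 1e4, learning_rate = 0.8, lr_decay = 0.01,
                         hidden_neurons = 10, batch_size = 64,
                         subsample = NULL, seed = 1) {
  stopifnot(
    epochs >= 1, learning_rate > 0, hidden_neurons >= 1, batch_size >= 1,
    lr_decay > 0, lr_decay <= 1
  )
  structure(
    list(
      epochs = as.integer(epochs), learning_rate = learning_rate,
      lr_decay = lr_decay,
      hidden_neurons = as.integer(hidden_neurons),
      batch_size = as.integer(batch_size),
      subsample = subsample, seed = seed
    ),
    class = "train_config"
  )
}

#' @rdname train_config
#' @export
fast_train_config <- function(epochs = 150, subsample = 16000, seed = 1) {
  train_config(epochs = epochs, subsample = subsample, seed = seed)
}

#' Collect inverse-model training pairs from the simulated player
#'
#' Mirrors the published data-collection protocol: each recorded pulse
#' signal is mean-filter downsampled to `target_fs`, integrated to the pulse
#' waveform, decomposed by EMD, and its normalized IMFs (zero-padded to
#' exactly `sift_cfg$max_imfs` components; the residue is the basic trend
#' and is excluded) are scaled by the amplifier `drive_gain` and played
#' through the plant at the given finger force. The re-recorded, integrated
#' vibration supplies the input `p` (player displacement) and the driving
#' voltage supplies the output `u` of each training pair.
#'
#' @param pulses List of recorded pulse signals (volts, 1 kHz, 8 s by
#'   default protocol).
#' @param force Finger force in newtons.
#' @param plant A [plant_config()].
#' @param sensor A [sensor_config()] used for the re-recording.
#' @param sift_cfg A [sift_config()].
#' @param target_fs Working rate after downsampling (default 250 Hz).
#' @return A tibble of class `training_set` with columns `set_index`,
#'   `imf_index`, `p`, `u` (10 pulses x 7 IMFs x 2000 points = 140,000 rows
#'   under the default protocol).
#' @export
collect_training_data <- function(pulses, force, plant = plant_config(),
                                  sensor = sensor_config(),
                                  sift_cfg = sift_config(),
                                  target_fs = 250) {
  stopifnot(is.list(pulses), length(pulses) >= 1)
  rows <- purrr::imap(pulses, function(pulse, set_i) {
    pulse <- as_signal(pulse)
    assert_unit(pulse, "volt")
    ds <- mean_filter_downsample(pulse, target_fs)
    w <- integrate_signal(ds, detrend = TRUE)
    bank <- imf_bank(normalize_imfs(decompose(w, sift_cfg)), sift_cfg$max_imfs)
    fs_play <- signal_fs(pulse)
    purrr::imap(bank$imfs, function(imf, i) {
      u <- plant$drive_gain * imf
      # play at the recorder rate, exactly as the reproduction pipeline does
      drive <- upsample_linear(
        new_signal(u, fs = target_fs, unit = "volt"), fs_play
      )
      resp <- apply_drive(drive, force, plant)
      sens_i <- sensor
      if (!is.null(sensor$seed)) sens_i$seed <- sensor$seed + 1000L * set_i + i
      rec <- pvdf_record(resp, sens_i)
      p <- mean_filter_downsample(
        integrate_signal(rec, detrend = TRUE), target_fs
      )$value
      # the integrated recording is linearly detrended (drift suppression),
      # so project the same span out of the drive to keep the pointwise
      # pairing consistent; for zero-mean oscillatory IMFs this changes the
      # drive negligibly
      tt <- seq_along(u)
      u_d <- u - stats::lm.fit(cbind(1, tt), u)$fitted.values
      tibble::tibble(set_index = set_i, imf_index = i, p = p, u = u_d)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "force") <- force
  attr(out, "force_level") <- force_level_of(force)
  attr(out, "drive_gain") <- plant$drive_gain
  class(out) <- c("training_set", class(out))
  out
}

new_inverse_model <- function(kind, force_level, parameters, scalers = NULL,
                              fit = list()) {
  structure(
    list(
      kind = kind, force_level = force_level, parameters = parameters,
      scalers = scalers, fit = fit
    ),
    class = "inverse_model"
  )
}

#' Fit the linear baseline inverse model
#'
#' Least-squares gain and offset from player displacement `p` to driving
#' voltage `u` — the linearity assumption the neural model is compared
#' against.
#'
#' @param train A `training_set` (any data frame with columns `p` and `u`).
#' @return An `inverse_model` of kind `"linear"`.
#' @export
fit_linear <- function(train) {
  stopifnot(all(c("p", "u") %in% names(train)))
  p <- train$p
  u <- train$u
  if (length(unique(p)) < 2L) {
    stop("degenerate training data: `p` is constant.", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(offset = 1, gain = p), u)
  model <- new_inverse_model(
    kind = "linear",
    force_level = attr(train, "force_level") %||% NA_character_,
    parameters = list(
      offset = unname(fit$coefficients[1]),
      gain = unname(fit$coefficients[2])
    ),
    fit = list(
      n_train = length(p),
      residual_sd = stats::sd(fit$residuals)
    )
  )
  model$fit$train_nrmse <- training_nrmse(model, train)
  model
}

sigmoid <- function(n) 1 / (1 + exp(-n))
tanh_sigmoid <- function(n) 2 / (1 + exp(-2 * n)) - 1

ann_forward <- function(x_scaled, par) {
  a1 <- sigmoid(outer(x_scaled, drop(par$w1)) +
    matrix(par$b1, length(x_scaled), length(par$b1), byrow = TRUE))
  drop(tanh_sigmoid(a1 %*% par$w2 + par$b2))
}

#' Fit the 1-10-1 neural inverse model
#'
#' Trains a one-input, one-output multilayer perceptron (10 sigmoid hidden
#' units, hyperbolic-tangent sigmoid output) by mini-batch gradient
#' back-propagation on affine-scaled data: inputs mapped to \[0.05, 0.95\],
#' outputs to \[-0.9, 0.9\] (margins keep the activations out of
#' saturation). Weights are initialized uniformly in +/-0.5. Training is
#' deterministic under the configured seed.
#'
#' @param train A `training_set` (any data frame with columns `p` and `u`).
#' @param cfg A [train_config()].
#' @return An `inverse_model` of kind `"ann"`, carrying the per-IMF training
#'   NRMSE table in `$fit$train_nrmse` when `train` has an `imf_index`
#'   column.
#' @export
fit_ann <- function(train, cfg = train_config()) {
  stopifnot(all(c("p", "u") %in% names(train)))
  p_all <- train$p
  u_all <- train$u
  if (length(p_all) < 2L || length(unique(p_all)) < 2L) {
    stop("degenerate training data: need >= 2 distinct `p` values.", call. = FALSE)
  }
  # scalers fitted on the training data only
  in_rng <- range(p_all)
  out_rng <- range(u_all)
  if (diff(out_rng) == 0) {
    stop("degenerate training data: `u` is constant.", call. = FALSE)
  }
  scalers <- list(
    in_a = 0.9 / diff(in_rng), in_b = 0.05 - 0.9 * in_rng[1] / diff(in_rng),
    out_a = 1.8 / diff(out_rng), out_b = -0.9 - 1.8 * out_rng[1] / diff(out_rng)
  )
  h <- cfg$hidden_neurons
  state <- withr::with_seed(cfg$seed, {
    keep <- seq_along(p_all)
    if (!is.null(cfg$subsample) && length(keep) > cfg$subsample) {
      keep <- sort(sample.int(length(p_all), cfg$subsample))
    }
    x <- scalers$in_a * p_all[keep] + scalers$in_b
    y <- scalers$out_a * u_all[keep] + scalers$out_b
    n <- length(x)
    w1 <- stats::runif(h, -0.5, 0.5)
    b1 <- stats::runif(h, -0.5, 0.5)
    w2 <- matrix(stats::runif(h, -0.5, 0.5), h, 1)
    b2 <- stats::runif(1, -0.5, 0.5)
    loss_trace <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate *
        cfg$lr_decay^((epoch - 1) / max(1, cfg$epochs - 1))
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      loss_sum <- 0
      for (s in starts) {
        ix <- ord[s:min(s + cfg$batch_size - 1L, n)]
        xb <- x[ix]
        yb <- y[ix]
        m <- length(ix)
        z1 <- outer(xb, w1) + matrix(b1, m, h, byrow = TRUE)
        a1 <- 1 / (1 + exp(-z1))
        yh <- drop(tanh(a1 %*% w2 + b2))
        err <- yh - yb
        loss_sum <- loss_sum + sum(err^2)
        d2 <- err * (1 - yh^2)
        gw2 <- crossprod(a1, d2) / m
        gb2 <- mean(d2)
        d1 <- (d2 %o% drop(w2)) * a1 * (1 - a1)
        gw1 <- colMeans(d1 * xb)
        gb1 <- colMeans(d1)
        w1 <- w1 - lr * gw1
        b1 <- b1 - lr * gb1
        w2 <- w2 - lr * gw2
        b2 <- b2 - lr * gb2
      }
      loss_trace[epoch] <- loss_sum / n
      if (!is.finite(loss_trace[epoch])) {
        stop(sprintf("ANN training diverged at epoch %d.", epoch), call. = FALSE)
      }
    }
    list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, loss_trace = loss_trace, n = n)
  })
  model <- new_inverse_model(
    kind = "ann",
    force_level = attr(train, "force_level") %||% NA_character_,
    parameters = list(
      w1 = state$w1, b1 = state$b1, w2 = drop(state$w2), b2 = state$b2
    ),
    scalers = scalers,
    fit = list(
      n_train = state$n, epochs = cfg$epochs,
      learning_rate = cfg$learning_rate,
      final_loss = state$loss_trace[length(state$loss_trace)],
      loss_trace = state$loss_trace
    )
  )
  model$fit$train_nrmse <- training_nrmse(model, train)
  model
}

#' Per-IMF training error of an inverse model
#'
#' NRMSE between predicted and true driving voltage, one row per
#' (set, IMF) series, as in the published training-error table; series with
#' zero voltage range (zero-padded IMF slots) are skipped.
#'
#' @param model An `inverse_model`.
#' @param train A data frame with columns `p`, `u` and optionally
#'   `imf_index`, `set_index`.
#' @return A tibble with columns `imf_index`, `nrmse` (averaged over sets),
#'   or a single overall row when no `imf_index` column is present.
#' @export
training_nrmse <- function(model, train) {
  pred <- predict(model, train$p)
  if (!"imf_index" %in% names(train)) {
    rng <- diff(range(train$u))
    if (rng == 0) return(tibble::tibble(imf_index = NA_integer_, nrmse = NA_real_))
    return(tibble::tibble(
      imf_index = NA_integer_,
      nrmse = sqrt(mean((train$u - pred)^2)) / rng
    ))
  }
  df <- tibble::tibble(
    imf_index = train$imf_index,
    set_index = train$set_index %||% 1L,
    u = train$u, pred = pred
  )
  per_series <- dplyr::summarise(
    dplyr::group_by(df, .data$imf_index, .data$set_index),
    rng = diff(range(.data$u)),
    rmse = sqrt(mean((.data$u - .data$pred)^2)),
    .groups = "drop"
  )
  per_series <- dplyr::filter(per_series, .data$rng > 0)
  dplyr::summarise(
    dplyr::group_by(per_series, .data$imf_index),
    nrmse = mean(.data$rmse / .data$rng),
    .groups = "drop"
  )
}

#' Predict driving voltage from a desired displacement
#'
#' Pointwise application of the inverse model (through its scalers for the
#' neural kind); sample order is immaterial because the map is memoryless.
#'
#' @param object An `inverse_model`.
#' @param newdata Numeric vector of displacement samples, or a
#'   `pulse_signal` in displacement units.
#' @param ... Unused.
#' @return Numeric vector of voltages (or a volt `pulse_signal` via
#'   [predict_drive()]).
#' @export
predict.inverse_model <- function(object, newdata, ...) {
  p <- if (is.data.frame(newdata)) newdata$value else as.numeric(newdata)
  if (!all(is.finite(p))) stop("`newdata` must be finite.", call. = FALSE)
  if (object$kind == "linear") {
    object$parameters$offset + object$parameters$gain * p
  } else {
    sc <- object$scalers
    x <- sc$in_a * p + sc$in_b
    y <- ann_forward(x, list(
      w1 = object$parameters$w1, b1 = object$parameters$b1,
      w2 = matrix(object$parameters$w2, ncol = 1), b2 = object$parameters$b2
    ))
    (y - sc$out_b) / sc$out_a
  }
}

#' @rdname predict.inverse_model
#' @param target A `pulse_signal` in displacement units.
#' @param v_limit Optional voltage clip applied to the prediction.
#' @export
predict_drive <- function(object, target, v_limit = NULL) {
  stopifnot(inherits(object, "inverse_model"))
  target <- as_signal(target)
  assert_unit(target, "du")
  u <- predict(object, target$value)
  if (!is.null(v_limit)) u <- pmin(pmax(u, -v_limit), v_limit)
  signal_like(target, u, unit = "volt")
}

#' @export
print.inverse_model <- function(x, ...) {
  cat(sprintf(
    "# inverse_model (%s), force level: %s, n_train = %s\n",
    x$kind, x$force_level, format(x$fit$n_train %||% NA)
  ))
  invisible(x)
}

#' Tidy an inverse model's parameters
#'
#' @param x An `inverse_model`.
#' @param ... Unused.
#' @return A tibble of terms and estimates (layer weights for the neural
#'   kind).
#' @export
tidy.inverse_model <- function(x, ...) {
  if (x$kind == "linear") {
    return(tibble::tibble(
      term = c("offset", "gain"),
      estimate = c(x$parameters$offset, x$parameters$gain)
    ))
  }
  h <- length(x$parameters$w1)
  tibble::tibble(
    term = c(
      sprintf("w1[%d]", seq_len(h)), sprintf("b1[%d]", seq_len(h)),
      sprintf("w2[%d]", seq_len(h)), "b2"
    ),
    estimate = c(x$parameters$w1, x$parameters$b1, x$parameters$w2,
                 x$parameters$b2)
  )
}

#' One-row summary of an inverse model fit
#'
#' @param x An `inverse_model`.
#' @param ... Unused.
#' @return A tibble with kind, force level, training size and mean training
#'   NRMSE.
#' @export
glance.inverse_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    force_level = x$force_level,
    n_train = x$fit$n_train %||% NA_integer_,
    epochs = x$fit$epochs %||% NA_integer_,
    final_loss = x$fit$final_loss %||% NA_real_,
    mean_train_nrmse = mean(x$fit$train_nrmse$nrmse, na.rm = TRUE)
  )
}

#' Save / load an inverse model as JSON
#'
#' @param model An `inverse_model`.
#' @param path File path.
#' @return `read_inverse_model()` returns the model; `save_inverse_model()`
#'   returns it invisibly.
#' @export
save_inverse_model <- function(model, path) {
  stopifnot(inherits(model, "inverse_model"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("saving models requires the `jsonlite` package.", call. = FALSE)
  }
  obj <- list(
    kind = model$kind, force_level = model$force_level,
    parameters = model$parameters, scalers = model$scalers,
    fit = model$fit[setdiff(names(model$fit), c("loss_trace", "train_nrmse"))]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname save_inverse_model
#' @export
read_inverse_model <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("reading models requires the `jsonlite` package.", call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_inverse_model(
    kind = obj$kind, force_level = obj$force_level,
    parameters = as.list(obj$parameters),
    scalers = if (!is.null(obj$scalers)) as.list(obj$scalers),
    fit = as.list(obj$fit)
  )
}
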