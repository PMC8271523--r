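#' PVDF recorder configuration
#'
#' The PVDF piezo film generates charge proportional to strain, so the voltage
#' seen by the acquisition stage is proportional to the *rate* of displacement;
#' the displacement itself is recovered by time integration of the recording.
#'
#' @param sensitivity Volts per unit displacement rate (du/s); > 0.
#' @param noise_sd Additive measurement noise, in volts; >= 0.
#' @param seed RNG seed for the noise, or `NULL`.
#' @return A list of class `sensor_config`.
#' @export
sensor_config <- function(sensitivity = 1, noise_sd = 0, seed = NULL) {
  stopifnot(is.numeric(sensitivity), sensitivity > 0, noise_sd >= 0)
  structure(
    list(sensitivity = sensitivity, noise_sd = noise_sd, seed = seed),
    class = "sensor_config"
  )
}

#' Record a displacement waveform through the simulated PVDF sensor
#'
#' Output is `sensitivity` times the discrete time-derivative (first
#' difference times `fs`, padded by repeating the first difference) plus
#' Gaussian noise; same length and rate as the input.
#'
#' @param displacement A `pulse_signal` in displacement units.
#' @param cfg A [sensor_config()].
#' @return A `pulse_signal` in volts.
#' @export
pvdf_record <- function(displacement, cfg = sensor_config()) {
  displacement <- as_signal(displacement)
  assert_unit(displacement, "du")
  fs <- signal_fs(displacement)
  d <- diff(displacement$value) * fs
  v <- cfg$sensitivity * c(d[1], d)
  if (cfg$noise_sd > 0) {
    add_noise <- function() v + stats::rnorm(length(v), 0, cfg$noise_sd)
    v <- if (is.null(cfg$seed)) add_noise() else withr::with_seed(cfg$seed, add_noise())
  }
  signal_like(displacement, v, unit = "volt")
}

#' Integrate a recorded voltage back to displacement
#'
#' Cumulative trapezoidal integration; the first sample is 0 (the DC level of
#' the displacement is unobservable to a rate sensor). With `detrend = TRUE`
#' a least-squares straight line is removed afterwards, which suppresses the
#' random-walk drift that integrating measurement noise produces.
#'
#' @param signal A `pulse_signal` in volts.
#' @param detrend Remove a fitted linear trend after integrating.
#' @return A `pulse_signal` in displacement units.
#' @export
integrate_signal <- function(signal, detrend = FALSE) {
  signal <- as_signal(signal)
  assert_unit(signal, "volt")
  v <- signal$value
  if (length(v) < 2L) stop("need at least 2 samples.", call. = FALSE)
  fs <- signal_fs(signal)
  y <- c(0, cumsum((v[-length(v)] + v[-1]) / 2)) / fs
  if (detrend) {
    t <- seq_along(y)
    fit <- stats::lm.fit(cbind(1, t), y)
    y <- y - fit$fitted.values
  }
  signal_like(signal, y, unit = "du")
}

#' Mean-filter downsampling
#'
#' Averages non-overlapping windows of `fs / target_fs` samples (windows
#' aligned to the first sample), simultaneously decimating and denoising;
#' 8 s at 1 kHz becomes exactly 2000 points at 250 Hz.
#'
#' @param signal A `pulse_signal`.
#' @param target_fs Target rate; `fs / target_fs` must be an integer.
#' @return A `pulse_signal` at `target_fs`.
#' @export
mean_filter_downsample <- function(signal, target_fs = 250) {
  signal <- as_signal(signal)
  fs <- signal_fs(signal)
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-8 || factor < 1) {
    stop("`fs / target_fs` must be a positive integer.", call. = FALSE)
  }
  factor <- round(factor)
  n_out <- floor(nrow(signal) / factor)
  if (n_out < 2L) stop("too few samples after decimation.", call. = FALSE)
  v <- signal$value[seq_len(n_out * factor)]
  means <- colMeans(matrix(v, nrow = factor))
  new_signal(means, fs = target_fs, unit = signal_unit(signal),
             t0 = signal$time_s[1])
}

#' Design score for recorder-structure screening
#'
#' A candidate recorder layout is scored as the sum of the goodness of fit
#' between its measured profile and the reference profile (R-squared) and its
#' normalized peak output voltage, both in \[0, 1\]: higher-sensitivity,
#' higher-fidelity designs score higher.
#'
#' @param r_squared Fit between measured and reference profile, in \[0, 1\].
#' @param norm_peak_volt Peak output voltage normalized across designs, in
#'   \[0, 1\].
#' @return The score (numeric scalar).
#' @examples
#' taguchi_score(0.98, 0.65) # 1.63
#' @export
taguchi_score <- function(r_squared, norm_peak_volt) {
  stopifnot(is.numeric(r_squared), is.numeric(norm_peak_volt))
  if (any(r_squared < 0 | r_squared > 1)) {
    stop("`r_squared` must lie in [0, 1].", call. = FALSE)
  }
  if (any(norm_peak_volt < 0 | norm_peak_volt > 1)) {
    stop("`norm_peak_volt` must lie in [0, 1].", call. = FALSE)
  }
  r_squared + norm_peak_volt
}

#' One-period cam profile fixture
#'
#' A synthetic stand-in for the verification cam: one noiseless pulse beat
#' (percussion, tidal and dicrotic features) spanning exactly one second,
#' i.e. a cam turning at 60 rpm.
#'
#' @param fs Sampling rate in Hz.
#' @return A `pulse_signal` in displacement units, `fs` samples long.
#' @export
cam_profile <- function(fs = 1000) {
  p <- pulse_params(heart_rate = 1, beat_jitter = 0, noise_sd = 0, seed = NULL)
  generate_pulse(p, duration = 1, fs = fs)
}

#' Cam-verification protocol for the simulated recorder
#'
#' Repeatedly records the rotating cam profile through the PVDF model,
#' integrates the recording back to displacement, and compares it with the
#' cam profile using NRMSE and R-squared. With `cfg = NULL` the sensor noise
#' defaults to 2% of the peak (absolute) voltage of a noiseless recording of
#' the profile.
#'
#' @param cam A `pulse_signal` displacement profile (one period at 1 Hz).
#' @param cfg A [sensor_config()], or `NULL` for the 2%-of-peak default.
#' @param repeats Number of repeated recordings (>= 1).
#' @param seed Base seed; repeat `i` uses `seed + i`.
#' @return An `eval_report` (see [verify()]) with one row per repeat.
#' @export
cam_verification <- function(cam = cam_profile(), cfg = NULL, repeats = 10,
                             seed = 0) {
  stopifnot(repeats >= 1)
  cam <- as_signal(cam)
  assert_unit(cam, "du")
  if (is.null(cfg)) {
    peak <- max(abs(pvdf_record(cam, sensor_config())$value))
    cfg <- sensor_config(noise_sd = 0.02 * peak)
  }
  rows <- purrr::map_dfr(seq_len(repeats), function(i) {
    cfg_i <- sensor_config(cfg$sensitivity, cfg$noise_sd, seed = seed + i)
    rec <- pvdf_record(cam, cfg_i)
    est <- integrate_signal(rec)
    # the integration constant is unobservable; align means before comparing
    ref <- cam$value - mean(cam$value)
    got <- est$value / cfg$sensitivity
    got <- got - mean(got)
    tibble::tibble(
      trial = i,
      nrmse = nrmse(ref, got),
      r_squared = r_squared(ref, got)
    )
  })
  new_eval_report(rows)
}
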