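#' Simulated piezoelectric-bender player (the plant)
#'
#' A configurable voltage-to-displacement map standing in for the physical
#' five-bender stack. The memoryless core is
#' `y = linear_gain * (v + cubic_coeff * v^3 / v_limit^2) * (1 - force_damping * force)`
#' after clipping `v` to the +/-`v_limit` drive rails; a positive
#' `cubic_coeff` bends the response away from linearity near the rails, and
#' finger force attenuates the output (finger pressure suppresses bender
#' vibration). An optional play-operator hysteresis adds input-history
#' dependence; it is off by default because the pointwise inverse models can
#' only invert a memoryless map.
#'
#' Default scales follow the published hardware envelope: +/-48 V drive
#' rails and an amplifier stage (`drive_gain`, about 80 Vpp from 3.3 Vpp,
#' i.e. 24) that brings unit-amplitude normalized driving signals up to
#' bender voltage. The default `linear_gain` of 0.04 du/V makes the bender
#' stroke at amplified unit drive (~24 V) span about one displacement unit —
#' the amplitude scale of the synthetic pulses — with headroom to the rails.
#'
#' @param linear_gain Displacement units per volt (> 0).
#' @param cubic_coeff Dimensionless cubic nonlinearity strength.
#' @param hysteresis_strength Play-operator half-width as a fraction of
#'   `v_limit`; 0 = memoryless.
#' @param force_damping Gain attenuation per newton; must satisfy
#'   `force_damping * force < 1` for all supported forces.
#' @param v_limit Drive voltage rails in volts (default 48).
#' @param drive_gain Amplifier gain applied by the driving protocol to
#'   normalized (unit-amplitude) driving signals (default 24).
#' @param output_noise_sd Additive displacement noise, du (default 0).
#' @param seed RNG seed for output noise.
#' @return A list of class `plant_config`.
#' @export
plant_config <- function(linear_gain = 0.04, cubic_coeff = 3,
                         hysteresis_strength = 0, force_damping = 0.05,
                         v_limit = 48, drive_gain = 24,
                         output_noise_sd = 0, seed = NULL) {
  stopifnot(
    linear_gain > 0, v_limit > 0, drive_gain > 0,
    hysteresis_strength >= 0, force_damping >= 0, output_noise_sd >= 0
  )
  structure(
    list(
      linear_gain = linear_gain, cubic_coeff = cubic_coeff,
      hysteresis_strength = hysteresis_strength,
      force_damping = force_damping, v_limit = v_limit,
      drive_gain = drive_gain,
      output_noise_sd = output_noise_sd, seed = seed
    ),
    class = "plant_config"
  )
}

#' Drive the simulated player
#'
#' @param voltage A `pulse_signal` in volts (bender voltage; clipped to
#'   +/-`v_limit`).
#' @param force Finger force in newtons (> 0).
#' @param cfg A [plant_config()].
#' @return A `pulse_signal` in displacement units, same rate and length.
#' @export
apply_drive <- function(voltage, force, cfg = plant_config()) {
  voltage <- as_signal(voltage)
  assert_unit(voltage, "volt")
  if (!is.numeric(force) || length(force) != 1L || force <= 0) {
    stop("`force` must be a single positive number of newtons.", call. = FALSE)
  }
  damp <- 1 - cfg$force_damping * force
  if (damp <= 0) {
    stop("`force_damping * force` must be < 1.", call. = FALSE)
  }
  v <- pmin(pmax(voltage$value, -cfg$v_limit), cfg$v_limit)
  if (cfg$hysteresis_strength > 0) {
    v <- play_operator(v, cfg$hysteresis_strength * cfg$v_limit)
  }
  y <- cfg$linear_gain * (v + cfg$cubic_coeff * v^3 / cfg$v_limit^2) * damp
  if (cfg$output_noise_sd > 0) {
    add_noise <- function() y + stats::rnorm(length(y), 0, cfg$output_noise_sd)
    y <- if (is.null(cfg$seed)) add_noise() else withr::with_seed(cfg$seed, add_noise())
  }
  signal_like(voltage, y, unit = "du")
}

# play (backlash) operator with half-width r: the state follows the input
# only once the input has moved by more than r since the last reversal
play_operator <- function(v, r) {
  z <- numeric(length(v))
  z[1] <- v[1]
  for (k in 2:length(v)) {
    z[k] <- min(max(z[k - 1], v[k] - r), v[k] + r)
  }
  z
}

#' Drive the player and re-record its vibration
#'
#' Chains [apply_drive()] and [pvdf_record()]: the recorder sits on the
#' player's silicon skin, so the played displacement is observed through the
#' same rate-sensing path as a real wrist pulse.
#'
#' @inheritParams apply_drive
#' @param sensor A [sensor_config()].
#' @return A list with elements `displacement` (du) and `recorded` (volt).
#' @export
record_playback <- function(voltage, force, cfg = plant_config(),
                            sensor = sensor_config()) {
  disp <- apply_drive(voltage, force, cfg)
  rec <- pvdf_record(disp, sensor)
  list(displacement = disp, recorded = rec)
}
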