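#' Palpation-force regimes
#'
#' Pulse palpation distinguishes light (< 0.9 N), moderate (0.9-1.5 N) and
#' heavy (> 1.5 N) pressing forces; the three intervals partition (0, Inf).
#' Each regime carries a representative force (its interval midpoint, with
#' 1.8 N standing in for the open heavy interval) used when driving the
#' simulated player.
#'
#' @return A tibble with columns `force_level`, `lower_n`, `upper_n`,
#'   `force_n` (representative force in newtons).
#' @examples
#' force_ranges()
#' @export
force_ranges <- function() {
  tibble::tibble(
    force_level = c("light", "moderate", "heavy"),
    lower_n = c(0, 0.9, 1.5),
    upper_n = c(0.9, 1.5, Inf),
    force_n = c(0.6, 1.2, 1.8)
  )
}

#' Map a force in newtons to its palpation regime
#'
#' @param force Force in newtons (> 0).
#' @return `"light"`, `"moderate"` or `"heavy"`.
#' @export
force_level_of <- function(force) {
  stopifnot(is.numeric(force), all(force > 0))
  ifelse(force < 0.9, "light", ifelse(force <= 1.5, "moderate", "heavy"))
}

#' Parameters of the synthetic pulse generator
#'
#' One heartbeat is modelled as three Gaussian bumps above a baseline: the
#' percussion wave (early systolic peak, the largest), the tidal wave (late
#' systolic shoulder) and the dicrotic bump (rebound after the dicrotic
#' notch). Timing offsets are fractions of the beat period. Beat-to-beat
#' variability perturbs the period only; measurement-like noise is additive
#' white Gaussian on the displacement, with standard deviation expressed
#' relative to the percussion amplitude.
#'
#' The three force presets encode the well-known pattern that lightly-pressed
#' pulses are fainter and noisier: `light` scales amplitudes by 0.4 with 5%
#' relative noise, `moderate` uses scale 1 with 2% noise, `heavy` scale 1.3
#' with 1% noise.
#'
#' @param heart_rate Beats per second, in \[0.6, 2\].
#' @param percussion_amp,tidal_amp,dicrotic_amp Relative displacement
#'   amplitudes; percussion must be the largest, all positive.
#' @param percussion_t,tidal_t,dicrotic_t Within-beat timing offsets as
#'   fractions of the beat period, strictly increasing in \[0, 1).
#' @param percussion_w,tidal_w,dicrotic_w Bump widths (Gaussian sd) as
#'   fractions of the beat period.
#' @param baseline Constant displacement offset the features ride on.
#' @param beat_jitter Coefficient of variation of the beat period.
#' @param noise_sd Additive noise sd relative to `percussion_amp`.
#' @param force_level One of `"light"`, `"moderate"`, `"heavy"`, or `NULL`
#'   to keep the amplitudes/noise exactly as given.
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @return A list of class `pulse_params`.
#' @examples
#' p <- pulse_params(heart_rate = 1, force_level = "moderate", seed = 1)
#' s <- generate_pulse(p, duration = 8, fs = 1000)
#' nrow(s)
#' @export
pulse_params <- function(heart_rate = 1.2,
                         percussion_amp = 1, tidal_amp = 0.5, dicrotic_amp = 0.25,
                         percussion_t = 0.15, tidal_t = 0.35, dicrotic_t = 0.55,
                         percussion_w = 0.045, tidal_w = 0.075, dicrotic_w = 0.06,
                         baseline = 0.05,
                         beat_jitter = 0.02, noise_sd = 0.02,
                         force_level = NULL, seed = NULL) {
  if (!is.null(force_level)) {
    force_level <- match.arg(force_level, c("light", "moderate", "heavy"))
    preset <- switch(force_level,
      light = list(scale = 0.4, noise = 0.05),
      moderate = list(scale = 1.0, noise = 0.02),
      heavy = list(scale = 1.3, noise = 0.01)
    )
    percussion_amp <- percussion_amp * preset$scale
    tidal_amp <- tidal_amp * preset$scale
    dicrotic_amp <- dicrotic_amp * preset$scale
    baseline <- baseline * preset$scale
    noise_sd <- preset$noise
  }
  p <- list(
    heart_rate = heart_rate,
    percussion_amp = percussion_amp, tidal_amp = tidal_amp,
    dicrotic_amp = dicrotic_amp,
    percussion_t = percussion_t, tidal_t = tidal_t, dicrotic_t = dicrotic_t,
    percussion_w = percussion_w, tidal_w = tidal_w, dicrotic_w = dicrotic_w,
    baseline = baseline,
    beat_jitter = beat_jitter, noise_sd = noise_sd,
    force_level = force_level, seed = seed
  )
  validate_pulse_params(p)
  structure(p, class = "pulse_params")
}

validate_pulse_params <- function(p) {
  if (p$heart_rate < 0.6 || p$heart_rate > 2.0) {
    stop("`heart_rate` must lie in [0.6, 2] Hz.", call. = FALSE)
  }
  if (!(p$percussion_amp > p$tidal_amp && p$tidal_amp > p$dicrotic_amp &&
    p$dicrotic_amp > 0)) {
    stop("amplitudes must satisfy percussion > tidal > dicrotic > 0.",
      call. = FALSE
    )
  }
  if (!(p$percussion_t >= 0 && p$percussion_t < p$tidal_t &&
    p$tidal_t < p$dicrotic_t && p$dicrotic_t < 1)) {
    stop("timing offsets must satisfy 0 <= percussion_t < tidal_t < dicrotic_t < 1.",
      call. = FALSE
    )
  }
  if (p$noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  if (p$beat_jitter < 0) stop("`beat_jitter` must be >= 0.", call. = FALSE)
  invisible(p)
}

# one beat evaluated at phase u in [0, 1) (fraction of the beat period)
beat_template <- function(u, p) {
  bump <- function(amp, t0, w) amp * exp(-0.5 * ((u - t0) / w)^2)
  p$baseline +
    bump(p$percussion_amp, p$percussion_t, p$percussion_w) +
    bump(p$tidal_amp, p$tidal_t, p$tidal_w) +
    bump(p$dicrotic_amp, p$dicrotic_t, p$dicrotic_w)
}

#' Generate a synthetic pulse displacement waveform
#'
#' Produces `duration * fs` samples of a beat train whose every beat contains
#' the three canonical features above a baseline. With `noise_sd = 0` and no
#' jitter the waveform is strictly periodic at `heart_rate`.
#'
#' @param params A [pulse_params()] object.
#' @param duration Length in seconds (> 0).
#' @param fs Sampling rate in Hz (must exceed twice the heart rate).
#' @return A `pulse_signal` in displacement units.
#' @export
generate_pulse <- function(params, duration = 8, fs = 1000) {
  stopifnot(inherits(params, "pulse_params"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive.", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) {
    stop("`fs` must be positive.", call. = FALSE)
  }
  if (fs < 2 * params$heart_rate) {
    stop("`fs` must be at least twice the heart rate (Nyquist).", call. = FALSE)
  }
  gen <- function() {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1L) / fs
    period0 <- 1 / params$heart_rate
    # enough beats to cover the window even with jittered periods
    n_beats <- ceiling(duration / period0) + 3L
    jitter <- if (params$beat_jitter > 0) {
      stats::rnorm(n_beats, 0, params$beat_jitter)
    } else {
      rep(0, n_beats)
    }
    periods <- pmax(period0 * (1 + jitter), 0.25 * period0)
    onsets <- c(0, cumsum(periods))[seq_len(n_beats)]
    v <- rep(0, n)
    for (k in seq_len(n_beats)) {
      u <- (t - onsets[k]) / periods[k]
      in_beat <- u >= 0 & u < 1
      if (!any(in_beat)) next
      v[in_beat] <- v[in_beat] + beat_template(u[in_beat], params) -
        params$baseline
    }
    v <- v + params$baseline
    if (params$noise_sd > 0) {
      v <- v + stats::rnorm(n, 0, params$noise_sd * params$percussion_amp)
    }
    new_signal(v, fs = fs, unit = "du")
  }
  if (is.null(params$seed)) gen() else withr::with_seed(params$seed, gen())
}
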