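#' Uniformly sampled signal tibbles
#'
#' All waveforms in pulsereplay travel as tibbles with two columns, `time_s`
#' and `value`, carrying a sampling rate (`fs`, Hz) and a unit tag as
#' attributes. Two units are used: `"volt"` for sensor/driving voltages and
#' `"du"` for displacement in arbitrary displacement units (the physical
#' amplitude of real wrist pulses is never known in absolute terms, so all
#' displacement is relative by design).
#'
#' @param value Numeric vector of samples (finite, length >= 2).
#' @param fs Sampling rate in Hz (> 0).
#' @param unit `"volt"` or `"du"`.
#' @param t0 Time of the first sample in seconds.
#' @return A tibble of class `pulse_signal` with columns `time_s` and `value`.
#' @examples
#' s <- new_signal(sin(2 * pi * 2 * seq(0, 1, by = 1 / 250)), fs = 250, unit = "du")
#' signal_fs(s)
#' @export
new_signal <- function(value, fs, unit = c("du", "volt"), t0 = 0) {
  unit <- match.arg(unit)
  value <- as.numeric(value)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number.", call. = FALSE)
  }
  if (length(value) < 2L) {
    stop("a signal needs at least 2 samples.", call. = FALSE)
  }
  if (!all(is.finite(value))) {
    stop("all samples must be finite.", call. = FALSE)
  }
  out <- tibble::tibble(
    time_s = t0 + (seq_along(value) - 1L) / fs,
    value = value
  )
  attr(out, "fs") <- fs
  attr(out, "unit") <- unit
  class(out) <- c("pulse_signal", class(out))
  out
}

#' Coerce a data frame to a pulse signal
#'
#' Accepts any data frame with a `value` column (and optionally `time_s`);
#' the sampling rate is taken from `fs` or inferred from the median spacing
#' of `time_s`.
#'
#' @param x A data frame with columns `time_s` and/or `value`.
#' @param fs Sampling rate in Hz; inferred from `time_s` when `NULL`.
#' @param unit Unit tag; defaults to the `unit` attribute of `x` or `"du"`.
#' @return A `pulse_signal` tibble.
#' @export
as_signal <- function(x, fs = NULL, unit = NULL) {
  if (inherits(x, "pulse_signal") && is.null(fs) && is.null(unit)) {
    return(x)
  }
  stopifnot(is.data.frame(x), "value" %in% names(x))
  if (is.null(fs)) {
    fs <- attr(x, "fs")
  }
  if (is.null(fs)) {
    if (!"time_s" %in% names(x)) {
      stop("need `fs` or a `time_s` column to infer the sampling rate.",
        call. = FALSE
      )
    }
    fs <- 1 / stats::median(diff(x$time_s))
  }
  if (is.null(unit)) unit <- attr(x, "unit") %||% "du"
  t0 <- if ("time_s" %in% names(x)) x$time_s[1] else 0
  new_signal(x$value, fs = fs, unit = unit, t0 = t0)
}

#' @rdname new_signal
#' @param x A `pulse_signal` (or data frame with a `time_s` column).
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) fs <- 1 / stats::median(diff(x$time_s))
  fs
}

#' @rdname new_signal
#' @export
signal_unit <- function(x) {
  attr(x, "unit") %||% "du"
}

# internal: rebuild a signal with new samples, keeping grid metadata
signal_like <- function(template, value, unit = signal_unit(template),
                        fs = signal_fs(template)) {
  new_signal(value, fs = fs, unit = unit, t0 = template$time_s[1])
}

assert_unit <- function(x, unit) {
  if (!identical(signal_unit(x), unit)) {
    stop(sprintf(
      "expected a signal in unit '%s', got '%s'.", unit, signal_unit(x)
    ), call. = FALSE)
  }
  invisible(x)
}

#' Read / write the two-column signal CSV format
#'
#' The on-disk interchange format is a plain CSV with header `time_s,value`.
#'
#' @param path File path.
#' @param unit Unit tag to attach on read.
#' @return `read_signal_csv()` returns a `pulse_signal`;
#'   `write_signal_csv()` returns `x` invisibly.
#' @export
read_signal_csv <- function(path, unit = c("du", "volt")) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("signal CSV must have columns `time_s` and `value`.", call. = FALSE)
  }
  as_signal(df, unit = unit)
}

#' @rdname read_signal_csv
#' @param x A `pulse_signal`.
#' @export
write_signal_csv <- function(x, path) {
  utils::write.csv(x[, c("time_s", "value")], path, row.names = FALSE)
  invisible(x)
}

#' Linear-interpolation resampling to a higher rate
#'
#' Used by the reproduction pipeline to bring 250 Hz driving signals back to
#' the 1 kHz playback rate.
#'
#' @param x A `pulse_signal`.
#' @param target_fs Target sampling rate in Hz (must be an integer multiple
#'   of the current rate).
#' @return A `pulse_signal` at `target_fs` with `factor * n` samples.
#' @export
upsample_linear <- function(x, target_fs) {
  x <- as_signal(x)
  fs <- signal_fs(x)
  factor <- target_fs / fs
  if (abs(factor - round(factor)) > 1e-8 || factor < 1) {
    stop("`target_fs` must be an integer multiple of the current rate.",
      call. = FALSE
    )
  }
  factor <- round(factor)
  n <- nrow(x)
  t_new <- x$time_s[1] + (seq_len(n * factor) - 1L) / target_fs
  v <- stats::approx(x$time_s, x$value, xout = t_new, rule = 2)$y
  new_signal(v, fs = target_fs, unit = signal_unit(x), t0 = x$time_s[1])
}

#' @export
print.pulse_signal <- function(x, ...) {
  cat(sprintf(
    "# pulse_signal: %d samples @ %g Hz [%s]\n",
    nrow(x), signal_fs(x), signal_unit(x)
  ))
  NextMethod()
}

#' Plot a signal
#'
#' @param object A `pulse_signal`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pulse_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)",
      y = if (signal_unit(object) == "volt") "voltage (V)" else "displacement (du)"
    ) +
    ggplot2::theme_minimal()
}
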