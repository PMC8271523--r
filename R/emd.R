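#' Sifting configuration for empirical mode decomposition
#'
#' Sifting subtracts the mean of the cubic-spline upper and lower extrema
#' envelopes until a Cauchy-type criterion is met: the normalized squared
#' change between consecutive sift iterates,
#' `SD_k = sum((h_[k-1] - h_k)^2) / sum(h_[k-1]^2)`, drops below
#' `sd_threshold` (0.1 by default).
#'
#' @param sd_threshold Cauchy-type stop threshold (> 0, default 0.1).
#' @param max_sift_iters Cap on sift iterations per IMF (>= 1).
#' @param max_imfs Cap on the number of IMFs extracted (default 7: an
#'   eight-second pulse waveform decomposes into at most seven IMFs).
#' @param boundary_mode Envelope end-condition; only `"mirror"` (reflect the
#'   two extrema nearest each end about the endpoints) is implemented.
#' @return A list of class `sift_config`.
#' @export
sift_config <- function(sd_threshold = 0.1, max_sift_iters = 50,
                        max_imfs = 7, boundary_mode = "mirror") {
  stopifnot(sd_threshold > 0, max_sift_iters >= 1, max_imfs >= 1)
  boundary_mode <- match.arg(boundary_mode)
  structure(
    list(
      sd_threshold = sd_threshold, max_sift_iters = max_sift_iters,
      max_imfs = max_imfs, boundary_mode = boundary_mode
    ),
    class = "sift_config"
  )
}

#' Locate strict local extrema
#'
#' Extrema are sign changes of the first difference; a flat plateau at a
#' turning point is assigned its midpoint sample, so detection is
#' deterministic on any input.
#'
#' @param x Numeric vector.
#' @return A list with integer vectors `maxima` and `minima` (indices into
#'   `x`).
#' @export
find_extrema <- function(x) {
  d <- sign(diff(x))
  idx <- which(d != 0)
  if (length(idx) < 2L) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  s <- d[idx]
  chg <- which(s[-length(s)] != s[-1])
  if (length(chg) == 0L) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  # plateau between the last step of one run and the first step of the next
  pos <- as.integer(floor((idx[chg] + 1 + idx[chg + 1]) / 2))
  list(maxima = pos[s[chg] == 1], minima = pos[s[chg] == -1])
}

count_zero_crossings <- function(x) {
  z <- sign(x)
  z <- z[z != 0]
  if (length(z) < 2L) return(0L)
  sum(z[-1] != z[-length(z)])
}

# natural cubic spline through extrema, with the two extrema nearest each
# end mirrored about the endpoints to tame boundary swings
spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  take_l <- seq_len(min(2L, k))
  take_r <- seq(max(1L, k - 1L), k)
  knots <- c(2L - rev(idx[take_l]), idx, 2L * n - rev(idx[take_r]))
  vals <- c(rev(val[take_l]), val, rev(val[take_r]))
  keep <- !duplicated(knots)
  knots <- knots[keep]
  vals <- vals[keep]
  stats::splinefun(knots, vals, method = "natural")(seq_len(n))
}

#' Mean of the upper and lower extrema envelopes
#'
#' Cubic splines interpolate the local maxima (upper envelope) and local
#' minima (lower envelope); the pointwise mean of the two is the quantity
#' subtracted at each sift iteration. When the signal has fewer than 2
#' maxima or fewer than 2 minima no envelope exists and `NULL` is returned
#' (the sifter reads this as termination, not an error).
#'
#' @param x Numeric vector or `pulse_signal`.
#' @return Numeric vector of the envelope mean, or `NULL`.
#' @export
envelope_mean <- function(x) {
  if (is.data.frame(x)) x <- x$value
  ext <- find_extrema(x)
  if (length(ext$maxima) < 2L || length(ext$minima) < 2L) {
    return(NULL)
  }
  n <- length(x)
  up <- spline_envelope(ext$maxima, x[ext$maxima], n)
  lo <- spline_envelope(ext$minima, x[ext$minima], n)
  (up + lo) / 2
}

#' Extract one intrinsic mode function by sifting
#'
#' Iterates `h <- h - envelope_mean(h)` until the Cauchy-type SD criterion
#' falls below `cfg$sd_threshold` or `cfg$max_sift_iters` is reached. The
#' result satisfies the two IMF conditions: extrema and zero-crossing counts
#' differ by at most one, and the local envelope mean is near zero.
#'
#' @param x Numeric vector or `pulse_signal` admitting at least one envelope.
#' @param cfg A [sift_config()].
#' @return Numeric vector (one IMF) with attributes `n_iter` and `sd_trace`,
#'   or `NULL` when no envelope exists at the first iteration.
#' @export
sift <- function(x, cfg = sift_config()) {
  if (is.data.frame(x)) x <- x$value
  h <- x
  n_iter <- 0L
  sd_trace <- numeric(0)
  sd_k <- Inf
  repeat {
    m <- envelope_mean(h)
    if (is.null(m)) {
      if (n_iter == 0L) return(NULL)
      break
    }
    # stop once the Cauchy criterion has been met *and* the candidate
    # already satisfies both IMF conditions (extrema/zero-crossing count,
    # near-zero envelope mean away from the boundaries)
    if (n_iter >= 1L && sd_k < cfg$sd_threshold && is_imf_like(h, m)) break
    if (n_iter >= cfg$max_sift_iters) break
    denom <- sum(h^2)
    if (denom == 0) break
    h <- h - m
    n_iter <- n_iter + 1L
    sd_k <- sum(m^2) / denom
    sd_trace <- c(sd_trace, sd_k)
  }
  attr(h, "n_iter") <- n_iter
  attr(h, "sd_trace") <- sd_trace
  h
}

# both IMF conditions, with the envelope mean judged away from the end 5%
# of samples (spline end effects) against a 5%-of-amplitude tolerance
is_imf_like <- function(h, m) {
  ext <- find_extrema(h)
  n_ext <- length(ext$maxima) + length(ext$minima)
  if (abs(n_ext - count_zero_crossings(h)) > 1L) {
    return(FALSE)
  }
  n <- length(h)
  core <- seq(from = max(1L, ceiling(0.05 * n)), to = floor(0.95 * n))
  amp <- max(abs(h))
  amp > 0 && max(abs(m[core])) <= 0.05 * amp
}

#' Empirical mode decomposition
#'
#' Repeatedly sifts the running residue, extracting IMFs in order of
#' decreasing characteristic frequency, until the residue has fewer than two
#' maxima or two minima (the monotonic-trend stop) or `max_imfs` is reached.
#' The element-wise sum of all IMFs plus the residue reconstructs the input
#' exactly (telescoping identity). Each IMF's energy (sum of squares),
#' normalized to sum 1 over the IMFs, is stored as its weight.
#'
#' @param signal A `pulse_signal` (or data frame with a `value` column) of
#'   length >= 16.
#' @param cfg A [sift_config()].
#' @return An object of class `imf_set`: a list with `imfs` (list of numeric
#'   vectors), `residue`, `weights` (energy weights, sum 1), `scales`
#'   (per-IMF amplitude scales; 1 until [normalize_imfs()] is applied),
#'   `fs`, `n_iter` per IMF.
#' @export
decompose <- function(signal, cfg = sift_config()) {
  signal <- as_signal(signal)
  x <- signal$value
  if (length(x) < 16L) {
    stop("signal too short to decompose (need >= 16 samples).", call. = FALSE)
  }
  r <- x
  imfs <- list()
  n_iter <- integer(0)
  while (length(imfs) < cfg$max_imfs) {
    ext <- find_extrema(r)
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L) break
    imf <- sift(r, cfg)
    if (is.null(imf)) break
    n_iter <- c(n_iter, attr(imf, "n_iter"))
    attributes(imf) <- NULL
    imfs <- c(imfs, list(imf))
    r <- r - imf
  }
  energies <- vapply(imfs, function(v) sum(v^2), numeric(1))
  weights <- if (length(energies) && sum(energies) > 0) {
    energies / sum(energies)
  } else {
    rep(0, length(energies))
  }
  structure(
    list(
      imfs = imfs, residue = r, weights = weights,
      scales = rep(1, length(imfs)), normalized = FALSE,
      fs = signal_fs(signal), t0 = signal$time_s[1], n_iter = n_iter
    ),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf(
    "# imf_set: %d IMF(s) + residue, %d samples @ %g Hz%s\n",
    length(x$imfs), length(x$residue), x$fs,
    if (x$normalized) " (normalized)" else ""
  ))
  if (length(x$weights)) {
    cat("  energy weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of IMFs in a decomposition
#' @param x An `imf_set`.
#' @export
n_imfs <- function(x) length(x$imfs)

#' Normalize IMFs to unit maximum absolute value
#'
#' Each IMF is divided by its peak absolute value so it can serve directly
#' as a driving signal; the removed amplitude is retained in `scales` so the
#' weighted recombination `sum(scales[i] * imfs[[i]])` restores the original
#' IMF sum exactly. An all-zero IMF is left unchanged with scale 0.
#'
#' @param imfset An `imf_set` from [decompose()].
#' @return The `imf_set` with unit-max-abs IMFs and populated `scales`.
#' @export
normalize_imfs <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  if (length(imfset$imfs) == 0L) {
    stop("cannot normalize an empty IMF set.", call. = FALSE)
  }
  scales <- vapply(imfset$imfs, function(v) max(abs(v)), numeric(1))
  imfset$imfs <- purrr::map2(imfset$imfs, scales, function(v, s) {
    if (s > 0) v / s else v
  })
  imfset$scales <- imfset$scales * scales
  imfset$normalized <- TRUE
  imfset
}

#' Recombine an IMF set
#'
#' `reconstruct_imfs()` returns `sum(scales * imfs) + residue` (the full
#' reconstruction, equal to the decomposed input); `recombine_imfs()` omits
#' the residue, i.e. the drivable, trend-free part of the waveform.
#'
#' @param imfset An `imf_set`.
#' @return A `pulse_signal` in displacement units.
#' @export
reconstruct_imfs <- function(imfset) {
  v <- recombine_imfs(imfset)$value + imfset$residue
  new_signal(v, fs = imfset$fs, unit = "du", t0 = imfset$t0)
}

#' @rdname reconstruct_imfs
#' @export
recombine_imfs <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  n <- length(imfset$residue)
  v <- rep(0, n)
  for (i in seq_along(imfset$imfs)) {
    v <- v + imfset$scales[i] * imfset$imfs[[i]]
  }
  new_signal(v, fs = imfset$fs, unit = "du", t0 = imfset$t0)
}

# fixed-width IMF bank: exactly n components, zero-padded, scales padded with 0
imf_bank <- function(imfset, n) {
  len <- length(imfset$residue)
  imfs <- imfset$imfs
  scales <- imfset$scales
  weights <- imfset$weights
  if (length(imfs) > n) {
    imfs <- imfs[seq_len(n)]
    scales <- scales[seq_len(n)]
    weights <- weights[seq_len(n)]
  } else if (length(imfs) < n) {
    pad <- n - length(imfs)
    imfs <- c(imfs, replicate(pad, rep(0, len), simplify = FALSE))
    scales <- c(scales, rep(0, pad))
    weights <- c(weights, rep(0, pad))
  }
  list(imfs = imfs, scales = scales, weights = weights)
}

#' IMF condition diagnostics
#'
#' For each IMF reports the extrema count, zero-crossing count, and the
#' maximum absolute local-envelope mean relative to the IMF's peak amplitude
#' (computed away from the first and last 5% of samples, where spline end
#' effects live). An intrinsic mode function should have
#' `|n_extrema - n_zero_crossings| <= 1` and a near-zero envelope mean.
#'
#' @param imfset An `imf_set`.
#' @return A tibble with one row per IMF.
#' @export
imf_conditions <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  purrr::imap_dfr(imfset$imfs, function(v, i) {
    ext <- find_extrema(v)
    n_ext <- length(ext$maxima) + length(ext$minima)
    n_zc <- count_zero_crossings(v)
    m <- envelope_mean(v)
    rel <- NA_real_
    if (!is.null(m)) {
      n <- length(v)
      core <- seq(from = max(1L, ceiling(0.05 * n)), to = floor(0.95 * n))
      amp <- max(abs(v))
      rel <- if (amp > 0) max(abs(m[core])) / amp else 0
    }
    tibble::tibble(
      imf = i, n_extrema = n_ext, n_zero_crossings = n_zc,
      count_diff = abs(n_ext - n_zc), max_env_mean_rel = rel
    )
  })
}

#' Long-format view of a decomposition
#'
#' @param x An `imf_set`.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `component` (imf1..imfN,
#'   residue), `value`, `weight`.
#' @export
tidy.imf_set <- function(x, ...) {
  n <- length(x$residue)
  t <- x$t0 + (seq_len(n) - 1L) / x$fs
  comps <- c(
    purrr::imap(x$imfs, function(v, i) {
      tibble::tibble(
        time_s = t, component = sprintf("imf%d", i), value = v,
        weight = x$weights[i]
      )
    }),
    list(tibble::tibble(
      time_s = t, component = "residue", value = x$residue, weight = NA_real_
    ))
  )
  dplyr::bind_rows(comps)
}

#' @rdname tidy.imf_set
#' @export
glance.imf_set <- function(x, ...) {
  tibble::tibble(
    n_imfs = length(x$imfs),
    n_samples = length(x$residue),
    fs = x$fs,
    normalized = x$normalized,
    top3_weight = if (length(x$weights) >= 3) {
      sum(sort(x$weights, decreasing = TRUE)[1:3])
    } else {
      sum(x$weights)
    }
  )
}

#' Plot a decomposition
#'
#' @param object An `imf_set`.
#' @param ... Unused.
#' @return A ggplot with one facet per component.
#' @export
autoplot.imf_set <- function(object, ...) {
  long <- tidy.imf_set(object)
  long$component <- factor(long$component, levels = unique(long$component))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize a decomposition to CSV (+ JSON sidecar)
#'
#' Writes a multi-column CSV (`time_s`, `imf1`..`imfN`, `residue`) and, when
#' `jsonlite` is available, a `.json` sidecar with weights, scales and sift
#' iteration counts.
#'
#' @param x An `imf_set`.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_imf_csv <- function(x, path) {
  n <- length(x$residue)
  df <- data.frame(time_s = x$t0 + (seq_len(n) - 1L) / x$fs)
  for (i in seq_along(x$imfs)) df[[sprintf("imf%d", i)]] <- x$imfs[[i]]
  df$residue <- x$residue
  utils::write.csv(df, path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(
      weights = x$weights, scales = x$scales, n_iter = x$n_iter,
      fs = x$fs, normalized = x$normalized
    )
    jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(x)
}
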