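# Independent reference implementations used as oracles. These are written
# as plain, loop-heavy code on purpose: they share the algorithms' published
# definitions with the package but none of its internals.

# reference EMD: straightforward sifting with the same Cauchy SD criterion
# (threshold 0.1), same IMF-condition stop and mirrored-extrema natural
# cubic-spline envelopes, coded independently of pulsereplay's internals.
ref_local_extrema <- function(x) {
  n <- length(x)
  mx <- c()
  mn <- c()
  i <- 2L
  while (i < n) {
    if (x[i] == x[i - 1]) {
      i <- i + 1L
      next
    }
    # scan forward over any plateau
    j <- i
    while (j < n && x[j + 1] == x[j]) j <- j + 1L
    if (j >= n) break
    if (x[i] > x[i - 1] && x[j] > x[j + 1]) {
      mx <- c(mx, floor((i + j) / 2))
    }
    if (x[i] < x[i - 1] && x[j] < x[j + 1]) {
      mn <- c(mn, floor((i + j) / 2))
    }
    i <- j + 1L
  }
  list(max = mx, min = mn)
}

ref_envelope <- function(idx, val, n) {
  l <- length(idx)
  xs <- c(2 - idx[min(2, l)], 2 - idx[1], idx, 2 * n - idx[l], 2 * n - idx[max(1, l - 1)])
  ys <- c(val[min(2, l)], val[1], val, val[l], val[max(1, l - 1)])
  ok <- !duplicated(xs)
  stats::spline(xs[ok], ys[ok], method = "natural", xout = 1:n)$y
}

ref_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) 0 else sum(abs(diff(s)) > 0)
}

ref_sift_once <- function(x, sd_tol = 0.1, max_it = 50) {
  h <- x
  n <- length(x)
  it <- 0
  sd_k <- Inf
  repeat {
    e <- ref_local_extrema(h)
    if (length(e$max) < 2 || length(e$min) < 2) {
      if (it == 0) return(NULL)
      break
    }
    m <- (ref_envelope(e$max, h[e$max], n) + ref_envelope(e$min, h[e$min], n)) / 2
    if (it >= 1 && sd_k < sd_tol) {
      nm <- length(e$max) + length(e$min)
      core <- ceiling(0.05 * n):floor(0.95 * n)
      if (abs(nm - ref_zero_crossings(h)) <= 1 &&
        max(abs(m[core])) <= 0.05 * max(abs(h))) {
        break
      }
    }
    if (it >= max_it) break
    sd_k <- sum(m^2) / sum(h^2)
    h <- h - m
    it <- it + 1
  }
  h
}

ref_emd <- function(x, max_imfs = 7, sd_tol = 0.1) {
  res <- x
  out <- list()
  while (length(out) < max_imfs) {
    e <- ref_local_extrema(res)
    if (length(e$max) < 2 || length(e$min) < 2) break
    imf <- ref_sift_once(res, sd_tol)
    if (is.null(imf)) break
    out[[length(out) + 1]] <- imf
    res <- res - imf
  }
  list(imfs = out, residue = res)
}

# band-limited random test signal: a few well-separated tones with random
# phases plus a smooth trend
make_bandlimited <- function(n = 1000, fs = 250, seed = 1) {
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    f <- sort(stats::runif(3, 0.3, 30))
    # keep tones separated by at least a factor of 3 so EMD can split them
    f <- f[1] * c(1, max(3.5, f[2] / f[1]), max(14, f[3] / f[1]))
    a <- stats::runif(3, 0.5, 1.5)
    ph <- stats::runif(3, 0, 2 * pi)
    v <- a[1] * sin(2 * pi * f[1] * t + ph[1]) +
      a[2] * sin(2 * pi * f[2] * t + ph[2]) +
      a[3] * sin(2 * pi * f[3] * t + ph[3]) + 0.3 * t
    v
  })
}

# tiny deterministic training world for inverse-model tests: noiseless
# sensor, identity-scale plant unless overridden
quiet_sensor <- function() sensor_config(noise_sd = 0)

linear_plant <- function(gain = 0.04, drive_gain = 25) {
  plant_config(
    linear_gain = gain, cubic_coeff = 0, force_damping = 0,
    drive_gain = drive_gain
  )
}

make_recorded_pulses <- function(n, level = "moderate", seed = 1,
                                 noise_sd = 0, fs = 1000, duration = 8) {
  lapply(seq_len(n), function(i) {
    p <- pulse_params(
      heart_rate = 0.9 + 0.5 * (i - 1) / max(1, n - 1),
      force_level = level, seed = seed + i
    )
    w <- generate_pulse(p, duration = duration, fs = fs)
    pvdf_record(w, sensor_config(noise_sd = noise_sd, seed = seed + 100 + i))
  })
}
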