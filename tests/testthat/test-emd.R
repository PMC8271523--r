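sine_signal <- function(f, fs = 250, duration = 8, amp = 1, offset = 0) {
  t <- (seq_len(duration * fs) - 1) / fs
  new_signal(amp * sin(2 * pi * f * t) + offset, fs = fs, unit = "du")
}

test_that("envelope mean of a pure sinusoid is near zero away from the ends", {
  s <- sine_signal(5)
  m <- envelope_mean(s)
  core <- 100:(length(m) - 100)
  expect_lt(max(abs(m[core])), 0.02) # < 2% of unit amplitude

  # a constant offset shifts the envelope mean by that constant
  m2 <- envelope_mean(sine_signal(5, offset = 1.3))
  expect_lt(max(abs(m2[core] - 1.3)), 0.02)
})

test_that("signals without two maxima and two minima have no envelope", {
  expect_null(envelope_mean(seq(0, 1, length.out = 100)))
  expect_null(envelope_mean(rep(1, 50)))
  expect_null(sift(new_signal(seq(0, 1, length.out = 100), fs = 10, unit = "du")))
})

test_that("a sinusoid is already an intrinsic mode function", {
  s <- sine_signal(5)
  imf <- sift(s)
  expect_gt(stats::cor(imf, s$value), 0.99)
  expect_lte(attr(imf, "n_iter"), 3)
})

test_that("sifting separates well-spaced tones, fastest first", {
  t <- (0:1999) / 250
  fast <- sin(2 * pi * 5 * t)
  slow <- sin(2 * pi * 0.5 * t)
  imf1 <- sift(new_signal(fast + slow, fs = 250, unit = "du"))
  expect_gt(stats::cor(imf1, fast), 0.95)
})

test_that("plateaus at turning points are assigned their midpoint", {
  x <- c(0, 1, 2, 2, 2, 1, 0, -1, -1, 0, 1)
  ext <- find_extrema(x)
  expect_equal(ext$maxima, 4L) # middle of the 2,2,2 plateau
  expect_equal(ext$minima, 8L) # floor midpoint of the -1,-1 plateau
})

test_that("decomposition telescopes back to the input within 1e-8", {
  inputs <- list(
    generate_pulse(pulse_params(force_level = "moderate", seed = 1), 8, 250),
    generate_pulse(pulse_params(force_level = "light", seed = 2), 8, 250),
    new_signal(make_bandlimited(seed = 3), fs = 250, unit = "du")
  )
  for (s in inputs) {
    dec <- decompose(s)
    rel <- max(abs(reconstruct_imfs(dec)$value - s$value)) /
      diff(range(s$value))
    expect_lt(rel, 1e-8)
    expect_equal(sum(dec$weights), 1, tolerance = 1e-12)
    expect_true(all(dec$weights >= 0))
  }
})

test_that("a constant signal yields no IMFs and returns itself as residue", {
  s <- new_signal(rep(2.5, 64), fs = 10, unit = "du")
  dec <- decompose(s)
  expect_equal(n_imfs(dec), 0)
  expect_equal(dec$residue, rep(2.5, 64))
  expect_error(decompose(new_signal(c(1, 2), fs = 1, unit = "du")), "short")
})

test_that("an 8 s pulse waveform decomposes into at most seven IMFs", {
  for (lvl in c("light", "moderate", "heavy")) {
    s <- generate_pulse(pulse_params(force_level = lvl, seed = 4), 8, 250)
    expect_lte(n_imfs(decompose(s)), 7)
  }
})

test_that("every returned IMF satisfies the two IMF conditions", {
  s <- generate_pulse(pulse_params(force_level = "moderate", seed = 5), 8, 250)
  cond <- imf_conditions(decompose(s))
  expect_true(all(cond$count_diff <= 1))
  expect_true(all(cond$max_env_mean_rel <= 0.05, na.rm = TRUE))
})

test_that("the residue is left with fewer than two interior extrema pairs", {
  s <- generate_pulse(pulse_params(force_level = "moderate", seed = 6), 8, 250)
  dec <- decompose(s, sift_config(max_imfs = 20))
  ext <- find_extrema(dec$residue)
  expect_true(length(ext$maxima) < 2 || length(ext$minima) < 2)
})

test_that("normalization scales IMFs to unit peak and is exactly invertible", {
  s <- generate_pulse(pulse_params(force_level = "heavy", seed = 7), 8, 250)
  dec <- decompose(s)
  before <- recombine_imfs(dec)$value
  norm <- normalize_imfs(dec)
  for (imf in norm$imfs) expect_equal(max(abs(imf)), 1, tolerance = 1e-12)
  # weighted recombination restores the original IMF sum
  expect_lt(max(abs(recombine_imfs(norm)$value - before)), 1e-8)
  # an already-unit IMF is unchanged
  u <- sine_signal(5)
  dec_u <- normalize_imfs(decompose(u))
  expect_equal(max(abs(dec_u$imfs[[1]])), 1, tolerance = 1e-12)
})

test_that("pulse-structure energy concentrates in the first three IMFs", {
  # noiseless morphology: additive instrument noise would split off extra
  # leading IMFs with near-zero weight (see the methods vignette)
  s <- generate_pulse(pulse_params(noise_sd = 0, seed = 8), 8, 250)
  w <- decompose(s)$weights
  expect_gte(length(w), 3)
  expect_true(all(rank(-w)[1:3] <= 3))
})

test_that("decomposition agrees with an independent reference EMD", {
  n_ok <- 0
  n_cmp <- 0
  for (seed in 1:20) {
    v <- make_bandlimited(n = 1000, fs = 250, seed = seed)
    mine <- decompose(new_signal(v, fs = 250, unit = "du"))
    ref <- ref_emd(v)
    k <- min(3, n_imfs(mine), length(ref$imfs))
    for (i in seq_len(k)) {
      n_cmp <- n_cmp + 1
      if (stats::cor(mine$imfs[[i]], ref$imfs[[i]]) > 0.9) n_ok <- n_ok + 1
    }
  }
  expect_gte(n_cmp, 40)
  expect_equal(n_ok, n_cmp)
})

test_that("IMF serialization writes one column per component", {
  s <- generate_pulse(pulse_params(seed = 9), 4, 250)
  dec <- decompose(s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_imf_csv(dec, path)
  tab <- utils::read.csv(path)
  expect_equal(ncol(tab), n_imfs(dec) + 2) # time + imfs + residue
  expect_equal(tab$imf1, dec$imfs[[1]], tolerance = 1e-9)
})
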