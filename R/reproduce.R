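#' Reproduce one recorded pulse through the simulated player
#'
#' The full replay pipeline: the 1 kHz recorded pulse signal is mean-filter
#' downsampled to 250 Hz and integrated (with linear detrend) to the pulse
#' waveform; EMD splits the waveform into normalized IMFs; the force-matched
#' inverse model predicts a driving signal for each IMF; each driving signal
#' is multiplied by its IMF's amplitude scale and all are summed; the
#' combined drive is upsampled back to 1 kHz by linear interpolation, played
#' through the plant, re-recorded by the PVDF model and integrated to the
#' replayed waveform. The residue (the basic trend of the waveform) is never
#' driven, so the reproduction target is the residue-removed waveform.
#'
#' @param recorded A `pulse_signal` in volts at `playback_fs` (1 kHz).
#' @param force Finger force in newtons; selects the inverse model.
#' @param models A single `inverse_model`, or a named list with elements
#'   `light`, `moderate`, `heavy`.
#' @param plant A [plant_config()].
#' @param sensor A [sensor_config()] used for the replay re-recording.
#' @param sift_cfg A [sift_config()].
#' @param target_fs Working rate of the decomposition grid (250 Hz).
#' @param playback_fs Playback rate (1 kHz).
#' @return A list of class `pulse_reproduction`: `drive` (volt, 1 kHz),
#'   `replayed` (du, 1 kHz), `replayed_ds` (du, 250 Hz), `target` (the
#'   residue-removed original waveform, du, 250 Hz), `waveform` (the full
#'   integrated original, du, 250 Hz) and `imfset`.
#' @export
reproduce_pulse <- function(recorded, force, models,
                            plant = plant_config(),
                            sensor = sensor_config(),
                            sift_cfg = sift_config(),
                            target_fs = 250, playback_fs = 1000) {
  recorded <- as_signal(recorded)
  assert_unit(recorded, "volt")
  if (abs(signal_fs(recorded) - playback_fs) > 1e-6) {
    stop(sprintf("`recorded` must be sampled at %g Hz.", playback_fs),
      call. = FALSE
    )
  }
  model <- if (inherits(models, "inverse_model")) {
    models
  } else {
    lvl <- force_level_of(force)
    if (!lvl %in% names(models)) {
      stop(sprintf("no inverse model supplied for force level '%s'.", lvl),
        call. = FALSE
      )
    }
    models[[lvl]]
  }
  ds <- mean_filter_downsample(recorded, target_fs)
  w <- integrate_signal(ds, detrend = TRUE)
  dec <- decompose(w, sift_cfg)
  if (n_imfs(dec) == 0L) {
    stop("the waveform produced no IMFs; nothing to drive.", call. = FALSE)
  }
  norm <- normalize_imfs(dec)
  n <- length(norm$residue)
  combined <- rep(0, n)
  for (i in seq_along(norm$imfs)) {
    if (norm$scales[i] == 0) next
    imf_sig <- new_signal(norm$imfs[[i]], fs = target_fs, unit = "du",
                          t0 = norm$t0)
    d_i <- predict_drive(model, imf_sig) # volts, unit-amplitude target
    combined <- combined + norm$scales[i] * d_i$value
  }
  drive_lo <- new_signal(combined, fs = target_fs, unit = "volt", t0 = norm$t0)
  drive <- upsample_linear(drive_lo, playback_fs)
  played <- apply_drive(drive, force, plant)
  re_rec <- pvdf_record(played, sensor)
  replayed <- integrate_signal(re_rec, detrend = TRUE)
  structure(
    list(
      drive = drive,
      replayed = replayed,
      replayed_ds = mean_filter_downsample(replayed, target_fs),
      target = recombine_imfs(norm),
      waveform = w,
      imfset = norm,
      force = force
    ),
    class = "pulse_reproduction"
  )
}

#' @export
print.pulse_reproduction <- function(x, ...) {
  m <- verify(list(x$target), list(x$replayed_ds))
  g <- glance.eval_report(m)
  cat(sprintf(
    "# pulse_reproduction @ %.2f N: NRMSE = %.4f, R^2 = %.4f\n",
    x$force, g$mean_nrmse[g$group == "overall"],
    g$mean_r_squared[g$group == "overall"]
  ))
  invisible(x)
}

#' Plot original versus replayed waveform
#'
#' @param object A `pulse_reproduction`.
#' @param ... Unused.
#' @return A ggplot overlaying the residue-removed original and the
#'   replayed waveform on the 250 Hz grid.
#' @export
autoplot.pulse_reproduction <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$target, series = "original (residue removed)"),
    dplyr::mutate(
      tibble::tibble(
        time_s = object$replayed_ds$time_s,
        value = object$replayed_ds$value - mean(object$replayed_ds$value) +
          mean(object$target$value)
      ),
      series = "replayed"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value,
    colour = .data$series
  )) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "displacement (du)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Compare original and replayed waveforms
#'
#' Computes NRMSE and R-squared per pair. Pairs must share a sampling grid
#' and length. Because the DC level of an integrated rate-sensor recording
#' is arbitrary, both series are mean-centred before comparison by default.
#'
#' @param originals,replayed Lists of `pulse_signal`s (or numeric vectors)
#'   of equal count and pairwise equal length.
#' @param ids Optional per-pair identifiers (e.g. subject numbers).
#' @param force_levels Optional per-pair force levels.
#' @param align `"trend"` (default) removes each series' own least-squares
#'   line before comparing — integrated rate-sensor recordings are only
#'   defined modulo an affine-in-time component (unobservable DC level plus
#'   the drift-suppression detrend); `"mean"` centres each series;
#'   `"none"` compares raw values.
#' @return An `eval_report`; see [tidy.eval_report()] and
#'   [glance.eval_report()].
#' @export
verify <- function(originals, replayed, ids = NULL, force_levels = NULL,
                   align = c("trend", "mean", "none")) {
  align <- match.arg(align)
  stopifnot(is.list(originals), is.list(replayed))
  if (length(originals) != length(replayed)) {
    stop("`originals` and `replayed` must have the same length.", call. = FALSE)
  }
  n <- length(originals)
  ids <- ids %||% seq_len(n)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    x <- if (is.data.frame(originals[[i]])) originals[[i]]$value else originals[[i]]
    y <- if (is.data.frame(replayed[[i]])) replayed[[i]]$value else replayed[[i]]
    if (length(x) != length(y)) {
      stop(sprintf("pair %d: length mismatch (%d vs %d).", i, length(x), length(y)),
        call. = FALSE
      )
    }
    if (align == "mean") {
      x <- x - mean(x)
      y <- y - mean(y)
    } else if (align == "trend") {
      tt <- cbind(1, seq_along(x))
      x <- x - stats::lm.fit(tt, x)$fitted.values
      y <- y - stats::lm.fit(tt, y)$fitted.values
    }
    tibble::tibble(
      subject = ids[[i]],
      nrmse = nrmse(x, y),
      r_squared = r_squared(x, y)
    )
  })
  if (!is.null(force_levels)) rows$force_level <- force_levels
  new_eval_report(rows)
}

#' Compare linear and neural reproduction fidelity
#'
#' Independent-sample t-tests (pooled variance by default, Welch via
#' `var_equal = FALSE`) on NRMSE and on R-squared between two evaluation
#' reports over the same trials, per force level (when present) and pooled.
#'
#' @param linear_report,ann_report `eval_report`s over the same trials.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @return A tibble of class `comparison_report` with columns `metric`,
#'   `group`, `mean_linear`, `mean_ann`, `p_value`, `significant`.
#' @export
compare_models <- function(linear_report, ann_report, alpha = 0.05,
                           var_equal = TRUE) {
  stopifnot(inherits(linear_report, "eval_report"),
            inherits(ann_report, "eval_report"))
  lt <- linear_report$trials
  at <- ann_report$trials
  if (nrow(lt) != nrow(at)) {
    stop("the two reports must cover the same trials.", call. = FALSE)
  }
  groups <- list(all = rep(TRUE, nrow(lt)))
  if ("force_level" %in% names(lt)) {
    for (lvl in unique(lt$force_level)) {
      groups[[lvl]] <- lt$force_level == lvl
    }
  }
  rows <- purrr::imap(groups, function(sel, label) {
    if (sum(sel) < 2L) {
      stop(sprintf("group '%s' has fewer than 2 trials.", label), call. = FALSE)
    }
    purrr::map_dfr(c("nrmse", "r_squared"), function(metric) {
      a <- lt[[metric]][sel]
      b <- at[[metric]][sel]
      p <- if (isTRUE(all.equal(a, b))) {
        1
      } else {
        stats::t.test(a, b, var.equal = var_equal)$p.value
      }
      tibble::tibble(
        metric = metric, group = label,
        mean_linear = mean(a), mean_ann = mean(b),
        p_value = p, significant = p < alpha
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("comparison_report", class(out))
  out
}

#' Run the full synthetic record-and-replay benchmark
#'
#' The study protocol, end to end, on synthetic data: for each of the three
#' palpation-force regimes, `n_train` pulse signals are synthesized and
#' recorded, inverse models (1-10-1 neural and linear baseline) are trained
#' on their IMF driving data, and `n_test` held-out pulse signals are
#' reproduced through the plant and scored against the residue-removed
#' originals on the 250 Hz grid. All randomness derives from `seed`.
#'
#' @param seed Master seed (integer).
#' @param n_train Training pulse sets per force range (default 10).
#' @param n_test Held-out verification sets per force range (default 8).
#' @param train_cfg A [train_config()]; defaults to [fast_train_config()].
#' @param plant A [plant_config()].
#' @param sensor_noise_sd Recorder noise in volts (default 0.3, about 2% of
#'   the peak recorded voltage of the reference moderate pulse).
#' @param sift_cfg A [sift_config()].
#' @param duration,fs Pulse length (s) and recording rate (Hz).
#' @return A list of class `pulse_benchmark` with elements `ann_report`,
#'   `linear_report` (both `eval_report`s with `force_level` columns),
#'   `comparison` (a `comparison_report`), and `models` (per-force list with
#'   `ann` and `linear`).
#' @export
run_benchmark <- function(seed = 1, n_train = 10, n_test = 8,
                          train_cfg = fast_train_config(),
                          plant = plant_config(),
                          sensor_noise_sd = 0.3,
                          sift_cfg = sift_config(),
                          duration = 8, fs = 1000) {
  fr <- force_ranges()
  n_levels <- nrow(fr)
  n_sets <- n_train + n_test
  draws <- withr::with_seed(seed, {
    list(
      heart_rates = matrix(stats::runif(n_levels * n_sets, 0.9, 1.5),
        n_levels, n_sets
      ),
      pulse_seeds = matrix(sample.int(2^20, n_levels * n_sets),
        n_levels, n_sets
      ),
      sensor_seeds = matrix(sample.int(2^20, n_levels * (2 * n_sets + 1)),
        n_levels, 2 * n_sets + 1
      ),
      train_seeds = sample.int(2^20, n_levels)
    )
  })
  per_level <- purrr::map(seq_len(n_levels), function(k) {
    lvl <- fr$force_level[k]
    force <- fr$force_n[k]
    record_set <- function(j) {
      params <- pulse_params(
        heart_rate = draws$heart_rates[k, j],
        force_level = lvl, seed = draws$pulse_seeds[k, j]
      )
      w <- generate_pulse(params, duration = duration, fs = fs)
      pvdf_record(w, sensor_config(
        noise_sd = sensor_noise_sd,
        seed = draws$sensor_seeds[k, j]
      ))
    }
    train_recs <- purrr::map(seq_len(n_train), record_set)
    test_recs <- purrr::map(n_train + seq_len(n_test), record_set)
    train_sensor <- sensor_config(
      noise_sd = sensor_noise_sd,
      seed = draws$sensor_seeds[k, 2 * n_sets + 1]
    )
    train <- collect_training_data(
      train_recs, force,
      plant = plant, sensor = train_sensor, sift_cfg = sift_cfg
    )
    cfg_k <- train_cfg
    cfg_k$seed <- draws$train_seeds[k]
    ann <- fit_ann(train, cfg_k)
    linear <- fit_linear(train)
    trial <- function(rec, model, j) {
      replay_sensor <- sensor_config(
        noise_sd = sensor_noise_sd,
        seed = draws$sensor_seeds[k, n_sets + j]
      )
      reproduce_pulse(rec, force, model,
        plant = plant, sensor = replay_sensor, sift_cfg = sift_cfg,
        playback_fs = fs
      )
    }
    reps_ann <- purrr::imap(test_recs, function(rec, j) trial(rec, ann, j))
    reps_lin <- purrr::imap(test_recs, function(rec, j) trial(rec, linear, j))
    list(
      level = lvl,
      targets = purrr::map(reps_ann, "target"),
      targets_lin = purrr::map(reps_lin, "target"),
      replayed_ann = purrr::map(reps_ann, "replayed_ds"),
      replayed_lin = purrr::map(reps_lin, "replayed_ds"),
      models = list(ann = ann, linear = linear)
    )
  })
  ids <- unlist(purrr::map(per_level, function(x) seq_along(x$targets)))
  lvls <- unlist(purrr::map(per_level, function(x) {
    rep(x$level, length(x$targets))
  }))
  ann_report <- verify(
    purrr::flatten(purrr::map(per_level, "targets")),
    purrr::flatten(purrr::map(per_level, "replayed_ann")),
    ids = ids, force_levels = lvls
  )
  linear_report <- verify(
    purrr::flatten(purrr::map(per_level, "targets_lin")),
    purrr::flatten(purrr::map(per_level, "replayed_lin")),
    ids = ids, force_levels = lvls
  )
  structure(
    list(
      ann_report = ann_report,
      linear_report = linear_report,
      comparison = compare_models(linear_report, ann_report),
      models = stats::setNames(
        purrr::map(per_level, "models"),
        purrr::map_chr(per_level, "level")
      )
    ),
    class = "pulse_benchmark"
  )
}

#' @export
print.pulse_benchmark <- function(x, ...) {
  g_ann <- glance.eval_report(x$ann_report)
  g_lin <- glance.eval_report(x$linear_report)
  ov_a <- g_ann[g_ann$group == "overall", ]
  ov_l <- g_lin[g_lin$group == "overall", ]
  cat("# pulse_benchmark\n")
  cat(sprintf(
    "  ANN:    NRMSE %.4f (sd %.4f), R^2 %.4f (sd %.4f), n = %d\n",
    ov_a$mean_nrmse, ov_a$sd_nrmse, ov_a$mean_r_squared, ov_a$sd_r_squared,
    ov_a$n
  ))
  cat(sprintf(
    "  linear: NRMSE %.4f (sd %.4f), R^2 %.4f (sd %.4f)\n",
    ov_l$mean_nrmse, ov_l$sd_nrmse, ov_l$mean_r_squared, ov_l$sd_r_squared
  ))
  invisible(x)
}

#' Summaries of a benchmark run
#'
#' @param x A `pulse_benchmark`.
#' @param ... Unused.
#' @return `glance()`: one row with overall ANN and linear NRMSE / R-squared
#'   averages; `tidy()`: the per-trial table of both model kinds.
#' @export
glance.pulse_benchmark <- function(x, ...) {
  ga <- glance.eval_report(x$ann_report)
  gl <- glance.eval_report(x$linear_report)
  ova <- ga[ga$group == "overall", ]
  ovl <- gl[gl$group == "overall", ]
  tibble::tibble(
    n_trials = ova$n,
    ann_nrmse = ova$mean_nrmse, ann_r_squared = ova$mean_r_squared,
    linear_nrmse = ovl$mean_nrmse, linear_r_squared = ovl$mean_r_squared,
    p_nrmse = x$comparison$p_value[
      x$comparison$metric == "nrmse" & x$comparison$group == "all"
    ],
    p_r_squared = x$comparison$p_value[
      x$comparison$metric == "r_squared" & x$comparison$group == "all"
    ]
  )
}

#' @rdname glance.pulse_benchmark
#' @export
tidy.pulse_benchmark <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$ann_report$trials, model = "ann"),
    dplyr::mutate(x$linear_report$trials, model = "linear")
  )
}
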