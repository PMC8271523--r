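#' Reproduction-fidelity metrics
#'
#' `nrmse()` is the root-mean-square error between the reproduced and original
#' series divided by the range (max - min) of the *original*. `r_squared()` is
#' the coefficient of determination `1 - SS_res / SS_tot` with the original as
#' reference (the squared Pearson correlation is available via
#' `method = "correlation"`).
#'
#' @param original,reproduced Numeric vectors or `pulse_signal`s of equal
#'   length; `original` must not be constant.
#' @return A numeric scalar.
#' @examples
#' nrmse(c(0, 1), c(0, 0)) # sqrt(0.5)
#' r_squared(0:3, 0:3 + 0.1) # 0.992
#' @export
nrmse <- function(original, reproduced) {
  v <- metric_inputs(original, reproduced)
  rng <- max(v$x) - min(v$x)
  if (rng == 0) {
    stop("`original` is constant; NRMSE is undefined.", call. = FALSE)
  }
  sqrt(mean((v$x - v$y)^2)) / rng
}

#' @rdname nrmse
#' @param method `"determination"` (default) for 1 - SS_res/SS_tot, or
#'   `"correlation"` for the squared Pearson correlation.
#' @export
r_squared <- function(original, reproduced,
                      method = c("determination", "correlation")) {
  method <- match.arg(method)
  v <- metric_inputs(original, reproduced)
  if (length(v$x) < 3L) stop("need at least 3 samples.", call. = FALSE)
  ss_tot <- sum((v$x - mean(v$x))^2)
  if (ss_tot == 0) {
    stop("`original` is constant; R-squared is undefined.", call. = FALSE)
  }
  if (method == "determination") {
    1 - sum((v$x - v$y)^2) / ss_tot
  } else {
    stats::cor(v$x, v$y)^2
  }
}

metric_inputs <- function(original, reproduced) {
  x <- if (is.data.frame(original)) original$value else as.numeric(original)
  y <- if (is.data.frame(reproduced)) reproduced$value else as.numeric(reproduced)
  if (length(x) != length(y)) {
    stop("`original` and `reproduced` must have equal length.", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite.", call. = FALSE)
  }
  list(x = x, y = y)
}

# ---- evaluation reports ----------------------------------------------------

new_eval_report <- function(trials) {
  stopifnot(all(c("nrmse", "r_squared") %in% names(trials)))
  structure(list(trials = tibble::as_tibble(trials)), class = "eval_report")
}

#' Per-trial fidelity table of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with one row per trial (`nrmse`, `r_squared`, plus any
#'   identifier columns such as `trial` or `force_level`).
#' @export
tidy.eval_report <- function(x, ...) {
  x$trials
}

#' Summary statistics of an evaluation report
#'
#' Averages and standard deviations of NRMSE and R-squared, per force level
#' when a `force_level` column is present, plus an overall row.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with columns `group`, `n`, `mean_nrmse`, `sd_nrmse`,
#'   `mean_r_squared`, `sd_r_squared`.
#' @export
glance.eval_report <- function(x, ...) {
  tr <- x$trials
  summarise_grp <- function(df, label) {
    tibble::tibble(
      group = label,
      n = nrow(df),
      mean_nrmse = mean(df$nrmse),
      sd_nrmse = if (nrow(df) > 1) stats::sd(df$nrmse) else 0,
      mean_r_squared = mean(df$r_squared),
      sd_r_squared = if (nrow(df) > 1) stats::sd(df$r_squared) else 0
    )
  }
  out <- summarise_grp(tr, "overall")
  if ("force_level" %in% names(tr)) {
    per <- dplyr::bind_rows(lapply(
      split(tr, tr$force_level),
      function(d) summarise_grp(d, d$force_level[1])
    ))
    out <- dplyr::bind_rows(per, out)
  }
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("# eval_report\n")
  print(glance.eval_report(x))
  invisible(x)
}

#' Write an evaluation report as a CSV table
#'
#' Mirrors the published layout: numbered trial rows followed by Average and
#' S.D. rows.
#'
#' @param x An `eval_report`.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_eval_report_csv <- function(x, path) {
  tr <- x$trials
  g <- glance.eval_report(x)
  ov <- g[g$group == "overall", ]
  tab <- data.frame(
    No. = c(as.character(seq_len(nrow(tr))), "Average", "S.D."),
    NRMSE = c(tr$nrmse, ov$mean_nrmse, ov$sd_nrmse),
    R.squared = c(tr$r_squared, ov$mean_r_squared, ov$sd_r_squared)
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(x)
}

#' Plot an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot of per-trial NRMSE and R-squared.
#' @export
autoplot.eval_report <- function(object, ...) {
  tr <- object$trials
  tr$trial <- if ("trial" %in% names(tr)) tr$trial else seq_len(nrow(tr))
  long <- tidyr::pivot_longer(tr, c("nrmse", "r_squared"),
    names_to = "metric", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value))
  if ("force_level" %in% names(long)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$force_level))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
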