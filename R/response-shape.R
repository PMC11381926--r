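#' Trial-averaged traces aligned to stimulation onset
#'
#' Averages each neuron's dF/F across trials (optionally of one PRF) on a
#' common onset-aligned grid from `-pre_s` to `+post_s` seconds.
#'
#' @param traces neurons x timepoints dF/F matrix.
#' @param trials trial tibble (columns `onset_s`, `prf_hz`).
#' @param fs sampling rate.
#' @param pre_s,post_s window around onset, seconds.
#' @param prf_hz optional PRF filter.
#' @return list with `time_rel` (seconds relative to onset; onset at 0) and
#'   `mean` (neurons x window matrix).
#' @export
trial_average <- function(traces, trials, fs = 20, pre_s = 10, post_s = 10,
                          prf_hz = NULL) {
  if (!is.null(prf_hz)) trials <- trials[trials$prf_hz %in% prf_hz, ]
  if (nrow(trials) == 0L) abort("no trials selected")
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  n_samp <- ncol(traces)
  rel_idx <- seq.int(-round(pre_s * fs), round(post_s * fs) - 1L)
  acc <- matrix(0, nrow(traces), length(rel_idx))
  cnt <- 0L
  for (on in trials$onset_s) {
    i0 <- floor(on * fs + 1e-9) + 1L
    idx <- i0 + rel_idx
    if (idx[1] < 1L || idx[length(idx)] > n_samp) next
    acc <- acc + traces[, idx, drop = FALSE]
    cnt <- cnt + 1L
  }
  if (cnt == 0L) abort("no trial fits the requested window")
  list(time_rel = rel_idx / fs, mean = acc / cnt, n_trials = cnt)
}

#' Evoked response profile of a trial-averaged trace
#'
#' Characterizes the evoked response within 5 s of onset: peak time (time of
#' the post-onset maximum), amplitude (peak value minus the minimum between
#' onset and peak), full width at half maximum (total time — possibly
#' non-contiguous — the trace stays above the pre-peak minimum plus half the
#' amplitude, within the 5 s window), and area under the curve (trapezoidal
#' integral over exactly the 5 s post-onset). When the post-onset maximum of
#' the supplied trace occurs after 5 s the profile is invalid (`valid = FALSE`)
#' and the neuron is excluded from response analysis.
#'
#' @param y trial-averaged dF/F starting at onset (first sample = t 0);
#'   supply the full post-onset extent available so late peaks can be detected.
#' @param fs sampling rate.
#' @param window_s analysis window, seconds (5).
#' @return one-row tibble: `peak_time_s`, `amplitude`, `fwhm_s`, `auc`,
#'   `valid`.
#' @export
response_profile <- function(y, fs = 20, window_s = 5) {
  if (all(is.na(y))) abort("all-NA trace")
  n_win <- round(window_s * fs)
  if (length(y) < n_win + 1L) abort("trace must cover the full analysis window")
  post <- y[-1] # peak searched on (0, end]
  ipk <- which.max(post) + 1L
  peak_time <- (ipk - 1) / fs
  if (peak_time > window_s) {
    return(tibble(peak_time_s = peak_time, amplitude = NA_real_,
                  fwhm_s = NA_real_, auc = NA_real_, valid = FALSE))
  }
  base_min <- min(y[1:ipk])
  amplitude <- y[ipk] - base_min
  win <- y[1:(n_win + 1L)]
  half <- base_min + 0.5 * amplitude
  fwhm <- sum(win > half) / fs
  auc <- sum((win[-1] + win[-length(win)]) / 2) / fs
  tibble(peak_time_s = peak_time, amplitude = amplitude, fwhm_s = fwhm,
         auc = auc, valid = TRUE)
}

#' Population response latency
#'
#' The first post-onset time at which the population-average dF/F exceeds the
#' 10 s pre-onset baseline mean by more than two baseline standard deviations;
#' `NA` when the threshold is never crossed.
#'
#' @param y population-average trace on an onset-aligned grid.
#' @param time_rel time relative to onset, seconds (same length as `y`;
#'   must include a pre-onset baseline).
#' @param baseline_s baseline length, seconds.
#' @return latency in seconds, or `NA_real_`.
#' @export
population_latency <- function(y, time_rel, baseline_s = 10) {
  bl <- y[time_rel < 0 & time_rel >= -baseline_s]
  if (length(bl) < 2L) abort("baseline window unavailable")
  s <- sd(bl)
  if (s == 0) abort("zero baseline standard deviation")
  thr <- mean(bl) + 2 * s
  post <- which(time_rel >= 0 & y > thr)
  if (length(post) == 0L) return(NA_real_)
  time_rel[post[1]]
}

#' Two-factor GLM comparison of response metrics
#'
#' Fits `value ~ prf + cell_type + prf:cell_type` (factors) with the requested
#' family (Gaussian/identity by default) and compares it to the intercept-only
#' model with a deviance test (F test for Gaussian, likelihood-ratio chi-square
#' otherwise). Per-coefficient tests are reported only when the deviance test
#' is significant at `alpha`.
#'
#' @param profiles tibble with columns `prf`, `cell_type` and the response.
#' @param response name of the response column.
#' @param family a [stats::family] object.
#' @param alpha significance level gating the coefficient report.
#' @return a `prf_glm` object; see [tidy()] and [glance()] methods.
#' @export
glm_compare <- function(profiles, response, family = gaussian(),
                        alpha = 0.05) {
  stopifnot(all(c("prf", "cell_type", response) %in% names(profiles)))
  df <- tibble(
    value = profiles[[response]],
    prf = factor(profiles$prf),
    cell_type = factor(profiles$cell_type)
  )
  df <- df[is.finite(df$value), ]
  if (nlevels(droplevels(df$prf)) < 2L || nlevels(droplevels(df$cell_type)) < 2L) {
    abort("need at least two levels per factor")
  }
  fit <- glm(value ~ prf * cell_type, data = df, family = family)
  if (fit$rank < length(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste("rank-deficient design; aliased terms:",
                paste(bad, collapse = ", ")))
  }
  null <- glm(value ~ 1, data = df, family = family)
  test_type <- if (family$family == "gaussian") "F" else "LRT"
  an <- anova(null, fit, test = test_type)
  p <- an[2, grep("^Pr", names(an))]
  structure(list(fit = fit, null = null, response = response,
                 deviance = an$Deviance[2], df = an$Df[2],
                 test = test_type, p_value = p, alpha = alpha,
                 n = nrow(df)),
            class = "prf_glm")
}

#' @export
print.prf_glm <- function(x, ...) {
  cat(sprintf("<prf_glm> %s ~ prf * cell_type (n = %d)\n", x$response, x$n))
  cat(sprintf("deviance test vs intercept-only (%s): p = %.4g%s\n",
              x$test, x$p_value,
              if (x$p_value < x$alpha) "" else " (coefficients not analysed)"))
  invisible(x)
}

#' @describeIn glm_compare coefficient table (empty unless the deviance test is
#'   significant, matching the rule of only analysing coefficients after a
#'   significant omnibus test).
#' @param x a `prf_glm` object.
#' @param ... unused.
#' @export
tidy.prf_glm <- function(x, ...) {
  if (x$p_value >= x$alpha) {
    return(tibble(term = character(), estimate = numeric(),
                  std.error = numeric(), statistic = numeric(),
                  p.value = numeric()))
  }
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' @describeIn glm_compare one-row model summary with the deviance test.
#' @export
glance.prf_glm <- function(x, ...) {
  tibble(response = x$response, n = x$n, deviance = x$deviance,
         df = x$df, test = x$test, p_value = x$p_value,
         significant = x$p_value < x$alpha)
}
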