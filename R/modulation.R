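#' Shuffled-baseline null distribution of event density
#'
#' Builds the permutation null for stimulus modulation: in each of `n_iter`
#' iterations, `n_windows` one-second windows are drawn uniformly (with
#' replacement by default) from the baseline — the full recording excluding the
#' 5 s following every stimulation onset — and their event densities averaged.
#' Windows are aligned to the sample grid and must lie wholly inside the
#' baseline. The 95th percentile of the 1000 means is the modulation threshold.
#'
#' @param train an `event_train`.
#' @param trials trial tibble (column `onset_s`).
#' @param n_windows windows averaged per iteration; defaults to the number of
#'   trials of the most frequent PRF (20 for the single-PRF protocol, 25 per
#'   PRF for the alternating protocol).
#' @param n_iter iterations (1000).
#' @param window_s window length, seconds.
#' @param exclude_post_s exclusion zone after each onset, seconds.
#' @param replace draw windows with replacement within an iteration.
#' @param seed integer seed fixing the draw.
#' @return a `shuffle_dist`: list with `samples` (length `n_iter`), `p95`,
#'   `n_windows`, and `n_valid_starts`.
#' @export
shuffle_baseline <- function(train, trials, n_windows = NULL, n_iter = 1000,
                             window_s = 1, exclude_post_s = 5, replace = TRUE,
                             seed = 1L) {
  if (is.null(n_windows)) n_windows <- max(table(trials$prf_hz))
  fs <- train$fs
  n <- train$n
  nw <- round(window_s * fs)
  excluded <- logical(n)
  for (on in trials$onset_s) {
    idx <- window_samples(on, min(on + exclude_post_s, n / fs), fs)
    idx <- idx[idx >= 1 & idx <= n]
    excluded[idx] <- TRUE
  }
  # valid starts: window of nw samples fully inside the recording and baseline
  bad <- cumsum(c(0, as.integer(excluded)))
  starts <- seq_len(n - nw + 1L)
  valid <- starts[bad[starts + nw] - bad[starts] == 0L]
  if (length(valid) == 0L) abort("baseline mask shorter than one window")
  cs <- cumsum(c(0L, train$mask))
  dens <- (cs[valid + nw] - cs[valid]) / nw
  withr::with_seed(seed, {
    samples <- if (replace) {
      rowMeans(matrix(sample(dens, n_iter * n_windows, replace = TRUE), n_iter))
    } else {
      if (length(dens) < n_windows) {
        abort("not enough baseline windows to draw without replacement")
      }
      vapply(seq_len(n_iter),
             function(i) mean(sample(dens, n_windows, replace = FALSE)),
             numeric(1))
    }
    structure(list(samples = samples,
                   p95 = unname(quantile(samples, 0.95)),
                   n_windows = n_windows, n_valid_starts = length(valid)),
              class = "shuffle_dist")
  })
}

#' @export
print.shuffle_dist <- function(x, ...) {
  cat(sprintf("<shuffle_dist> %d iterations x %d windows, p95 = %.4f\n",
              length(x$samples), x$n_windows, x$p95))
  invisible(x)
}

#' Response significance score
#'
#' `(observed - p95) / p95`: the observed stimulation-window event density
#' relative to the 95th percentile of the shuffled baseline distribution. When
#' `p95` is zero the score is `Inf` for a positive observation (reported as
#' such; excluded from rank tests) and 0 when both are zero.
#'
#' @param observed observed event density (>= 0).
#' @param p95 shuffle 95th percentile (>= 0).
#' @return numeric score.
#' @export
response_significance <- function(observed, p95) {
  if (any(observed < 0) || any(p95 < 0)) abort("inputs must be non-negative")
  out <- ifelse(p95 > 0, (observed - p95) / p95,
                ifelse(observed > 0, Inf, 0))
  out
}

#' Classify stimulus modulation for one neuron and PRF
#'
#' Compares the observed event density during the 1 s stimulation window
#' (averaged across that PRF's trials) with the shuffle 95th percentile. A
#' neuron is `modulated` when the stimulation density strictly exceeds p95 and
#' the neuron is not excluded; it is `excluded_preus` when the density in the
#' 1 s window *before* onset already exceeds p95 (events starting just before
#' stimulation would otherwise be falsely credited to it).
#'
#' @param train an `event_train`.
#' @param trials trial tibble (columns `onset_s`, `prf_hz`).
#' @param prf_hz PRF to test.
#' @param dist a [shuffle_baseline()] distribution for this neuron.
#' @param us_s stimulation window length, seconds.
#' @return one-row tibble: `prf_hz`, `observed_us_density`,
#'   `observed_pre_density`, `p95`, `excluded_preus`, `modulated`,
#'   `significance`.
#' @export
classify_modulation <- function(train, trials, prf_hz, dist, us_s = 1) {
  ons <- trials$onset_s[trials$prf_hz == prf_hz]
  if (length(ons) == 0L) abort(sprintf("no trials with PRF %s Hz", prf_hz))
  obs_us <- mean(vapply(ons, function(on) event_density(train, c(on, on + us_s)),
                        numeric(1)))
  obs_pre <- mean(vapply(ons, function(on) event_density(train, c(on - 1, on)),
                         numeric(1)))
  excluded <- obs_pre > dist$p95
  tibble(
    prf_hz = prf_hz,
    observed_us_density = obs_us,
    observed_pre_density = obs_pre,
    p95 = dist$p95,
    excluded_preus = excluded,
    modulated = (obs_us > dist$p95) && !excluded,
    significance = response_significance(obs_us, dist$p95)
  )
}

#' Modulation table for a whole session
#'
#' Runs [shuffle_baseline()] once per neuron (the baseline excludes the 5 s
#' after *all* onsets, so one distribution is reused across PRFs) and
#' [classify_modulation()] for every neuron x PRF. Per-neuron shuffle seeds are
#' derived as `seed + neuron index`, so flags are reproducible.
#'
#' @param trains list of `event_train` (one per neuron).
#' @param trials trial tibble.
#' @param n_iter shuffle iterations.
#' @param seed session-level seed.
#' @param ... passed to [shuffle_baseline()].
#' @return tibble with one row per neuron x PRF (column `neuron` first).
#' @export
modulation_table <- function(trains, trials, n_iter = 1000, seed = 1L, ...) {
  prfs <- sort(unique(trials$prf_hz))
  purrr::map_dfr(seq_along(trains), function(i) {
    train <- trains[[i]]
    if (isTRUE(train$removed)) return(NULL)
    dist <- shuffle_baseline(train, trials, n_iter = n_iter,
                             seed = seed + i, ...)
    purrr::map_dfr(prfs, function(p) {
      mutate(classify_modulation(train, trials, p, dist), neuron = i,
             .before = 1)
    })
  })
}

#' Classify PRF specificity of responders
#'
#' A neuron modulated by exactly one PRF is a `"specific"` responder, by two or
#' more `"non_specific"`, and by none a `"non_responder"`.
#'
#' @param mod_tbl a [modulation_table()] (columns `neuron`, `prf_hz`,
#'   `modulated`).
#' @return tibble: `neuron`, `n_prfs_tested`, `n_modulated`, `class`,
#'   `prfs_modulated` (list column).
#' @export
classify_specificity <- function(mod_tbl) {
  mod_tbl %>%
    group_by(.data$neuron) %>%
    summarise(
      n_prfs_tested = dplyr::n(),
      n_modulated = sum(.data$modulated),
      prfs_modulated = list(.data$prf_hz[.data$modulated]),
      .groups = "drop"
    ) %>%
    mutate(class = dplyr::case_when(
      .data$n_modulated == 1 ~ "specific",
      .data$n_modulated >= 2 ~ "non_specific",
      TRUE ~ "non_responder"
    ))
}

#' Responder proportion report
#'
#' Counts modulated neurons and reports percentages rounded half away from zero
#' to two decimals (the convention used for printed values such as
#' 162/861 = 18.82%).
#'
#' @param df a tibble with a logical `modulated` column (e.g. a
#'   [modulation_table()]), or precomputed counts via `n_modulated` and
#'   `n_total` columns.
#' @param ... grouping columns (tidy-select), e.g. `prf_hz`, `pv`.
#' @return tibble with `n_modulated`, `n_total`, `percent`.
#' @examples
#' proportion_report(tibble::tibble(n_modulated = 162, n_total = 861))
#' @export
proportion_report <- function(df, ...) {
  if (all(c("n_modulated", "n_total") %in% names(df))) {
    out <- df
  } else {
    if (nrow(df) == 0L) abort("empty results")
    out <- df %>%
      group_by(...) %>%
      summarise(n_modulated = sum(.data$modulated),
                n_total = dplyr::n(), .groups = "drop")
  }
  mutate(out, percent = round_half_up(100 * .data$n_modulated / .data$n_total, 2))
}

#' Run the full single-session analysis pipeline
#'
#' Convenience wrapper: event detection on every trace, shuffled-baseline
#' modulation classification for every neuron x PRF, and specificity
#' classification.
#'
#' @param session a `us_session` (or any list with `traces`, `trials`, `fs`).
#' @param params a [detection_params()].
#' @param n_iter shuffle iterations.
#' @param seed seed for the shuffle draws.
#' @return list with `detections` (from [detect_events_matrix()]), `modulation`
#'   (tibble) and `responders` (tibble).
#' @export
analyze_session <- function(session, params = detection_params(),
                            n_iter = 1000, seed = 1L) {
  det <- detect_events_matrix(session$traces, session$fs, params)
  mod <- modulation_table(det$trains, session$trials, n_iter = n_iter,
                          seed = seed)
  list(detections = det, modulation = mod,
       responders = classify_specificity(mod))
}
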