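#' Detection parameters for calcium events
#'
#' Defaults: 1 s moving-mean smoothing; sliding multitaper spectrogram with a
#' 1 s window, time-bandwidth NW = 2 and K = 3 Slepian tapers; analysis band
#' 0.2–2 Hz with per-timepoint band power normalized by total (non-DC) power;
#' candidate peaks must exceed the recording-wide median normalized band power;
#' rise onset is searched within 3 s before the peak; events must have rise
#' time > 100 ms and amplitude > 2.5x the pre-event standard deviation (2 s of
#' clean raw trace before rise onset, falling back to the whole-trace robust SD
#' when fewer than 0.5 s of clean samples are available).
#'
#' `rise_frac` is the takeoff tolerance for rise-onset localisation: the onset
#' is the last pre-peak timepoint at which the lightly smoothed trace is within
#' `rise_frac` of the search window's robust floor (its 10th percentile),
#' relative to the peak-minus-floor excursion. This is the operational reading
#' of "the minimum trace timepoint within 3 s before the peak" that stays put
#' under baseline noise, where the literal argmin lands anywhere in the flat
#' baseline. When the window reaches back across a previously accepted event,
#' the onset search restarts at the separating trough between the two events.
#'
#' @param smooth_s smoothing window, seconds.
#' @param window_s spectrogram window, seconds.
#' @param nw time-bandwidth product of the Slepian tapers.
#' @param k_tapers number of tapers.
#' @param band_hz analysis frequency band, Hz (length 2).
#' @param min_rise_s minimum rise time, seconds (strict).
#' @param amp_factor amplitude threshold in units of pre-event SD (strict).
#' @param pre_sd_s pre-event SD window, seconds.
#' @param min_clean_s minimum clean pre-event data before falling back to the
#'   whole-trace robust SD.
#' @param rise_search_s rise-onset search window before the peak, seconds.
#' @param rise_frac takeoff tolerance (fraction of peak excursion).
#' @param event_footprint_s decay extent past the peak treated as inside the
#'   event when collecting clean pre-event samples for the SD estimate.
#' @param loc_smooth_s light smoothing window used to localise the peak and
#'   rise onset (the heavy `smooth_s` window blurs onsets by half its width).
#' @param peak_refine_s half-width of the window around a candidate within
#'   which the peak position is refined on the lightly smoothed trace.
#' @return a `detection_params` list.
#' @export
detection_params <- function(smooth_s = 1, window_s = 1, nw = 2, k_tapers = 3,
                             band_hz = c(0.2, 2), min_rise_s = 0.1,
                             amp_factor = 2.5, pre_sd_s = 2, min_clean_s = 0.5,
                             rise_search_s = 3, rise_frac = 0.1,
                             event_footprint_s = 2, loc_smooth_s = 0.25,
                             peak_refine_s = 0.5) {
  structure(as.list(environment()), class = "detection_params")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth product
#' `nw`, via the symmetric tridiagonal eigenproblem. Tapers are unit-energy
#' columns, ordered by decreasing eigenvalue.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (k <= 2*nw is the usual choice).
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  stopifnot(n >= 2, k >= 1, k <= n)
  w <- nw / n
  t0 <- 0:(n - 1)
  diag_el <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  off_el <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  a <- matrix(0, n, n)
  diag(a) <- diag_el
  a[cbind(1:(n - 1), 2:n)] <- off_el
  a[cbind(2:n, 1:(n - 1))] <- off_el
  v <- eigen(a, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (sum(v[, j]) < 0) v[, j] <- -v[, j]
  }
  v
}

# per-timepoint multitaper band power normalized by total non-DC power,
# computed with moving complex dot products (centred windows; NA at the edges)
mt_normalized_band_power <- function(x, fs, params) {
  nwin <- max(4L, round(params$window_s * fs))
  tapers <- dpss_tapers(nwin, params$nw, params$k_tapers)
  freqs <- (0:(nwin - 1)) * fs / nwin
  half <- freqs[freqs <= fs / 2]
  band_bins <- which(half >= params$band_hz[1] & half <= params$band_hz[2] &
                       half > 0)
  if (length(band_bins) == 0L) abort("analysis band contains no frequency bins")
  n <- length(x)
  if (n < nwin) abort("trace shorter than the spectrogram window")

  mov_dot <- function(z, kern) {
    # centred moving dot product of z with kern (length nwin)
    as.numeric(stats::filter(z, rev(kern), method = "convolution", sides = 2))
  }
  band <- numeric(n)
  total <- numeric(n)
  for (j in seq_len(ncol(tapers))) {
    h <- tapers[, j]
    # Parseval: sum over all FFT bins of |X_f|^2 = nwin * sum((x*h)^2);
    # the DC bin is removed so slow offsets do not swamp the ratio
    total <- total + nwin * mov_dot(x^2, h^2) - mov_dot(x, h)^2
    for (fb in half[band_bins]) {
      om <- 2 * pi * fb / fs
      tau <- 0:(nwin - 1)
      re <- mov_dot(x, h * cos(om * tau))
      im <- mov_dot(x, h * sin(om * tau))
      two <- if (abs(fb - fs / 2) < 1e-9) 1 else 2 # Nyquist bin is unpaired
      band <- band + two * (re^2 + im^2)
    }
  }
  out <- band / total
  out[!is.finite(out)] <- NA_real_
  out
}

#' Detect calcium events in a dF/F trace
#'
#' Implements the spectral event detector: a sliding multitaper spectrogram
#' yields a per-timepoint normalized band power; candidate peaks are local
#' maxima of the (lightly) smoothed trace whose normalized band power exceeds
#' its median over the recording; each candidate's rise onset is located
#' within 3 s before the peak (restarting at the separating trough when the
#' window crosses a preceding event); events are kept when the rise time
#' exceeds 100 ms and the amplitude (peak minus rise-onset value) exceeds 2.5x
#' the pre-event standard deviation of the raw trace, corroborated on the
#' heavily smoothed trace for events rising straight from baseline.
#' Overlapping rise intervals are merged, keeping the higher peak.
#'
#' @param x numeric dF/F trace on a uniform grid.
#' @param fs sampling rate, samples/s.
#' @param params a [detection_params()].
#' @return an `event_train`: list with `events` tibble (`rise_start_s`,
#'   `peak_s`, `rise_time_s`, `amplitude`, `pre_event_sd`), `mask` (binary
#'   rising-phase vector, 1 during \[rise start, peak\] inclusive), `fs`, `n`
#'   (trace length) and `removed` (`TRUE` when no event was found anywhere, the
#'   rule by which a neuron is excluded from further analysis).
#' @export
detect_events <- function(x, fs = 20, params = detection_params()) {
  n <- length(x)
  if (n < 10 * fs) abort("trace must cover at least 10 s")
  s <- moving_mean(x, max(1L, round(params$smooth_s * fs)))
  sl <- moving_mean(x, max(1L, round(params$loc_smooth_s * fs)))
  np <- mt_normalized_band_power(x, fs, params)
  med <- median(np, na.rm = TRUE)

  refine_n <- round(params$peak_refine_s * fs)
  search_n <- round(params$rise_search_s * fs)
  pre_n <- round(params$pre_sd_s * fs)
  min_clean_n <- round(params$min_clean_s * fs)
  # robust noise SD from first differences, immune to the events themselves
  # (their contribution to successive differences is bounded by the per-sample
  # slope); used for trough separation and as the pre-event SD fallback
  noise_sd <- mad(diff(x)) / sqrt(2)
  fallback_sd <- noise_sd

  # candidate peaks on the lightly smoothed trace: the heavy smoothing window
  # fuses peaks closer than its width into a single local maximum; spurious
  # noise maxima are removed by the spectral gate, a quick excursion screen
  # (no event can pass the amplitude criterion without this excursion), and
  # the amplitude gates downstream
  cand <- which(diff(sign(diff(sl))) < 0) + 1L
  cand <- cand[!is.na(np[cand]) & np[cand] > med]
  trail_min <- running_min_trailing(sl, search_n + 1L)
  cand <- cand[sl[cand] - trail_min[cand] > params$amp_factor * noise_sd]

  # trailing-neighbourhood minimum used by the trough-separation test
  la <- max(1L, round(0.25 * fs))
  lmin_prev <- c(Inf, running_min_trailing(sl, la)[-n])

  in_event <- logical(n)
  ev <- list()
  last_pk <- -Inf
  for (i in cand) {
    w0 <- max(1L, i - search_n)
    if (i - w0 < 2L) next
    seg <- sl[w0:(i - 1L)]
    # when the window reaches back across a preceding event, restart the onset
    # search at the separating trough: the latest point that (a) the trace
    # never undercuts again before the peak, (b) is a minimum of its trailing
    # 0.25 s neighbourhood (the trace descended into it, so points on a
    # monotone rise never qualify), and (c) has both the preceding drop and
    # the subsequent rise exceeding the amplitude criterion, so baseline noise
    # never counts as separation
    drop_thr <- params$amp_factor * noise_sd
    rmin <- rev(cummin(rev(seg)))
    pmax <- cummax(seg)
    sep <- which(seg <= rmin + 1e-12 & seg <= lmin_prev[w0:(i - 1L)] &
                   pmax - seg >= drop_thr & sl[i] - seg >= drop_thr)
    # a separating trough is only credited when an accepted event's peak lies
    # within the search window: the drop must come from a real predecessor,
    # not from an unexplained excursion
    has_sep <- length(sep) > 0L && last_pk >= w0
    if (has_sep) {
      w0 <- w0 + max(sep) - 1L
      if (i - w0 < 2L) next
      seg <- sl[w0:(i - 1L)]
    }
    # the takeoff reference is a low quantile rather than the raw minimum: the
    # minimum of a noisy baseline is an extreme statistic whose depth would
    # drag the takeoff threshold down and scatter the onset into the baseline
    k10 <- max(1L, floor(0.1 * length(seg)))
    base <- sort(seg, partial = k10)[k10]
    thr <- base + params$rise_frac * (sl[i] - base)
    ok <- which(seg <= thr)
    if (length(ok) == 0L) next
    j <- w0 + ok[length(ok)] - 1L
    rise_time <- (i - j) / fs
    if (rise_time <= params$min_rise_s) next
    amp <- sl[i] - sl[j]
    # corroborate on the heavily smoothed trace, whose residual noise is far
    # below the amplitude threshold, so baseline noise excursions cannot pass
    amp_heavy <- max(s[max(1L, i - refine_n):min(n, i + refine_n)]) -
      min(s[w0:i])
    p0 <- max(1L, j - pre_n)
    clean <- which(!in_event[p0:(j - 1L)])
    pre_sd <- if (j > 1L && length(clean) >= min_clean_n) {
      sd(x[p0:(j - 1L)][clean])
    } else fallback_sd
    if (!is.finite(pre_sd) || pre_sd == 0) pre_sd <- fallback_sd
    if (amp <= params$amp_factor * pre_sd) next
    # for candidates rising straight from baseline, corroborate on the heavily
    # smoothed trace; a candidate behind a separating trough already cleared
    # two noise-impossible drops, and the 1 s mean barely dips between close
    # consecutive events, so the corroboration would reject genuine followers
    if (!has_sep && amp_heavy <= params$amp_factor * pre_sd) next
    in_event[j:min(n, i + round(params$event_footprint_s * fs))] <- TRUE
    last_pk <- i
    ev[[length(ev) + 1L]] <- c(j = j, i = i, amp = amp, pre_sd = pre_sd)
  }

  if (length(ev) == 0L) {
    return(structure(list(
      events = tibble(rise_start_s = numeric(), peak_s = numeric(),
                      rise_time_s = numeric(), amplitude = numeric(),
                      pre_event_sd = numeric()),
      mask = integer(n), fs = fs, n = n, removed = TRUE
    ), class = "event_train"))
  }

  evm <- do.call(rbind, ev)
  evm <- evm[order(evm[, "j"], evm[, "i"]), , drop = FALSE]
  # merge chains of overlapping [rise_start, peak] intervals
  merged <- list()
  cur <- evm[1, ]
  cur_members <- list(evm[1, ])
  if (nrow(evm) > 1) {
    for (r in 2:nrow(evm)) {
      row <- evm[r, ]
      if (row["j"] <= cur["i"]) {
        cur_members[[length(cur_members) + 1L]] <- row
        cur["i"] <- max(cur["i"], row["i"])
      } else {
        merged[[length(merged) + 1L]] <- cur_members
        cur <- row
        cur_members <- list(row)
      }
    }
  }
  merged[[length(merged) + 1L]] <- cur_members

  # the merged event is the member with the higher peak; its own onset is kept
  # (an absorbed shoulder's takeoff reflects the shoulder's lower threshold,
  # not this event's onset)
  winners <- t(vapply(merged, function(members) {
    mm <- do.call(rbind, members)
    mm[which.max(sl[mm[, "i"]]), ]
  }, numeric(4)))
  mask <- integer(n)
  for (r in seq_len(nrow(winners))) {
    mask[winners[r, "j"]:winners[r, "i"]] <- 1L
  }
  jj <- unname(winners[, "j"])
  ii <- unname(winners[, "i"])
  rows <- tibble(
    rise_start_s = (jj - 1) / fs,
    peak_s = (ii - 1) / fs,
    rise_time_s = (ii - jj) / fs,
    amplitude = sl[ii] - sl[jj],
    pre_event_sd = unname(winners[, "pre_sd"])
  )
  structure(list(events = rows, mask = mask, fs = fs, n = n, removed = FALSE),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events over %.1f s (%s)\n", nrow(x$events),
              x$n / x$fs, if (x$removed) "flagged: no events" else "kept"))
  invisible(x)
}

#' Detect events for every neuron of a trace matrix
#'
#' @param traces neurons x timepoints dF/F matrix.
#' @param fs sampling rate.
#' @param params a [detection_params()].
#' @return list with `trains` (list of `event_train`), `events` (tidy tibble
#'   with a `neuron` column), and `removed` (logical per neuron: no events
#'   anywhere, excluded from further analysis).
#' @export
detect_events_matrix <- function(traces, fs = 20, params = detection_params()) {
  trains <- lapply(seq_len(nrow(traces)),
                   function(i) detect_events(traces[i, ], fs, params))
  events <- purrr::map_dfr(seq_along(trains), function(i) {
    ev <- trains[[i]]$events
    if (nrow(ev) == 0L) return(NULL)
    mutate(ev, neuron = i, .before = 1)
  })
  list(trains = trains, events = events,
       removed = vapply(trains, `[[`, logical(1), "removed"))
}

#' Event rate over a set of windows
#'
#' Counts events whose peak lies in any of the half-open windows and divides by
#' the total window duration, in events per minute.
#'
#' @param train an `event_train`.
#' @param windows tibble with `start_s`, `end_s` columns (half-open, within the
#'   recording).
#' @return events/min (scalar).
#' @export
event_rate <- function(train, windows) {
  if (nrow(windows) == 0L) abort("empty window set")
  dur <- train$n / train$fs
  if (any(windows$start_s < 0 | windows$end_s > dur + 1e-9)) {
    abort("windows extend outside the recording")
  }
  peaks <- train$events$peak_s
  n_in <- sum(vapply(peaks, function(p) {
    any(p >= windows$start_s & p < windows$end_s)
  }, logical(1)))
  total_s <- sum(windows$end_s - windows$start_s)
  n_in / total_s * 60
}

#' Event density over a window
#'
#' The fraction of samples within the half-open window occupied by event rising
#' phases (mean of the binary rising mask).
#'
#' @param train an `event_train`.
#' @param window numeric length 2: `c(start_s, end_s)`.
#' @return fraction in \[0, 1\].
#' @export
event_density <- function(train, window) {
  idx <- window_samples(window[1], window[2], train$fs, train$n)
  if (length(idx) == 0L) abort("window contains no samples")
  mean(train$mask[idx])
}
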