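#' Configuration for a synthetic imaging session
#'
#' Describes the trial protocol and the statistical structure of the synthetic
#' GCaMP7f traces. Two protocols are supported: `"single_prf"` (20 long trials
#' of 50 s — 10 s pre, 1 s stimulation, 39 s recovery — all at one PRF) and
#' `"alternating"` (25 blocks, each a random permutation of one 21 s trial per
#' PRF in `prf_set`: 10 s pre, 1 s stimulation, 10 s recovery). A 0.5 s pause
#' separates consecutive trials; the generated trace grid is continuous across
#' pauses, matching traces that have been interpolated across inter-trial gaps.
#'
#' Baseline calcium events occur as a homogeneous Poisson process at
#' `baseline_rate` events/min. Each event is a linear rise of duration drawn
#' from `Normal(rise_mean_s, rise_sd_s)` truncated above `rise_min_s`, followed
#' by exponential decay with time constant `decay_tau_s`. A `frac_modulated`
#' fraction of neurons (per PRF) is assigned that PRF as preferred and
#' additionally fires an event with probability `p_evoked` at a latency drawn
#' uniformly from `evoked_latency_s` after each onset of the preferred PRF.
#'
#' @param protocol `"alternating"` or `"single_prf"`.
#' @param n_trials trials (single PRF) or blocks (alternating). Defaults: 20
#'   trials / 25 blocks.
#' @param prf_set pulse repetition frequencies in Hz. Defaults: 10 for
#'   `single_prf`, c(10, 40, 140) for `alternating`.
#' @param pre_s,us_s,post_s,pause_s trial phase durations, seconds. Defaults:
#'   10 / 1 / (39 or 10) / 0.5.
#' @param fs sampling rate, samples/s.
#' @param n_neurons neurons per session.
#' @param frac_modulated fraction of neurons preferring each PRF.
#' @param p_evoked per-trial probability that the preferred PRF elicits an
#'   event.
#' @param baseline_rate spontaneous event rate, events/min.
#' @param rise_mean_s,rise_sd_s,rise_min_s rising-phase duration distribution,
#'   seconds (normal truncated above `rise_min_s`).
#' @param decay_tau_s decay time constant, seconds.
#' @param amp_mean,amp_sd,amp_min event amplitude distribution, dF/F units
#'   (normal truncated above `amp_min`).
#' @param noise_sd additive Gaussian noise SD, dF/F units.
#' @param evoked_latency_s length-2 range (seconds after onset) for evoked
#'   event times.
#' @param pv_frac fraction of neurons labelled parvalbumin-positive.
#' @param seed integer seed; equal seeds give bit-identical sessions.
#' @return an object of class `us_session_config` (a validated list).
#' @export
session_config <- function(protocol = c("alternating", "single_prf"),
                           n_trials = NULL, prf_set = NULL,
                           pre_s = 10, us_s = 1, post_s = NULL, pause_s = 0.5,
                           fs = 20, n_neurons = 50,
                           frac_modulated = 0.15, p_evoked = 0.5,
                           baseline_rate = 3.10,
                           rise_mean_s = 1.11, rise_sd_s = 0.67,
                           rise_min_s = 0.15,
                           decay_tau_s = 0.7,
                           amp_mean = 1, amp_sd = 0.15, amp_min = 0.5,
                           noise_sd = 0.1,
                           evoked_latency_s = c(0, 0.3),
                           pv_frac = 0.12,
                           seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(n_trials)) n_trials <- if (protocol == "single_prf") 20L else 25L
  if (is.null(prf_set)) {
    prf_set <- if (protocol == "single_prf") 10 else c(10, 40, 140)
  }
  if (is.null(post_s)) post_s <- if (protocol == "single_prf") 39 else 10
  if (protocol == "single_prf" && length(prf_set) != 1L) {
    abort("single_prf protocol takes exactly one PRF")
  }
  stopifnot(
    length(prf_set) >= 1L, fs > 0, n_trials >= 1L,
    pre_s >= 0, us_s > 0, post_s >= 0, pause_s >= 0,
    frac_modulated >= 0, frac_modulated <= 1,
    p_evoked >= 0, p_evoked <= 1,
    baseline_rate >= 0, rise_min_s > 0, decay_tau_s > 0,
    noise_sd >= 0, length(evoked_latency_s) == 2L,
    pv_frac >= 0, pv_frac <= 1
  )
  if (length(prf_set) * frac_modulated > 1) {
    abort("frac_modulated * number of PRFs cannot exceed 1")
  }
  if (pre_s + us_s + post_s <= 0) abort("trial durations inconsistent with protocol")
  structure(
    list(protocol = protocol, n_trials = as.integer(n_trials),
         prf_set = prf_set, pre_s = pre_s, us_s = us_s, post_s = post_s,
         pause_s = pause_s, fs = fs, n_neurons = as.integer(n_neurons),
         frac_modulated = frac_modulated, p_evoked = p_evoked,
         baseline_rate = baseline_rate, rise_mean_s = rise_mean_s,
         rise_sd_s = rise_sd_s, rise_min_s = rise_min_s,
         decay_tau_s = decay_tau_s, amp_mean = amp_mean, amp_sd = amp_sd,
         amp_min = amp_min, noise_sd = noise_sd,
         evoked_latency_s = evoked_latency_s, pv_frac = pv_frac,
         seed = as.integer(seed)),
    class = "us_session_config"
  )
}

# trial structure implied by a config; random block permutations for the
# alternating protocol are drawn from the current RNG stream
make_trial_structure <- function(config) {
  trial_len <- config$pre_s + config$us_s + config$post_s
  if (config$protocol == "single_prf") {
    starts <- (seq_len(config$n_trials) - 1) * (trial_len + config$pause_s)
    prf <- rep(config$prf_set, config$n_trials)
  } else {
    k <- length(config$prf_set)
    prf <- as.vector(vapply(seq_len(config$n_trials),
                            function(b) sample(config$prf_set, k),
                            numeric(k)))
    n_tot <- config$n_trials * k
    starts <- (seq_len(n_tot) - 1) * (trial_len + config$pause_s)
  }
  onsets <- starts + config$pre_s
  duration <- max(starts) + trial_len
  tibble(
    trial = seq_along(onsets),
    prf_hz = prf,
    start_s = starts,
    onset_s = onsets,
    end_s = starts + trial_len
  ) -> trials
  attr(trials, "session_duration_s") <- duration
  attr(trials, "pre_s") <- config$pre_s
  attr(trials, "us_s") <- config$us_s
  attr(trials, "post_s") <- config$post_s
  attr(trials, "fs") <- config$fs
  trials
}

# render a set of events (t0, rise, amp) onto a sample grid
render_events <- function(n_samples, fs, t0, rise, amp, tau) {
  x <- numeric(n_samples)
  if (length(t0) == 0L) return(x)
  t_grid <- (seq_len(n_samples) - 1) / fs
  span <- rise + 8 * tau
  for (e in seq_along(t0)) {
    i1 <- max(1L, floor(t0[e] * fs) + 1L)
    i2 <- min(n_samples, ceiling((t0[e] + span[e]) * fs) + 1L)
    if (i2 < i1) next
    tt <- t_grid[i1:i2] - t0[e]
    kern <- ifelse(tt < 0, 0,
            ifelse(tt <= rise[e], amp[e] * tt / rise[e],
                   amp[e] * exp(-(tt - rise[e]) / tau)))
    x[i1:i2] <- x[i1:i2] + kern
  }
  x
}

#' Generate a synthetic calcium imaging session
#'
#' Simulates per-neuron dF/F traces with ground truth: spontaneous events as a
#' homogeneous Poisson process, ultrasound-evoked events in a PRF-preferring
#' subset of neurons, linear-rise/exponential-decay event kernels, and additive
#' Gaussian noise. Identical seeds produce bit-identical sessions.
#'
#' @param config a [session_config()].
#' @param sham if `TRUE`, the trial structure is kept but no neuron receives
#'   evoked events and all ground-truth modulation flags are `FALSE`.
#' @return a `us_session`: list with `traces` (neurons x timepoints matrix of
#'   dF/F), `time` (seconds), `fs`, `trials` (tibble: trial, prf_hz, start_s,
#'   onset_s, end_s), `truth` (list of `neurons` and `events` tibbles), and
#'   `config`.
#' @seealso [simulate_sham_session()], [analyze_session()]
#' @export
simulate_session <- function(config, sham = FALSE) {
  stopifnot(inherits(config, "us_session_config"))
  withr::with_seed(config$seed, {
    trials <- make_trial_structure(config)
    duration <- attr(trials, "session_duration_s")
    n_samples <- floor(duration * config$fs)
    n <- config$n_neurons

    # preferred PRF per neuron: frac_modulated per PRF, rest unassigned
    k <- length(config$prf_set)
    probs <- c(rep(config$frac_modulated, k), 1 - k * config$frac_modulated)
    pref_idx <- sample.int(k + 1L, n, replace = TRUE, prob = probs)
    preferred <- ifelse(pref_idx <= k, config$prf_set[pmin(pref_idx, k)], NA_real_)
    if (sham) preferred <- rep(NA_real_, n)
    pv <- runif(n) < config$pv_frac

    traces <- matrix(0, nrow = n, ncol = n_samples)
    ev_list <- vector("list", n)
    for (i in seq_len(n)) {
      n_base <- rpois(1, config$baseline_rate * duration / 60)
      t0 <- sort(runif(n_base, 0, duration))
      evoked <- rep(FALSE, n_base)
      ev_prf <- rep(NA_real_, n_base)
      if (!sham && !is.na(preferred[i]) && config$p_evoked > 0) {
        ons <- trials$onset_s[trials$prf_hz == preferred[i]]
        hit <- runif(length(ons)) < config$p_evoked
        lat <- runif(sum(hit), config$evoked_latency_s[1], config$evoked_latency_s[2])
        t0 <- c(t0, ons[hit] + lat)
        evoked <- c(evoked, rep(TRUE, sum(hit)))
        ev_prf <- c(ev_prf, rep(preferred[i], sum(hit)))
      }
      ord <- order(t0)
      t0 <- t0[ord]; evoked <- evoked[ord]; ev_prf <- ev_prf[ord]
      m <- length(t0)
      rise <- rnorm_trunc(m, config$rise_mean_s, config$rise_sd_s, config$rise_min_s)
      amp <- rnorm_trunc(m, config$amp_mean, config$amp_sd, config$amp_min)
      traces[i, ] <- render_events(n_samples, config$fs, t0, rise, amp,
                                   config$decay_tau_s)
      ev_list[[i]] <- tibble(neuron = i, t0_s = t0, rise_s = rise,
                             amplitude = amp, evoked = evoked, prf_hz = ev_prf)
    }
    if (config$noise_sd > 0) {
      traces <- traces + matrix(rnorm(n * n_samples, 0, config$noise_sd), n)
    }

    neurons <- tibble(
      neuron = seq_len(n),
      preferred_prf = preferred,
      modulated = !is.na(preferred),
      pv = pv
    )
    structure(
      list(traces = traces,
           time = (seq_len(n_samples) - 1) / config$fs,
           fs = config$fs,
           trials = trials,
           truth = list(neurons = neurons, events = bind_rows(ev_list)),
           config = config,
           sham = sham),
      class = "us_session"
    )
  })
}

#' Generate a sham session (no acoustic coupling)
#'
#' Same trial structure as [simulate_session()] with the same seed, but no
#' evoked component for any neuron — emulating stimulation with the coupling
#' gel omitted so no acoustic wave reaches the brain.
#'
#' @inheritParams simulate_session
#' @return a `us_session` whose ground-truth modulation flags are all `FALSE`.
#' @export
simulate_sham_session <- function(config) {
  simulate_session(config, sham = TRUE)
}

#' @export
print.us_session <- function(x, ...) {
  cat(sprintf(
    "<us_session> %s%s: %d neurons, %d trials (PRFs %s Hz), %.1f s at %g Hz\n",
    x$config$protocol, if (isTRUE(x$sham)) " (sham)" else "",
    nrow(x$traces), nrow(x$trials),
    paste(unique(x$trials$prf_hz), collapse = "/"),
    max(x$time) + 1 / x$fs, x$fs))
  invisible(x)
}

#' Stimulation-relative windows of a trial structure
#'
#' Convenience window sets used throughout the analysis, as a tibble of
#' half-open `[start_s, end_s)` intervals.
#'
#' @param trials a trial tibble from a `us_session` (columns `onset_s`,
#'   `start_s`, `end_s`, `prf_hz`).
#' @param what `"us"` (the 1 s stimulation windows), `"pre"` (1 s immediately
#'   before onset), or `"non_us"` (everything outside
#'   `[onset, onset + us_s + exclude_post_s)`).
#' @param us_s stimulation duration in seconds.
#' @param exclude_post_s post-stimulation seconds excluded from `"non_us"`.
#' @param prf_hz optional PRF filter.
#' @param duration_s total recording duration (required for `"non_us"`).
#' @return tibble with columns `start_s`, `end_s`.
#' @export
trial_windows <- function(trials, what = c("us", "pre", "non_us"), us_s = 1,
                          exclude_post_s = 5, prf_hz = NULL,
                          duration_s = NULL) {
  what <- match.arg(what)
  if (!is.null(prf_hz)) trials <- trials[trials$prf_hz %in% prf_hz, ]
  ons <- sort(trials$onset_s)
  if (what == "us") return(tibble(start_s = ons, end_s = ons + us_s))
  if (what == "pre") return(tibble(start_s = ons - 1, end_s = ons))
  if (is.null(duration_s)) abort("duration_s is required for non_us windows")
  excl_start <- ons
  excl_end <- pmin(ons + us_s + exclude_post_s, duration_s)
  starts <- c(0, excl_end)
  ends <- c(excl_start, duration_s)
  keep <- ends > starts
  tibble(start_s = starts[keep], end_s = ends[keep])
}
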