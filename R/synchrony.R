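#' Asymmetric correlation coefficient of two binary event trains
#'
#' \deqn{ACC_{A,B} = \frac{1}{2}\left(\frac{\sum A \cap B}{\sum A} +
#' \frac{\sum B \cap A}{\sum B}\right)}
#'
#' The proportion of co-occurring event samples, averaged over the two
#' directions; symmetric, in \[0, 1\], and 1 for identical nonzero trains.
#' Pairs where either train has no events are undefined (`NA`), and are
#' excluded from group averages rather than counted as zero.
#'
#' @param a,b binary vectors of equal length (event rising-phase masks).
#' @return numeric scalar or `NA` when undefined.
#' @examples
#' acc(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 0.5
#' @export
acc <- function(a, b) {
  if (length(a) != length(b)) abort("trains must have equal length")
  sa <- sum(a != 0)
  sb <- sum(b != 0)
  if (sa == 0 || sb == 0) return(NA_real_)
  inter <- sum(a != 0 & b != 0)
  (inter / sa + inter / sb) / 2
}

pair_group_label <- function(fi, fj, names = c("Mod", "Non")) {
  # canonical order: Mod:Mod, Mod:Non, Non:Non
  first <- ifelse(fi | fj, names[1], names[2])
  second <- ifelse(fi & fj, names[1], names[2])
  paste(first, second, sep = ":")
}

#' Sustained ACC over all neuron pairs
#'
#' Computes the ACC over the full recording for every unordered pair (i < j),
#' with optional pair-group labels from a per-neuron logical flag (e.g.
#' modulated by a given PRF, or PV).
#'
#' @param masks neurons x timepoints binary matrix (rows are rising-phase
#'   masks).
#' @param flags optional logical vector per neuron; pairs are labelled
#'   `Mod:Mod`, `Mod:Non`, `Non:Non` (names controlled by `group_names`).
#' @param group_names length-2 labels for flagged / unflagged neurons.
#' @return tibble with `i`, `j`, `acc`, and `group` when flags are given.
#' @export
sustained_acc <- function(masks, flags = NULL, group_names = c("Mod", "Non")) {
  n <- nrow(masks)
  if (n < 2L) abort("need at least two neurons")
  m <- (masks != 0) * 1
  inter <- m %*% t(m)
  s <- rowSums(m)
  pairs <- which(upper.tri(inter), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  val <- ifelse(s[i] == 0 | s[j] == 0, NA_real_,
                (inter[pairs] / s[i] + inter[pairs] / s[j]) / 2)
  out <- tibble(i = i, j = j, acc = val)
  if (!is.null(flags)) {
    out$group <- pair_group_label(flags[i], flags[j], group_names)
  }
  out
}

#' Transient ACC in trial-aligned one-second bins
#'
#' For every neuron pair and every 1 s bin of the trial (bin grid anchored at
#' the trial start, labelled by bin start relative to stimulation onset), the
#' ACC is computed on that bin's samples pooled across the selected trials.
#' Pooling keeps the event-rate information that drives the stimulation-locked
#' synchrony increase; computing the ACC within single trials and averaging
#' would condition on both neurons firing in the same trial-bin and leave most
#' baseline bins undefined. Bins where either train has no event sample in any
#' trial are undefined (`NA`) and excluded from group averages.
#'
#' @param masks neurons x timepoints binary matrix.
#' @param trials trial tibble (columns `start_s`, `onset_s`, `end_s`); only
#'   trials of `prf_hz` are used when given.
#' @param fs sampling rate.
#' @param bin_s bin width, seconds.
#' @param prf_hz optional PRF filter.
#' @param flags optional per-neuron logical for pair-group labels.
#' @param group_names length-2 labels for flagged / unflagged neurons.
#' @return tibble: `i`, `j`, `bin_rel_s` (bin start relative to onset), `acc`,
#'   and `group` when flags are given.
#' @export
transient_acc <- function(masks, trials, fs = 20, bin_s = 1, prf_hz = NULL,
                          flags = NULL, group_names = c("Mod", "Non")) {
  if (!is.null(prf_hz)) trials <- trials[trials$prf_hz %in% prf_hz, ]
  if (nrow(trials) == 0L) abort("no trials selected")
  n <- nrow(masks)
  m <- (masks != 0) * 1
  n_samp <- ncol(m)
  trial_len <- min(trials$end_s - trials$start_s)
  n_bins <- floor(trial_len / bin_s)
  rel0 <- trials$start_s[1] - trials$onset_s[1]

  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  out <- purrr::map_dfr(seq_len(n_bins), function(b) {
    idx <- unlist(lapply(trials$start_s, function(t0) {
      w <- window_samples(t0 + (b - 1) * bin_s, t0 + b * bin_s, fs)
      w[w >= 1 & w <= n_samp]
    }))
    sl <- m[, idx, drop = FALSE]
    s <- rowSums(sl)
    inter <- sl %*% t(sl)
    v <- ifelse(s[pairs[, 1]] == 0 | s[pairs[, 2]] == 0, NA_real_,
                (inter[pairs] / s[pairs[, 1]] + inter[pairs] / s[pairs[, 2]]) / 2)
    tibble(i = pairs[, 1], j = pairs[, 2],
           bin_rel_s = rel0 + (b - 1) * bin_s, acc = v)
  })
  if (!is.null(flags)) {
    out$group <- pair_group_label(flags[out$i], flags[out$j], group_names)
  }
  out
}

#' Collapse a transient-ACC table to group time courses and conditions
#'
#' Averages the trial-averaged pair ACC over pairs per group and bin, then
#' collapses the first `bl_s` seconds of the trial into a baseline condition
#' `"BL"`; post-onset bins keep labels `"0-1"`, `"1-2"`, ... These are the
#' session-level summaries used for the repeated-measures (Friedman)
#' comparison.
#'
#' @param tacc a [transient_acc()] table with a `group` column (use
#'   `group = "All:All"` by adding a constant column to compare all pairs).
#' @param bl_s seconds of the trial head averaged into the baseline condition.
#' @param max_post_s latest post-onset bin retained.
#' @return tibble: `group`, `condition` (factor: BL, 0-1, 1-2, ...), `acc`.
#' @export
transient_acc_conditions <- function(tacc, bl_s = 8, max_post_s = 5) {
  pre_start <- min(tacc$bin_rel_s)
  tacc %>%
    filter(.data$bin_rel_s < pre_start + bl_s |
             (.data$bin_rel_s >= 0 & .data$bin_rel_s < max_post_s)) %>%
    mutate(condition = ifelse(.data$bin_rel_s < 0, "BL",
                              sprintf("%d-%d", floor(.data$bin_rel_s),
                                      floor(.data$bin_rel_s) + 1L))) %>%
    group_by(.data$group, .data$condition) %>%
    summarise(acc = mean(.data$acc, na.rm = TRUE), .groups = "drop")
}
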