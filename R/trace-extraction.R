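#' Extract ROI traces with donut background subtraction
#'
#' For every labelled ROI, the raw trace is the per-frame mean intensity of the
#' ROI's pixels minus the mean intensity of its surrounding "donut" mask: the
#' annulus between `inner_px` and `outer_px` pixels from the ROI centroid,
#' excluding pixels belonging to *any* ROI. This removes local background
#' activity; a spatially uniform offset per frame cancels exactly.
#'
#' @param movie height x width x time array.
#' @param mask integer label matrix (0 = background, k = ROI k).
#' @param inner_px,outer_px donut annulus radii in pixels (default 15 / 50).
#' @return list with `traces` (ROI x time matrix of background-subtracted
#'   intensities) and `info` tibble (`roi`, centroid `x`/`y`, `n_pixels`,
#'   `n_donut_pixels`, `flagged`). ROIs whose donut is empty after exclusions
#'   are flagged, skipped with a warning, and returned with `NA` traces.
#' @export
extract_traces <- function(movie, mask, inner_px = 15, outer_px = 50) {
  dm <- dim(movie)
  if (!all(dim(mask) == dm[1:2])) abort("mask dimensions must match movie frames")
  labels <- sort(unique(mask[mask > 0L]))
  if (length(labels) == 0L) abort("mask contains no ROIs")
  n_t <- dm[3]
  m2 <- matrix(movie, dm[1] * dm[2], n_t)
  xg <- matrix(rep(seq_len(dm[2]), each = dm[1]), dm[1])
  yg <- matrix(rep(seq_len(dm[1]), dm[2]), dm[1])
  any_roi <- mask > 0L

  traces <- matrix(NA_real_, length(labels), n_t)
  info <- vector("list", length(labels))
  for (j in seq_along(labels)) {
    idx <- which(mask == labels[j])
    cx <- mean(xg[idx]); cy <- mean(yg[idx])
    d2 <- (xg - cx)^2 + (yg - cy)^2
    donut <- which(d2 > inner_px^2 & d2 <= outer_px^2 & !any_roi)
    flagged <- length(donut) == 0L
    if (flagged) {
      warn(sprintf("ROI %d has an empty donut after exclusions; skipped", labels[j]))
    } else {
      traces[j, ] <- colMeans(m2[idx, , drop = FALSE]) -
        colMeans(m2[donut, , drop = FALSE])
    }
    info[[j]] <- tibble(roi = labels[j], x = cx, y = cy,
                        n_pixels = length(idx),
                        n_donut_pixels = length(donut), flagged = flagged)
  }
  list(traces = traces, info = bind_rows(info))
}

#' Preprocess raw traces to trial-referenced dF/F
#'
#' Applies the fixed pipeline: (1) shape-preserving piecewise-cubic (PCHIP)
#' interpolation onto a uniform `fs` Hz grid (spanning any inter-trial gaps);
#' (2) linear detrend (removes the least-squares line, e.g. photobleaching);
#' (3) min–max normalization to \[0, 1\]; (4) per trial, subtraction of the
#' mean over the 10 s pre-stimulation window, so every trial's pre-onset
#' baseline averages exactly zero. Constant traces cannot be normalized and are
#' dropped (absent from the output, recorded in `dropped`).
#'
#' @param traces neurons x timepoints matrix of raw traces.
#' @param trials trial tibble (columns `start_s`, `onset_s`, `end_s`).
#' @param timestamps sample times in seconds (may be non-uniform); defaults to
#'   a uniform grid at `fs_in`.
#' @param fs_in input sampling rate used when `timestamps` is `NULL`.
#' @param fs output sampling rate (20 Hz).
#' @param pre_s pre-stimulation baseline length in seconds.
#' @return list with `traces` (kept neurons x output timepoints, stage dF/F),
#'   `time`, `fs`, `kept` (row indices of the input retained), and `dropped`
#'   tibble (`neuron`, `reason`).
#' @export
preprocess_traces <- function(traces, trials, timestamps = NULL, fs_in = 20,
                              fs = 20, pre_s = 10) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  n_t <- ncol(traces)
  if (is.null(timestamps)) timestamps <- (seq_len(n_t) - 1) / fs_in
  stopifnot(length(timestamps) == n_t)
  grid <- seq(0, max(timestamps), by = 1 / fs)
  n_out <- length(grid)

  # trial segment boundaries: each sample belongs to the trial whose segment
  # [start, next start) contains it, so pause samples attach to the preceding
  # trial and the per-trial baseline shift covers the whole segment
  seg_start <- trials$onset_s - pre_s
  seg_idx <- findInterval(grid, seg_start)

  out <- matrix(NA_real_, nrow(traces), n_out)
  dropped <- list()
  kept <- logical(nrow(traces))
  for (i in seq_len(nrow(traces))) {
    y <- traces[i, ]
    if (anyNA(y)) {
      dropped[[length(dropped) + 1L]] <- tibble(neuron = i, reason = "missing values")
      next
    }
    yi <- signal::pchip(timestamps, y, grid)
    rng_raw <- max(yi) - min(yi)
    yi <- stats::lm.fit(cbind(1, grid), yi)$residuals
    rng <- max(yi) - min(yi)
    if (rng <= 1e-9 * max(rng_raw, 1)) {
      dropped[[length(dropped) + 1L]] <- tibble(neuron = i, reason = "constant trace")
      next
    }
    yi <- (yi - min(yi)) / rng
    for (tr in seq_len(nrow(trials))) {
      base_idx <- window_samples(trials$onset_s[tr] - pre_s, trials$onset_s[tr],
                                 fs)
      base_idx <- base_idx[base_idx >= 1 & base_idx <= n_out]
      seg <- which(seg_idx == tr)
      if (length(base_idx) > 0 && length(seg) > 0) {
        yi[seg] <- yi[seg] - mean(yi[base_idx])
      }
    }
    out[i, ] <- yi
    kept[i] <- TRUE
  }
  list(traces = out[kept, , drop = FALSE], time = grid, fs = fs,
       kept = which(kept),
       dropped = if (length(dropped)) bind_rows(dropped) else
         tibble(neuron = integer(), reason = character()))
}

#' Label parvalbumin-positive ROIs by cross-channel overlap
#'
#' A GCaMP ROI is labelled PV-positive when strictly more than half of its
#' pixels fall inside any tdTomato ROI, after warping the tdTomato mask into
#' the GCaMP coordinate frame with an optional precomputed affine/projective
#' transform (3 x 3 matrix mapping homogeneous GCaMP pixel coordinates
#' `(x, y, 1)` to tdTomato coordinates; identity when `NULL`).
#'
#' @param gcamp_mask,tdt_mask integer label matrices.
#' @param transform optional 3 x 3 transform matrix (GCaMP -> tdT coordinates);
#'   must be non-degenerate.
#' @return tibble with `roi`, `overlap` (fraction of the GCaMP ROI covered),
#'   and `pv` (logical, `overlap > 0.5` strictly).
#' @export
match_pv <- function(gcamp_mask, tdt_mask, transform = NULL) {
  labels <- sort(unique(gcamp_mask[gcamp_mask > 0L]))
  if (length(labels) == 0L) abort("gcamp mask contains no ROIs")
  h <- nrow(gcamp_mask); w <- ncol(gcamp_mask)
  xg <- rep(seq_len(w), each = h)
  yg <- rep(seq_len(h), w)
  if (!is.null(transform)) {
    stopifnot(all(dim(transform) == c(3, 3)))
    if (abs(det(transform)) < 1e-12) abort("degenerate transform")
    pts <- transform %*% rbind(xg, yg, 1)
    xs <- round(pts[1, ] / pts[3, ]); ys <- round(pts[2, ] / pts[3, ])
  } else {
    xs <- xg; ys <- yg
  }
  inside <- xs >= 1 & xs <= ncol(tdt_mask) & ys >= 1 & ys <= nrow(tdt_mask)
  tdt_pos <- logical(h * w)
  tdt_pos[inside] <- tdt_mask[cbind(ys[inside], xs[inside])] > 0L
  purrr::map_dfr(labels, function(lb) {
    idx <- which(gcamp_mask == lb)
    ov <- mean(tdt_pos[idx])
    tibble(roi = lb, overlap = ov, pv = ov > 0.5)
  })
}
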