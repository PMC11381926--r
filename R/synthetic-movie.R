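#' Lay out non-overlapping circular ROIs in a frame
#'
#' Places `n` circular ROIs of radius `radius_px` in an `height_px` x
#' `width_px` frame such that no two ROIs overlap and each ROI keeps
#' `margin_px` clearance from the frame edge (so its background annulus fits).
#'
#' @param n number of ROIs.
#' @param height_px,width_px frame size in pixels.
#' @param radius_px ROI radius in pixels.
#' @param margin_px minimum distance from ROI centre to frame edge.
#' @param min_sep_px minimum centre-to-centre separation; defaults to
#'   `2 * radius_px + 2`.
#' @param seed integer seed.
#' @return tibble with columns `roi`, `x`, `y`, `radius_px`.
#' @export
roi_layout <- function(n, height_px = 128, width_px = 128, radius_px = 4,
                       margin_px = radius_px + 1, min_sep_px = NULL,
                       seed = 1L) {
  if (is.null(min_sep_px)) min_sep_px <- 2 * radius_px + 2
  withr::with_seed(seed, {
    xs <- ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n) {
      x <- runif(1, margin_px, width_px - margin_px)
      y <- runif(1, margin_px, height_px - margin_px)
      if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= min_sep_px^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
      tries <- tries + 1L
      if (tries > 10000L) abort("could not place non-overlapping ROIs; reduce n or radius")
    }
    tibble(roi = seq_len(n), x = xs, y = ys, radius_px = radius_px)
  })
}

#' Render traces into a synthetic fluorescence movie
#'
#' Builds an `height x width x time` movie in which each ROI's pixels carry its
#' trace (plus independent pixel noise) on top of a spatially smooth,
#' temporally drifting background process, so that background (donut)
#' subtraction during extraction is non-trivial. Returns the matching integer
#' label mask.
#'
#' @param traces neurons x timepoints matrix; row i drives ROI i.
#' @param layout a [roi_layout()] tibble with one row per trace row. ROIs must
#'   not overlap.
#' @param height_px,width_px frame size.
#' @param baseline constant offset added everywhere (camera baseline).
#' @param background_amp amplitude of the smooth background process (0 turns
#'   it off).
#' @param background_period_s temporal period of the background drift.
#' @param fs sampling rate (for the background drift).
#' @param pixel_noise_sd per-pixel Gaussian noise SD.
#' @param seed integer seed.
#' @return list with `movie` (array height x width x time), `mask` (integer
#'   label matrix), and `layout`.
#' @export
simulate_movie <- function(traces, layout, height_px = 128, width_px = 128,
                           baseline = 1, background_amp = 0,
                           background_period_s = 60, fs = 20,
                           pixel_noise_sd = 0, seed = 1L) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  stopifnot(nrow(traces) == nrow(layout))
  n_t <- ncol(traces)
  mask <- matrix(0L, height_px, width_px)
  xg <- matrix(rep(seq_len(width_px), each = height_px), height_px)
  yg <- matrix(rep(seq_len(height_px), width_px), height_px)
  pix_idx <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    d2 <- (xg - layout$x[i])^2 + (yg - layout$y[i])^2
    idx <- which(d2 <= layout$radius_px[i]^2)
    if (any(mask[idx] != 0L)) abort("ROIs overlap in the requested layout")
    mask[idx] <- i
    pix_idx[[i]] <- idx
  }
  withr::with_seed(seed, {
    movie <- array(baseline, dim = c(height_px, width_px, n_t))
    if (background_amp > 0) {
      cx <- width_px * runif(1, 0.3, 0.7)
      cy <- height_px * runif(1, 0.3, 0.7)
      sig <- 0.4 * max(width_px, height_px)
      g <- exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * sig^2))
      drift <- 0.5 + 0.5 * sin(2 * pi * (seq_len(n_t) - 1) / (fs * background_period_s))
      for (t in seq_len(n_t)) {
        movie[, , t] <- movie[, , t] + background_amp * g * drift[t]
      }
    }
    m2 <- matrix(movie, height_px * width_px, n_t)
    for (i in seq_len(nrow(layout))) {
      m2[pix_idx[[i]], ] <- m2[pix_idx[[i]], , drop = FALSE] +
        matrix(traces[i, ], length(pix_idx[[i]]), n_t, byrow = TRUE)
    }
    if (pixel_noise_sd > 0) {
      m2 <- m2 + matrix(rnorm(length(m2), 0, pixel_noise_sd), nrow(m2))
    }
    movie <- array(m2, dim = c(height_px, width_px, n_t))
    list(movie = movie, mask = mask, layout = layout)
  })
}

#' Read and write movies and label masks as TIFF
#'
#' Movies are written as multi-page 32-bit float TIFF with intensities
#' rescaled to \[0, 1\] (the TIFF sample range); `write_movie_tiff()` returns
#' the affine calibration, and `read_movie_tiff()` can apply it to restore the
#' original units. The analysis pipeline is invariant to this rescaling: donut
#' subtraction removes per-frame offsets and preprocessing min-max normalizes
#' each trace. Label masks are written as 16-bit integer TIFF.
#'
#' @param movie height x width x time array.
#' @param mask integer label matrix (values 0..65535).
#' @param path file path.
#' @param offset,scale affine calibration (`intensity = stored * scale +
#'   offset`), as returned by `write_movie_tiff()`.
#' @return `write_movie_tiff()` invisibly returns `list(path, offset, scale)`;
#'   `read_movie_tiff()` a height x width x time array; `write_mask_tiff()`
#'   the path invisibly; `read_mask_tiff()` an integer label matrix.
#' @name tiff_io
NULL

#' @rdname tiff_io
#' @export
write_movie_tiff <- function(movie, path) {
  offset <- min(movie)
  scale <- max(movie) - offset
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(movie)[3]),
                  function(t) (movie[, , t] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(list(path = path, offset = offset, scale = scale))
}

#' @rdname tiff_io
#' @export
read_movie_tiff <- function(path, offset = 0, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages))) * scale + offset
}

#' @rdname tiff_io
#' @export
write_mask_tiff <- function(mask, path) {
  if (any(mask < 0 | mask > 65535)) abort("mask labels must fit in 16 bits")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}
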