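# Shared internal helpers. Time convention throughout the package: seconds,
# sample i (1-based) represents the half-open interval [(i-1)/fs, i/fs), so a
# window [a, b) at sampling rate fs covers samples floor(a*fs)+1 .. floor(b*fs).

window_samples <- function(a, b, fs, n_total = NULL) {
  i1 <- floor(a * fs + 1e-9) + 1L
  i2 <- floor(b * fs + 1e-9)
  if (!is.null(n_total) && (i1 < 1L || i2 > n_total)) {
    abort("window extends outside the recording")
  }
  if (i2 < i1) return(integer(0))
  seq.int(i1, i2)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used when reporting responder percentages (e.g. 162/861 ->
#' 18.82).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# moving mean with shrinking windows at the edges (MATLAB movmean behaviour)
moving_mean <- function(x, n) {
  if (n <= 1L) return(x)
  len <- length(x)
  half_l <- floor((n - 1) / 2)
  half_r <- n - 1L - half_l
  cs <- cumsum(c(0, x))
  i1 <- pmax(seq_len(len) - half_l, 1L)
  i2 <- pmin(seq_len(len) + half_r, len)
  (cs[i2 + 1L] - cs[i1]) / (i2 - i1 + 1L)
}

# normal truncated below at `lower`, by inverse-cdf sampling
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd <= 0) return(pmax(rep(mean, n), lower))
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# trailing sliding minimum: out[i] = min(x[max(1, i - w + 1) .. i]), O(n) via
# the block prefix/suffix-min decomposition
running_min_trailing <- function(x, w) {
  n <- length(x)
  if (w <= 1L) return(x)
  nb <- ceiling(n / w)
  xp <- c(x, rep(Inf, nb * w - n))
  m <- matrix(xp, nrow = w)
  pre <- as.vector(apply(m, 2, cummin))
  suf <- as.vector(apply(m[w:1, , drop = FALSE], 2, cummin)[w:1, , drop = FALSE])
  idx <- seq_len(n)
  j <- idx - w + 1L
  ifelse(j <= 0L, pre[idx], pmin(suf[pmax(j, 1L)], pre[idx]))
}
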