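# Independent oracles used to check the implementation, deliberately written
# as direct enumerations / closed forms, never sharing code with R/.

# Cliff's delta by full pair enumeration, O(n*m)
brute_cliffs_delta <- function(x, y) {
  cmp <- outer(x, y, function(a, b) sign(a - b))
  sum(cmp) / (length(x) * length(y))
}

# two-sided Fisher exact p by enumerating all tables with the observed margins
brute_fisher_p <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact distribution of the mean of n_windows iid draws from the finite set of
# 1 s window event densities (integer window sums 0..nw convolved n times)
brute_shuffle_p95 <- function(window_sums, n_windows, nw) {
  pmf <- tabulate(window_sums + 1L, nbins = nw + 1L) / length(window_sums)
  conv <- 1
  for (i in seq_len(n_windows)) conv <- convolve(conv, rev(pmf), type = "open")
  conv[conv < 0] <- 0
  support <- (seq_along(conv) - 1) / (n_windows * nw) # mean density
  cdf <- cumsum(conv) / sum(conv)
  support[which(cdf >= 0.95)[1]]
}

# mean of a normal truncated below at `lo`
truncnorm_mean <- function(mu, sigma, lo) {
  a <- (lo - mu) / sigma
  mu + sigma * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# Cliff's delta between two zero-truncated negative binomials, by pmf
# enumeration on a common support (delta on the nonzero values is invariant to
# the monotone log-normalization the pipeline applies)
ztnb_delta_oracle <- function(mu1, size1, mu2, size2, upper = 4000) {
  k <- 1:upper
  p1 <- stats::dnbinom(k, mu = mu1, size = size1)
  p1 <- p1 / sum(p1)
  p2 <- stats::dnbinom(k, mu = mu2, size = size2)
  p2 <- p2 / sum(p2)
  cdf2 <- cumsum(p2)
  p_gt <- sum(p1 * c(0, cdf2[-length(cdf2)])) # P(X > Y)
  p_lt <- sum(p1 * (1 - cdf2))                # P(X < Y)
  p_gt - p_lt
}

# Dunn's pairwise rank z statistic with tie correction, written directly
brute_dunn_z <- function(values, groups, g1, g2) {
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  m1 <- mean(r[groups == g1]); m2 <- mean(r[groups == g2])
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  (m1 - m2) / sqrt(n * (n + 1) / 12 * corr * (1 / n1 + 1 / n2))
}

# cache for objects shared between acceptance-criterion blocks (built once per
# test run)
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_get <- function(key, build) {
  if (!exists(key, envir = .acceptance_cache)) {
    assign(key, build(), envir = .acceptance_cache)
  }
  get(key, envir = .acceptance_cache)
}

# simple trace builder: isolated events at given times on a noisy baseline
make_trace <- function(duration_s, t0, rise, amp, tau = 0.7, fs = 20,
                       noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  y <- usprf:::render_events(n, fs, t0, rise, amp, tau)
  y + rnorm(n, 0, noise_sd)
}
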