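toy_train <- function(mask, fs = 20) {
  structure(list(mask = as.integer(mask), fs = fs, n = length(mask),
                 events = NULL, removed = FALSE), class = "event_train")
}

toy_trials <- function(onsets, prf = 10) {
  tibble::tibble(trial = seq_along(onsets), prf_hz = prf,
                 start_s = onsets - 10, onset_s = onsets, end_s = onsets + 10)
}

test_that("degenerate masks give degenerate shuffle distributions", {
  trials <- toy_trials(30)
  d0 <- shuffle_baseline(toy_train(integer(1200)), trials, n_windows = 20,
                         seed = 1)
  expect_true(all(d0$samples == 0))
  expect_equal(d0$p95, 0)
  d1 <- shuffle_baseline(toy_train(rep(1L, 1200)), trials, n_windows = 20,
                         seed = 1)
  expect_true(all(d1$samples == 1))
  expect_equal(d1$p95, 1)
})

test_that("shuffle windows avoid the 5 s post-onset exclusion zones", {
  # mask is 1 exactly inside [onset, onset+5): every valid window must have
  # density 0, whatever the seed
  mask <- integer(1200)
  mask[usprf:::window_samples(30, 35, 20)] <- 1L
  d <- shuffle_baseline(toy_train(mask), toy_trials(30), n_windows = 20,
                        seed = 42)
  expect_true(all(d$samples == 0))
})

test_that("shuffle p95 matches exhaustive enumeration on a 60 s toy trace", {
  set.seed(99)
  # stationary random mask: rising segments scattered through 60 s
  mask <- integer(1200)
  starts <- sample(1100, 12)
  for (s in starts) mask[s:(s + sample(8:25, 1))] <- 1L
  mask <- mask[1:1200]
  trials <- toy_trials(30)
  train <- toy_train(mask)
  d <- shuffle_baseline(train, trials, n_windows = 20, n_iter = 1000, seed = 3)

  # oracle: enumerate every valid window's sum, convolve the exact pmf
  nw <- 20L
  excluded <- logical(1200)
  excluded[usprf:::window_samples(30, 35, 20)] <- TRUE
  sums <- vapply(seq_len(1200 - nw + 1), function(s) {
    if (any(excluded[s:(s + nw - 1)])) return(NA_integer_)
    sum(mask[s:(s + nw - 1)])
  }, integer(1))
  sums <- sums[!is.na(sums)]
  p95_exact <- brute_shuffle_p95(sums, 20, nw)
  expect_lt(abs(d$p95 - p95_exact), 0.02)
})

test_that("modulation flags follow the p95 and pre-onset exclusion rules", {
  fs <- 20
  trials <- toy_trials(c(30, 90), prf = 10)
  # events only inside the stimulation windows
  m_us <- integer(2400)
  m_us[c(usprf:::window_samples(30, 30.6, fs),
         usprf:::window_samples(90, 90.6, fs))] <- 1L
  tr_us <- toy_train(m_us)
  d <- shuffle_baseline(tr_us, trials, n_windows = 20, seed = 5)
  r <- classify_modulation(tr_us, trials, 10, d)
  expect_true(r$modulated)
  expect_false(r$excluded_preus)
  expect_equal(r$observed_us_density, 0.6)

  # events only in the 1 s pre-onset windows: excluded, not modulated
  m_pre <- integer(2400)
  m_pre[c(usprf:::window_samples(29, 30, fs),
          usprf:::window_samples(89, 90, fs))] <- 1L
  tr_pre <- toy_train(m_pre)
  d2 <- shuffle_baseline(tr_pre, trials, n_windows = 20, seed = 5)
  r2 <- classify_modulation(tr_pre, trials, 10, d2)
  expect_true(r2$excluded_preus)
  expect_false(r2$modulated)
  expect_error(classify_modulation(tr_us, trials, 40, d), "no trials")
})

test_that("response significance is (observed - p95) / p95 with sentinels", {
  expect_equal(response_significance(0.2, 0.2), 0)
  expect_equal(response_significance(0.4, 0.2), 1)
  expect_equal(response_significance(0.3, 0.2), 0.5)
  expect_equal(response_significance(0.3, 0), Inf)
  expect_equal(response_significance(0, 0), 0)
  expect_error(response_significance(-0.1, 0.2), "non-negative")
})

test_that("specificity classes follow the flag combinations", {
  mod <- tibble::tibble(
    neuron = rep(1:3, each = 3),
    prf_hz = rep(c(10, 40, 140), 3),
    modulated = c(TRUE, FALSE, FALSE,  TRUE, TRUE, FALSE,  FALSE, FALSE, FALSE)
  )
  cls <- classify_specificity(mod)
  expect_equal(cls$class, c("specific", "non_specific", "non_responder"))
  expect_equal(cls$prfs_modulated[[1]], 10)
  expect_equal(cls$prfs_modulated[[2]], c(10, 40))
})

test_that("proportion_report reproduces printed percentage arithmetic", {
  expect_equal(proportion_report(tibble::tibble(n_modulated = 162,
                                                n_total = 861))$percent, 18.82)
  expect_equal(proportion_report(tibble::tibble(n_modulated = 0,
                                                n_total = 100))$percent, 0)
  df <- tibble::tibble(prf_hz = rep(c(10, 40), c(4, 4)),
                       modulated = c(TRUE, TRUE, FALSE, FALSE,
                                     TRUE, FALSE, FALSE, FALSE))
  rep2 <- proportion_report(df, prf_hz)
  expect_equal(rep2$n_modulated, c(2, 1))
  expect_equal(rep2$percent, c(50, 25))
  expect_error(proportion_report(df[0, ]), "empty")
})

test_that("shuffle draws are reproducible by seed and support no-replacement", {
  mask <- integer(1200); mask[100:140] <- 1L
  trials <- toy_trials(30)
  train <- toy_train(mask)
  d1 <- shuffle_baseline(train, trials, n_windows = 10, seed = 7)
  d2 <- shuffle_baseline(train, trials, n_windows = 10, seed = 7)
  d3 <- shuffle_baseline(train, trials, n_windows = 10, seed = 8)
  expect_identical(d1$samples, d2$samples)
  expect_false(identical(d1$samples, d3$samples))
  d4 <- shuffle_baseline(train, trials, n_windows = 10, seed = 7,
                         replace = FALSE)
  expect_equal(length(d4$samples), 1000)
})
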