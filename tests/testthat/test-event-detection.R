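test_that("dpss tapers match the scipy.signal reference (up to sign)", {
  # frozen reference: scipy.signal.windows.dpss(20, 2, 3, norm=2)
  ref1 <- c(0.012598, 0.031894, 0.061768, 0.102372, 0.151951, 0.206785,
            0.261562, 0.310136, 0.346540, 0.366047, 0.366047, 0.346540,
            0.310136, 0.261562, 0.206785, 0.151951, 0.102372, 0.061768,
            0.031894, 0.012598)
  ref2 <- c(0.060091, 0.117039, 0.183280, 0.248077, 0.298438, 0.321867,
            0.309329, 0.257687, 0.170942, 0.059878, -0.059878, -0.170942,
            -0.257687, -0.309329, -0.321867, -0.298438, -0.248077, -0.183280,
            -0.117039, -0.060091)
  ref3 <- c(0.179854, 0.259107, 0.311710, 0.320638, 0.277844, 0.187441,
            0.065743, -0.062069, -0.167893, -0.227705, -0.227705, -0.167893,
            -0.062069, 0.065743, 0.187441, 0.277844, 0.320638, 0.311710,
            0.259107, 0.179854)
  tap <- dpss_tapers(20, 2, 3)
  expect_equal(abs(tap[, 1]), abs(ref1), tolerance = 1e-5)
  expect_equal(abs(tap[, 2]), abs(ref2), tolerance = 1e-5)
  expect_equal(abs(tap[, 3]), abs(ref3), tolerance = 1e-5)
  expect_equal(colSums(tap^2), rep(1, 3))
  expect_equal(max(abs(crossprod(tap) - diag(3))), 0, tolerance = 1e-10)
})

test_that("flat noise yields no events over 1000 s", {
  set.seed(7)
  x <- rnorm(20000, 0, 0.1)
  tr <- detect_events(x, 20)
  expect_equal(nrow(tr$events), 0)
  expect_true(tr$removed)
  expect_equal(sum(tr$mask), 0)
})

test_that("a single constructed transient is found with its rise time", {
  x <- make_trace(60, t0 = 30, rise = 0.5, amp = 1, noise_sd = 0.1, seed = 4)
  tr <- detect_events(x, 20)
  expect_equal(nrow(tr$events), 1)
  expect_lt(abs(tr$events$rise_time_s - 0.5), 0.1)
  expect_lt(abs(tr$events$peak_s - 30.5), 0.2)
  expect_gt(tr$events$amplitude, 2.5 * tr$events$pre_event_sd)
  # the rising mask covers exactly [rise start, peak]
  idx <- which(tr$mask == 1)
  expect_equal((min(idx) - 1) / 20, tr$events$rise_start_s)
  expect_equal((max(idx) - 1) / 20, tr$events$peak_s)
})

test_that("the minimum rise-time rule is strict and filters events", {
  x <- make_trace(120, c(20, 50, 90), c(0.4, 0.8, 1.5), c(1, 1, 1),
                  noise_sd = 0.1, seed = 2)
  # default threshold keeps all three; every reported rise obeys the rule
  ev <- detect_events(x, 20)$events
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$rise_time_s > 0.1))
  # raising the threshold: every surviving event obeys it strictly
  ev2 <- detect_events(x, 20, detection_params(min_rise_s = 1))$events
  expect_true(all(ev2$rise_time_s > 1))
})

test_that("detection is invariant to positive rescaling of the trace", {
  x <- make_trace(120, c(20, 50, 90), c(0.8, 1.2, 0.5), c(1, 0.7, 1.3),
                  noise_sd = 0.1, seed = 8)
  tr1 <- detect_events(x, 20)
  tr2 <- detect_events(7.3 * x, 20)
  expect_equal(tr1$events$rise_start_s, tr2$events$rise_start_s)
  expect_equal(tr1$events$peak_s, tr2$events$peak_s)
  expect_equal(tr2$events$amplitude, 7.3 * tr1$events$amplitude)
  expect_identical(tr1$mask, tr2$mask)
})

test_that("sensitivity >= 0.90 and FDR <= 0.10 at 5x noise amplitude", {
  set.seed(11)
  fs <- 20
  n_ev <- 520
  t0 <- 8 + (0:(n_ev - 1)) * 9 + runif(n_ev)
  rise <- runif(n_ev, 0.3, 2)
  x <- make_trace(max(t0) + 10, t0, rise, rep(0.5, n_ev), noise_sd = 0.1,
                  seed = 12)
  tr <- detect_events(x, fs)
  tpk <- t0 + rise
  hits <- vapply(tpk, function(p) any(abs(tr$events$peak_s - p) < 0.6),
                 logical(1))
  fp <- sum(vapply(tr$events$peak_s, function(p) all(abs(tpk - p) >= 0.6),
                   logical(1)))
  expect_gte(mean(hits), 0.90)
  expect_lte(fp / nrow(tr$events), 0.10)
})

test_that("event trains keep their bookkeeping invariants", {
  x <- make_trace(200, c(20, 21.4, 60, 130), c(1, 0.9, 1.2, 0.6),
                  c(1, 1.1, 0.8, 1), noise_sd = 0.1, seed = 3)
  tr <- detect_events(x, 20)
  ev <- tr$events
  expect_true(all(ev$rise_time_s > 0.1))
  expect_true(all(ev$amplitude > 2.5 * ev$pre_event_sd))
  expect_true(all(ev$rise_start_s < ev$peak_s))
  # non-nested, time ordered
  expect_true(all(diff(ev$rise_start_s) > 0))
  expect_true(all(utils::head(ev$peak_s, -1) <= utils::tail(ev$rise_start_s, -1)))
  # mask support equals the union of rise intervals
  mask2 <- integer(tr$n)
  for (k in seq_len(nrow(ev))) {
    mask2[(ev$rise_start_s[k] * 20 + 1):(ev$peak_s[k] * 20 + 1)] <- 1L
  }
  expect_identical(tr$mask, mask2)
})

test_that("event_rate counts peaks per minute over windows", {
  x <- make_trace(120, c(10, 30, 50), c(0.8, 0.8, 0.8), c(1, 1, 1),
                  noise_sd = 0.05, seed = 5)
  tr <- detect_events(x, 20)
  expect_equal(nrow(tr$events), 3)
  w60 <- tibble::tibble(start_s = 0, end_s = 60)
  expect_equal(event_rate(tr, w60), 3)
  w_none <- tibble::tibble(start_s = 100, end_s = 120)
  expect_equal(event_rate(tr, w_none), 0)
  expect_error(event_rate(tr, w60[0, ]), "empty")
  expect_error(event_rate(tr, tibble::tibble(start_s = 0, end_s = 500)),
               "outside")
})

test_that("event_density is the rising-mask mean over the window", {
  tr <- structure(list(mask = c(rep(0L, 10), rep(1L, 10), rep(0L, 20)),
                       fs = 20, n = 40), class = "event_train")
  expect_equal(event_density(tr, c(0.5, 1)), 1)
  expect_equal(event_density(tr, c(1.5, 2)), 0)
  expect_equal(event_density(tr, c(0.25, 1.25)), 0.5)
  expect_error(event_density(tr, c(1, 3)), "outside")
})

test_that("neurons with zero events are flagged as removed", {
  set.seed(20)
  traces <- rbind(make_trace(60, 30, 1, 1, seed = 21),
                  rnorm(1200, 0, 0.1))
  det <- detect_events_matrix(traces, 20)
  expect_equal(det$removed, c(FALSE, TRUE))
  expect_equal(unique(det$events$neuron), 1L)
})
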