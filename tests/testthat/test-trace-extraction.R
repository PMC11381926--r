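# small geometric fixture: one 2x2-ish square ROI in a 12x12 frame, donut
# radii chosen for the small frame
square_mask <- function(h = 12, w = 12, rows = 6:7, cols = 6:7) {
  m <- matrix(0L, h, w)
  m[rows, cols] <- 1L
  m
}

test_that("raw trace is ROI mean minus donut mean", {
  mask <- square_mask()
  movie <- array(4, dim = c(12, 12, 3))   # donut pixels = 4
  movie[rep(mask == 1L, 3)] <- 10         # ROI pixels = 10
  ex <- extract_traces(movie, mask, inner_px = 2, outer_px = 5)
  expect_equal(unname(ex$traces[1, ]), rep(6, 3))
})

test_that("uniform frames extract to zero and per-frame offsets cancel", {
  mask <- square_mask()
  movie <- array(rep(c(3, 7, 11), each = 144), dim = c(12, 12, 3))
  ex <- extract_traces(movie, mask, inner_px = 2, outer_px = 5)
  expect_equal(unname(ex$traces[1, ]), rep(0, 3))
  # adding any per-frame uniform offset leaves traces unchanged
  movie2 <- array(rnorm(12 * 12 * 5, 5), dim = c(12, 12, 5))
  off <- c(0, 10, -3, 100, 2)
  movie3 <- movie2 + rep(off, each = 144)
  ex2 <- extract_traces(movie2, mask, inner_px = 2, outer_px = 5)
  ex3 <- extract_traces(movie3, mask, inner_px = 2, outer_px = 5)
  expect_equal(ex2$traces, ex3$traces)
})

test_that("a neighbouring ROI's pixels never enter the donut", {
  h <- 24; w <- 24
  mask <- matrix(0L, h, w)
  mask[11:13, 11:13] <- 1L
  mask[11:13, 16:18] <- 2L   # neighbour inside ROI 1's annulus
  base <- array(1, dim = c(h, w, 2))
  bright <- base
  bright[cbind(rep(11:13, 2 * 3), rep(rep(16:18, each = 3), 2),
               rep(1:2, each = 9))] <- 50
  ex_dim <- extract_traces(base, mask, inner_px = 2, outer_px = 8)
  ex_bri <- extract_traces(bright, mask, inner_px = 2, outer_px = 8)
  expect_equal(ex_dim$traces[1, ], ex_bri$traces[1, ])
})

test_that("an ROI with an empty donut is flagged and skipped with a warning", {
  mask <- square_mask(8, 8, 4:5, 4:5)
  movie <- array(1, dim = c(8, 8, 2))
  # no background pixel falls in the (1.7, 2] annulus around this square ROI
  expect_warning(ex <- extract_traces(movie, mask, inner_px = 1.7, outer_px = 2),
                 "empty donut")
  expect_true(ex$info$flagged[1])
  expect_true(all(is.na(ex$traces[1, ])))
})

test_that("preprocessing is the fixed 4-step pipeline", {
  fs <- 20
  cfg <- session_config("single_prf", n_trials = 3, post_s = 9, pause_s = 0.5,
                        n_neurons = 2, seed = 9)
  ses <- simulate_session(cfg)
  raw <- ses$traces * 3 + 40 + 0.01 * seq_len(ncol(ses$traces)) # gain/offset/bleach
  pp <- preprocess_traces(raw, ses$trials, fs_in = fs, fs = fs)
  expect_equal(nrow(pp$traces), 2)
  # per-trial 10 s pre-onset means are exactly zero
  for (tr in seq_len(nrow(ses$trials))) {
    idx <- usprf:::window_samples(ses$trials$onset_s[tr] - 10,
                                  ses$trials$onset_s[tr], fs)
    expect_lt(max(abs(rowMeans(pp$traces[, idx]))), 1e-9)
  }
  # range property after min-max then baseline shift
  expect_true(all(pp$traces >= -1 - 1e-12 & pp$traces <= 1 + 1e-12))
})

test_that("on-grid interpolation is the identity and ramps are dropped", {
  fs <- 20
  trials <- tibble::tibble(trial = 1, prf_hz = 10, start_s = 0, onset_s = 10,
                           end_s = 20)
  t_grid <- seq(0, 20 - 1 / fs, by = 1 / fs)
  y <- sin(t_grid)
  pp <- preprocess_traces(y, trials, timestamps = t_grid, fs = fs)
  # pchip on its own nodes is the identity, so the output equals steps 2-4
  # applied to the raw samples directly
  r <- stats::residuals(stats::lm(y ~ t_grid))
  r <- (r - min(r)) / (max(r) - min(r))
  expected <- r - mean(r[t_grid >= 0 & t_grid < 10])
  expect_equal(unname(pp$traces[1, ]), unname(expected), tolerance = 1e-9)

  # a pure linear ramp detrends to a constant -> zero range -> dropped
  ramp <- 0.5 * t_grid + 2
  pp2 <- preprocess_traces(ramp, trials, timestamps = t_grid, fs = fs)
  expect_equal(nrow(pp2$traces), 0)
  expect_equal(pp2$dropped$reason, "constant trace")
})

test_that("off-grid timestamps are interpolated onto the 20 Hz grid", {
  trials <- tibble::tibble(trial = 1, prf_hz = 10, start_s = 0, onset_s = 10,
                           end_s = 20)
  ts <- sort(c(seq(0, 20, by = 0.11), 19.99))
  y <- cos(ts / 2) + 0.1 * ts
  pp <- preprocess_traces(y, trials, timestamps = ts, fs = 20)
  expect_equal(ncol(pp$traces), length(seq(0, max(ts), by = 0.05)))
  expect_false(anyNA(pp$traces))
})

test_that("PV matching uses strict >50% overlap of the GCaMP ROI", {
  g <- matrix(0L, 20, 20)
  g[5:8, 5:9] <- 1L           # 20 px ROI
  # identical mask -> overlap 1 -> PV
  expect_true(match_pv(g, g)$pv)
  # disjoint -> 0 -> non-PV
  t0 <- matrix(0L, 20, 20); t0[15:18, 15:18] <- 1L
  expect_false(match_pv(g, t0)$pv)
  # constructed 60% (12 of 20 px) -> PV
  t60 <- matrix(0L, 20, 20); t60[5:8, 5:7] <- 1L
  res60 <- match_pv(g, t60)
  expect_equal(res60$overlap, 0.6)
  expect_true(res60$pv)
  # exactly 50% (10 of 20 px) -> non-PV (strict inequality)
  t50 <- matrix(0L, 20, 20); t50[5:8, 5:6] <- 1L; t50[5:6, 7] <- 1L
  res50 <- match_pv(g, t50)
  expect_equal(res50$overlap, 0.5)
  expect_false(res50$pv)
})

test_that("PV matching applies the supplied transform and rejects degenerate ones", {
  g <- matrix(0L, 20, 20); g[9:12, 9:12] <- 1L
  # tdT mask shifted by +3 columns; transform maps gcamp (x,y) -> tdt (x+3,y)
  t1 <- matrix(0L, 20, 20); t1[9:12, 12:15] <- 1L
  shift <- matrix(c(1, 0, 0, 0, 1, 0, 3, 0, 1), 3, 3)
  expect_true(match_pv(g, t1, transform = shift)$pv)
  expect_false(match_pv(g, t1)$pv)
  expect_error(match_pv(g, t1, transform = matrix(0, 3, 3)), "degenerate")
})
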