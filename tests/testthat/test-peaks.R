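test_that("sliding means enumerate every window wholly inside the range", {
  times <- epoch_time_grid(-100, 1000, 100)
  w <- boxcar_wave(times, 400, 500, 6)
  w$values[] <- 4
  sm <- sliding_means(w, 100, c(300, 1000))
  # every window [start, start+100) with start on the 10 ms grid and
  # start + 100 <= 1000: starts 300, 310, ..., 900
  expect_equal(sm$start_ms, seq(300, 900, by = 10))
  expect_equal(sm$mean_uv, rep(4, nrow(sm)))

  # boxcar: unique maximal mean at its onset
  wb <- boxcar_wave(times, 400, 500, 6)
  smb <- sliding_means(wb, 100, c(300, 1000))
  expect_equal(smb$start_ms[which.max(smb$mean_uv)], 400)
  expect_equal(max(smb$mean_uv), 6)

  expect_error(sliding_means(wb, 100, c(950, 1000)), "no full inner window")
})

test_that("peak-to-peak matches its frozen constructions", {
  times <- epoch_time_grid(-100, 1000, 100)
  # +6 boxcar then -4 boxcar, P3b preset: p2p = 10
  v <- numeric(length(times))
  v[times >= 400 & times < 500] <- 6
  v[times >= 700 & times < 800] <- -4
  r <- peak_to_peak(waveform("Pz", times, v), peak_preset("p3b"))
  expect_equal(r[c("high_value", "high_start", "low_value", "low_start", "p2p")],
               list(high_value = 6, high_start = 400, low_value = -4,
                    low_start = 700, p2p = 10))
  expect_false(r$degenerate)

  # all-zero wave
  expect_equal(peak_to_peak(waveform("Pz", times, numeric(length(times))),
                            peak_preset("p3b"))$p2p, 0)

  # capped highest-peak search makes a negative p2p possible: the high peak
  # must end by 300 ms, so the best available "high" is -0.5 at 200 ms and
  # the following minimum is the zero baseline
  v2 <- numeric(length(times))
  v2[times >= 150 & times < 250] <- -1
  v2[times >= 400 & times < 500] <- 5
  r2 <- peak_to_peak(waveform("Fz", times, v2), peak_preset("p3a"))
  expect_equal(r2$high_value, -0.5)
  expect_equal(r2$high_start, 200)
  expect_equal(r2$low_value, 0)
  expect_equal(r2$p2p, -0.5)
})

test_that("degenerate low search yields p2p = 0 with a flag, not an error", {
  times <- epoch_time_grid(0, 500, 100)
  v <- numeric(length(times)); v[times >= 380 & times < 480] <- 3
  # bounding window 300-500, inner 100: high lands at 380, no room after
  r <- peak_to_peak(waveform("Cz", times, v), peak_params(300, 500, 100))
  expect_true(r$degenerate)
  expect_equal(r$p2p, 0)
  expect_true(is.na(r$low_start))
})

test_that("peak-to-peak is offset-invariant and positively homogeneous", {
  set.seed(31)
  times <- epoch_time_grid(-100, 1000, 250)
  for (pre in c("p3a", "p3b")) {
    p <- peak_preset(pre)
    for (i in 1:25) {
      w <- waveform("Fz", times, rnorm(length(times), sd = 5))
      r <- peak_to_peak(w, p)$p2p
      wc <- w; wc$values <- w$values + runif(1, -20, 20)
      expect_equal(peak_to_peak(wc, p)$p2p, r)
      a <- runif(1, 0.1, 4)
      ws <- w; ws$values <- a * w$values
      expect_equal(peak_to_peak(ws, p)$p2p, a * r)
    }
  }
})

test_that("peak statistics agree with the exhaustive-scan oracle on 500 waves", {
  set.seed(77)
  times <- epoch_time_grid(-100, 1000, 100)
  lat_p3a <- peak_preset("p3a-latency")
  lat_p3b <- peak_preset("p3b-latency")
  n_neg_p3a <- 0
  for (i in 1:500) {
    w <- waveform("Fz", times, rnorm(length(times), sd = 8))
    # p3b: no cap; sign must be non-negative for non-degenerate outputs
    rb <- peak_to_peak(w, peak_preset("p3b"))
    ob <- p2p_oracle(w$values, times, 300, 1000, 100)
    expect_identical(rb$degenerate, ob$degenerate)
    expect_equal(rb$p2p, ob$p2p)
    if (!rb$degenerate) expect_gte(rb$p2p, 0)
    # p3a: capped high search; can be negative
    ra <- peak_to_peak(w, peak_preset("p3a"))
    oa <- p2p_oracle(w$values, times, 150, 1000, 100, high_limit = 300)
    expect_equal(ra$p2p, oa$p2p)
    if (ra$p2p < 0) n_neg_p3a <- n_neg_p3a + 1
    # latency against brute-force argmax
    expect_equal(latency(w, lat_p3a),
                 latency_oracle(w$values, times, 150, 400, 50))
    expect_equal(latency(w, lat_p3b),
                 latency_oracle(w$values, times, 300, 1000, 100))
  }
  # the capped statistic does go negative on random noise now and then
  expect_gt(n_neg_p3a, 0)
})

test_that("latency ties break to the earliest start", {
  times <- epoch_time_grid(-100, 1000, 100)
  w <- boxcar_wave(times, 400, 500, 5)
  expect_equal(latency(w, peak_preset("p3b-latency")), 400)
  flat <- waveform("Pz", times, rep(1, length(times)))
  expect_equal(latency(flat, peak_preset("p3b-latency")), 300)
  expect_equal(latency(flat, peak_preset("p3a-latency")), 150)
})

test_that("vectorised and scalar peak statistics agree row by row", {
  set.seed(55)
  times <- epoch_time_grid(-100, 1000, 250)
  M <- matrix(rnorm(40 * length(times), sd = 6), 40)
  for (pre in c("p3a", "p3b")) {
    p <- peak_preset(pre)
    scalar <- apply(M, 1, function(v)
      peak_to_peak(waveform("x", times, v), p)$p2p)
    expect_equal(citerp:::peak_to_peak_matrix(M, times, p), scalar)
  }
  lp <- peak_preset("p3b-latency")
  scalar_lat <- apply(M, 1, function(v) latency(waveform("x", times, v), lp))
  expect_equal(citerp:::latency_matrix(M, times, lp), scalar_lat)
})

test_that("parameter validation rejects impossible windows", {
  expect_error(peak_params(500, 300, 100))
  expect_error(peak_params(300, 1000, 800))
  expect_error(peak_params(300, 1000, 100, high_limit = 200))
  expect_error(peak_preset("nope"), "unknown preset")
})
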