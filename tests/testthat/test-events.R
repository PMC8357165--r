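# Slow-oscillation and spindle detection, co-occurrence matching, timing.

rate <- 100
tgrid <- seq(0, 30 - 1 / rate, by = 1 / rate)

# baseline with unit candidate peak-to-peak: 1 Hz sine of amplitude 1/2
baseline_sine <- baseline_stats((1 / 2) * sin(2 * pi * tgrid), rate)

test_that("zero-phase bandpass preserves in-band tones and rejects out-of-band", {
  x1 <- sin(2 * pi * 1 * tgrid)
  y1 <- zero_phase_bandpass(x1, c(0.5, 1.25), rate)
  mid <- tgrid > 10 & tgrid < 20
  expect_equal(stats::sd(y1[mid]) / stats::sd(x1[mid]), 1, tolerance = 0.05)
  x5 <- sin(2 * pi * 5 * tgrid)
  y5 <- zero_phase_bandpass(x5, c(0.5, 1.25), rate)
  expect_lt(stats::sd(y5[mid]) / stats::sd(x5[mid]), 10^(-30 / 20))
  # symmetric pulse keeps its peak sample (zero net phase)
  g <- exp(-((tgrid - 15)^2) / (2 * 0.5^2))
  expect_equal(which.max(zero_phase_bandpass(g, c(0.5, 1.25), rate)),
               which.max(g))
  expect_error(zero_phase_bandpass(x1, c(0, 1), rate), "band")
})

test_that("slow oscillations are detected from amplitude-gated candidates", {
  x <- numeric(length(tgrid))
  seg <- tgrid >= 10 & tgrid < 13
  x[seg] <- 2 * sin(2 * pi * 1 * (tgrid[seg] - 10))
  so <- detect_slow_oscillations(x, baseline_sine, rate)
  expect_equal(nrow(so), 2)
  expect_true(all(so$t_end - so$t_start >= 0.8 & so$t_end - so$t_start <= 2))
  # down peaks at the sinusoid minima (10.75, 11.75), within filter shift
  expect_equal(so$down_peak_time, c(10.75, 11.75), tolerance = 0.1)
  expect_true(all(so$down_peak_value < -1e-6))
  expect_gt(min(so$peak_to_peak), 1.25 * baseline_sine$so_p2p_mean)
  # the same envelope at 3 Hz leaves nothing in the band
  x3 <- numeric(length(tgrid))
  x3[seg] <- 2 * sin(2 * pi * 3 * (tgrid[seg] - 10))
  expect_equal(nrow(detect_slow_oscillations(x3, baseline_sine, rate)), 0)
  expect_equal(nrow(detect_slow_oscillations(numeric(3000), baseline_sine,
                                             rate)), 0)
  expect_error(detect_slow_oscillations(x[1:400], baseline_sine, rate),
               "shorter")
})

test_that("spindle bursts are detected with centred timing and duration gating", {
  withr::with_seed(9, b <- stats::rnorm(3000))
  bl <- baseline_stats(b, rate)
  withr::with_seed(10, x <- stats::rnorm(3000))
  burst <- tgrid >= 15 & tgrid < 16
  x[burst] <- x[burst] + 5 * sin(2 * pi * 12 * (tgrid[burst] - 15))
  sp <- detect_spindles(x, bl, rate)
  strong <- sp[sp$peak_rms > 2, ]
  expect_equal(nrow(strong), 1)
  expect_equal(strong$center_time, 15.5, tolerance = 0.2)
  expect_gte(strong$t_end - strong$t_start, 0.5)
  # near-threshold bursts: the RMS and Hamming windows widen the
  # suprathreshold span by roughly their combined length, so at moderate
  # amplitude a 0.2 s burst stays under the 0.5 s floor while 1 s passes
  burst_events <- function(D) {
    withr::with_seed(10, x2 <- stats::rnorm(3000))
    bseg <- tgrid >= 15 & tgrid < 15 + D
    x2[bseg] <- x2[bseg] + 2 * sin(2 * pi * 12 * (tgrid[bseg] - 15))
    sp2 <- detect_spindles(x2, bl, rate)
    nrow(sp2[sp2$t_start < 15 + D + 0.3 & sp2$t_end > 14.7, ])
  }
  expect_equal(burst_events(0.2), 0)
  expect_equal(burst_events(1.0), 1)
  expect_equal(nrow(detect_spindles(numeric(3000), bl, rate)), 0)
})

test_that("raising either detection threshold never increases event counts", {
  x <- numeric(length(tgrid))
  seg <- tgrid >= 8 & tgrid < 14
  x[seg] <- 1.5 * sin(2 * pi * 1 * (tgrid[seg] - 8))
  n_so <- vapply(c(1, 1.25, 2, 3), function(k)
    nrow(detect_slow_oscillations(x, baseline_sine, rate, p2p_factor = k)),
    numeric(1))
  expect_true(all(diff(n_so) <= 0))
  withr::with_seed(9, b <- stats::rnorm(3000))
  bl <- baseline_stats(b, rate)
  withr::with_seed(12, xs <- stats::rnorm(3000))
  burst <- tgrid >= 15 & tgrid < 16
  xs[burst] <- xs[burst] + 4 * sin(2 * pi * 12 * (tgrid[burst] - 15))
  n_sp <- vapply(c(0.5, 1.25, 3, 8), function(k)
    nrow(detect_spindles(xs, bl, rate, threshold_factor = k)), numeric(1))
  expect_true(all(diff(n_sp) <= 0))
})

test_that("detected landmarks are equivariant under time shifts", {
  x <- numeric(length(tgrid))
  seg <- tgrid >= 10 & tgrid < 13
  x[seg] <- 2 * sin(2 * pi * 1 * (tgrid[seg] - 10))
  so <- detect_slow_oscillations(x, baseline_sine, rate)
  shift <- 150  # 1.5 s
  xs <- c(numeric(shift), x[1:(length(x) - shift)])
  sos <- detect_slow_oscillations(xs, baseline_sine, rate)
  expect_equal(nrow(sos), nrow(so))
  expect_equal(sos$down_peak_time, so$down_peak_time + shift / rate,
               tolerance = 1 / rate)
  expect_equal(sos$t_start, so$t_start + shift / rate, tolerance = 1 / rate)
})

test_that("co-occurrence matching enforces overlap, uniqueness and best-overlap", {
  so1 <- tibble::tibble(kind = "SO", t_start = 10.0, t_end = 11.2,
                        down_peak_time = 10.5, down_peak_value = -1,
                        peak_to_peak = 2)
  sp1 <- tibble::tibble(kind = "SP", t_start = 10.5, t_end = 11.3,
                        center_time = 10.9, peak_rms = 3)
  m <- match_cooccurrences(so1, sp1)
  expect_equal(nrow(m), 1)
  expect_equal(m$overlap, 0.7)
  expect_equal(m$delay, 10.9 - 10.5)
  # 0.2 s overlap is below the threshold
  sp2 <- dplyr::mutate(sp1, t_start = 11.0, t_end = 11.6, center_time = 11.3)
  expect_equal(nrow(match_cooccurrences(so1, sp2)), 0)
  # one spindle overlapping two slow oscillations pairs with the larger overlap
  so2 <- tibble::tibble(kind = "SO", t_start = c(10.0, 11.3),
                        t_end = c(11.2, 12.6),
                        down_peak_time = c(10.5, 11.9),
                        down_peak_value = -1, peak_to_peak = 2)
  sp3 <- tibble::tibble(kind = "SP", t_start = 10.9, t_end = 11.7,
                        center_time = 11.3, peak_rms = 3)
  # overlaps: 0.3 s with the first, 0.4 s with the second
  m3 <- match_cooccurrences(so2, sp3)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$so_index, 2)
  expect_equal(m3$overlap, 0.4, tolerance = 1e-9)
})

test_that("greedy matching agrees with a brute-force oracle on random event sets", {
  brute_force <- function(so, sp, min_overlap = 0.25) {
    used_so <- rep(FALSE, nrow(so)); n <- 0
    for (j in order(sp$t_start)) {
      best <- 0; best_ov <- -Inf
      for (i in seq_len(nrow(so))) {
        if (used_so[i]) next
        ov <- min(so$t_end[i], sp$t_end[j]) - max(so$t_start[i], sp$t_start[j])
        if (ov > best_ov) { best_ov <- ov; best <- i }
      }
      if (best > 0 && best_ov >= min_overlap) { used_so[best] <- TRUE; n <- n + 1 }
    }
    n
  }
  for (seed in 1:20) {
    withr::with_seed(seed, {
      ns <- sample(0:8, 2, replace = TRUE)
      so <- tibble::tibble(t_start = sort(stats::runif(ns[1], 0, 50)))
      so$t_end <- so$t_start + stats::runif(ns[1], 0.8, 2)
      so$down_peak_time <- (so$t_start + so$t_end) / 2
      sp <- tibble::tibble(t_start = sort(stats::runif(ns[2], 0, 50)))
      sp$t_end <- sp$t_start + stats::runif(ns[2], 0.5, 2)
      sp$center_time <- (sp$t_start + sp$t_end) / 2
    })
    m <- match_cooccurrences(so, sp)
    expect_equal(nrow(m), brute_force(so, sp))
    expect_lte(nrow(m), min(nrow(so), nrow(sp)))
    expect_true(!anyDuplicated(m$sp_index) && !anyDuplicated(m$so_index))
    if (nrow(m)) expect_true(all(m$overlap >= 0.25))
  }
})

test_that("spindle timing delays and histogram follow the matches", {
  so <- tibble::tibble(kind = "SO", t_start = c(10, 20), t_end = c(11.2, 21.2),
                       down_peak_time = c(10.4, 20.4), down_peak_value = -1,
                       peak_to_peak = 2)
  sp <- tibble::tibble(kind = "SP", t_start = c(10.1, 20.5),
                       t_end = c(10.7, 21.3),
                       center_time = c(10.4, 20.9), peak_rms = 3)
  m <- match_cooccurrences(so, sp)
  tm <- spindle_timing(m)
  expect_equal(length(tm$delays), nrow(m))
  expect_equal(sort(tm$delays), c(0, 0.5))
  expect_equal(sum(tm$histogram$count), 2)
  # bins are left-closed, so the delays 0 and 0.5 land at mid-points
  # 0.05 and 0.55
  expect_equal(sum(tm$histogram$count * tm$histogram$bin_mid), 0.60)
  empty <- spindle_timing(match_cooccurrences(so[0, ], sp[0, ]))
  expect_equal(sum(empty$histogram$count), 0)
})
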