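# events every `step` seconds with power from a supplied function of onset time
make_power_events <- function(duration_s, power_fn, step = 12,
                              channel = "C4") {
  onsets <- seq(6, duration_s - 6, by = step)
  data.frame(channel = channel, onset_s = onsets, offset_s = onsets + 1.5,
             duration_s = 1.5, normalised_power_uv2 = power_fn(onsets))
}

test_that("constant burst power gives a constant series; interior gaps interpolate", {
  ev <- make_power_events(3600, function(t) rep(5, length(t)))
  ser <- build_power_series(ev, 60, "C4", duration_s = 3600)
  expect_true(all(ser$values == 5))
  expect_false(any(ser$interpolated))

  # one empty interior bin between bins worth 2 and 4 -> interpolated 3
  ev2 <- data.frame(channel = "C4", onset_s = c(10, 30, 130, 150),
                    offset_s = c(11, 31, 131, 151), duration_s = 1,
                    normalised_power_uv2 = c(2, 2, 4, 4))
  ser2 <- build_power_series(ev2, 60, "C4", duration_s = 180)
  expect_identical(ser2$values[2], 3)
  expect_true(ser2$interpolated[2])

  expect_error(build_power_series(ev2[1, ], 60, "C4"), "at least 2")
})

test_that("a planted 1.7-h modulation is recovered within one spectral bin", {
  T_s <- 1.7 * 3600
  ev <- make_power_events(8 * 3600,
                          function(t) 10 * (1 + 0.5 * sin(2 * pi * t / T_s)))
  ser <- build_power_series(ev, 60, "C4", duration_s = 8 * 3600)
  # binned series tracks the modulator
  modulator <- 1 + 0.5 * sin(2 * pi * (ser$times_h * 3600) / T_s)
  expect_gt(cor(ser$values, modulator), 0.8)
  est <- estimate_cycle(ser)
  bin_h <- 8 / 4 - 8 / 5  # spacing between candidate periods near 1.7 h
  expect_lt(abs(est$period_h - 1.7), bin_h + 1e-9)
  expect_true(est$reliable)
})

test_that("recordings under 4.5 h are flagged unreliable", {
  T_s <- 1.7 * 3600
  ev <- make_power_events(4 * 3600,
                          function(t) 10 * (1 + 0.5 * sin(2 * pi * t / T_s)))
  ser <- build_power_series(ev, 60, "C4", duration_s = 4 * 3600)
  est <- estimate_cycle(ser)
  expect_false(est$reliable)
})

test_that("a constant series has no spectral peak and is not reliable", {
  ev <- make_power_events(6 * 3600, function(t) rep(7, length(t)))
  ser <- build_power_series(ev, 60, "C4", duration_s = 6 * 3600)
  est <- estimate_cycle(ser)
  expect_true(is.na(est$period_h))
  expect_false(est$reliable)
})

test_that("estimated period is invariant to the modulation phase", {
  T_s <- 1.7 * 3600
  periods <- vapply(c(0, pi / 3, pi, 4.8), function(phi) {
    ev <- make_power_events(
      8 * 3600, function(t) 10 * (1 + 0.5 * sin(2 * pi * t / T_s + phi)))
    ser <- build_power_series(ev, 60, "C4", duration_s = 8 * 3600)
    estimate_cycle(ser)$period_h
  }, numeric(1))
  expect_true(all(abs(periods - periods[1]) < 1e-9))
})

test_that("cycle estimates are independent of duration under the null and flag a planted confound", {
  # identical planted period, varying durations: dependence should rarely flag
  flagged <- vapply(1:10, function(batch) {
    durations <- seq(5, 10, length.out = 8)
    res <- lapply(seq_along(durations), function(i) {
      cfg <- sim_config(duration = durations[i] * 3600, n_channels = 1,
                        channel_labels = "C4", cycle_depth = 0.5,
                        artifact_rate = 0, seed = batch * 100 + i)
      ev <- simulate_burst_events(cfg)
      ser <- build_power_series(ev, 60, "C4", duration_s = cfg$duration)
      estimate_cycle(ser)
    })
    chk <- cycle_reliability_check(
      vapply(res, `[[`, numeric(1), "period_h"),
      vapply(res, `[[`, numeric(1), "amplitude"),
      durations, rep(0, 8))
    any(chk$flagged[chk$measure == "period" & chk$against == "duration"])
  }, logical(1))
  expect_gte(mean(!flagged), 0.9)

  # periods proportional to duration -> dependence flagged
  set.seed(1)
  dur <- seq(5, 10, length.out = 10)
  chk <- cycle_reliability_check(0.2 * dur + rnorm(10, sd = 0.01),
                                 runif(10), dur, rep(0, 10))
  expect_true(chk$flagged[chk$measure == "period" & chk$against == "duration"])

  expect_error(cycle_reliability_check(1:2, 1:2, 1:2, 1:2), "at least 3")
})

test_that("interval-power correlation: perfect coupling, shuffled null, planted coupling", {
  # power equal to the preceding silent gap -> r = 1 at each channel
  set.seed(4)
  onsets <- cumsum(runif(50, 5, 20))
  ev <- data.frame(channel = "C4", onset_s = onsets, offset_s = onsets + 1,
                   duration_s = 1, normalised_power_uv2 = NA)
  ev$normalised_power_uv2 <- c(1, onsets[-1] - (onsets[-50] + 1))
  res <- interval_power_correlation(ev)
  expect_equal(unname(res$per_channel_r["C4"]), 1, tolerance = 1e-12)

  # power shuffled against intervals -> mean r near 0 across replicates
  set.seed(9)
  null_rs <- vapply(1:100, function(i) {
    e <- ev
    e$normalised_power_uv2 <- sample(e$normalised_power_uv2)
    interval_power_correlation(e)$mean_r
  }, numeric(1))
  expect_lt(abs(mean(null_rs)), 0.1)

  # sleep-cycle coupled generator -> positive coupling in nearly all replicates
  pos <- vapply(1:20, function(s) {
    cfg <- sim_config(duration = 4 * 3600, n_channels = 1,
                      channel_labels = "C4", cycle_depth = 0.5,
                      artifact_rate = 0, seed = 1000 + s)
    interval_power_correlation(simulate_burst_events(cfg))$mean_r > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)

  expect_error(interval_power_correlation(ev[1:2, ]), "at least 3")
})

test_that("pairs spanning masked gaps are excluded", {
  ev <- data.frame(channel = "C4", onset_s = c(10, 30, 55, 70),
                   offset_s = c(11, 31, 56, 71), duration_s = 1,
                   normalised_power_uv2 = c(3, 9, 2, 7))
  mask <- data.frame(onset_s = 35, offset_s = 45)  # inside gap 31 -> 55
  full <- interval_power_correlation(ev)
  masked <- interval_power_correlation(ev, mask = mask)
  gaps <- c(19, 24, 14)
  pw <- c(9, 2, 7)
  expect_equal(unname(masked$per_channel_r["C4"]),
               cor(gaps[-2], pw[-2]), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(full$per_channel_r, masked$per_channel_r)))
})
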