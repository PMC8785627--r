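test_that("central difference is exact for linear and quadratic motion", {
  fs <- 250
  t_s <- (0:499) / fs
  vt_lin <- central_difference_velocity(make_rec(10 * t_s))
  expect_equal(attr(vt_lin, "k"), 3L)
  interior <- vt_lin$mask == "ok"
  expect_equal(vt_lin$vx[interior], rep(10, sum(interior)), tolerance = 1e-9)
  # edge samples masked on both sides
  expect_equal(vt_lin$mask[1:6], rep("edge", 6))
  expect_equal(tail(vt_lin$mask, 6), rep("edge", 6))

  a <- 3
  vt_quad <- central_difference_velocity(make_rec(a * t_s^2))
  i <- which(vt_quad$mask == "ok")
  expect_equal(vt_quad$vx[i], 2 * a * t_s[i], tolerance = 1e-9)
})

test_that("a position step concentrates acceleration at the step", {
  x <- rep(c(0, 1), each = 250)
  vt <- central_difference_velocity(make_rec(x))
  step_i <- 250
  # the differentiation window spreads the impulse across 2k samples
  expect_true(abs(which.max(abs(vt$ax)) - step_i) <= 2 * attr(vt, "k") + 1)
})

test_that("irregular timestamps are rejected", {
  rec <- make_rec(1:100 / 10)
  rec$t_ms[50] <- rec$t_ms[50] + 0.5
  expect_error(central_difference_velocity(rec), "irregular")
})

test_that("baseline noise clamps at the floor and scales with velocity noise", {
  p0 <- observer_params(noise_sd = 0, saccade_trigger_error = Inf,
                        blink_rate = 0)
  tr <- make_trajectory()
  vt0 <- central_difference_velocity(simulate_gaze(tr, p0, seed = 1))
  b0 <- estimate_baseline_noise(vt0)
  expect_lt(b0$baseline_sd, 1)
  expect_equal(b0$threshold, 750)

  # white velocity noise sigma_v propagates through the cascaded central
  # difference to an acceleration SD of sigma_v / (2 k^1.5 dt): the second
  # difference spans two disjoint 2k-sample sums of the velocity noise
  sds <- vapply(c(2, 4), function(sv) {
    p <- observer_params(noise_sd = sv, saccade_trigger_error = Inf,
                         blink_rate = 0)
    mean(vapply(1:10, function(i) {
      vt <- central_difference_velocity(simulate_gaze(tr, p, seed = i))
      c(sd(vt$ax[vt$t_ms >= 300 & vt$t_ms < 1300], na.rm = TRUE),
        estimate_baseline_noise(vt)$baseline_sd)
    }, numeric(2))[1, ])
  }, numeric(1))
  theory <- 2 / (2 * 3^1.5 * (1 / 250))
  expect_lt(abs(sds[1] - theory) / theory, 0.10)
  # doubling the velocity noise doubles the (trimmed) estimate
  ests <- vapply(c(2, 4), function(sv) {
    p <- observer_params(noise_sd = sv, saccade_trigger_error = Inf,
                         blink_rate = 0)
    mean(vapply(1:10, function(i) {
      vt <- central_difference_velocity(simulate_gaze(tr, p, seed = i))
      estimate_baseline_noise(vt)$baseline_sd
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(ests[2] / ests[1] - 2), 0.2)
})

test_that("pure pursuit yields no events; injected saccades are found", {
  p0 <- observer_params(noise_sd = 0, saccade_trigger_error = Inf,
                        blink_rate = 0)
  tr <- make_trajectory()
  vt0 <- central_difference_velocity(simulate_gaze(tr, p0, seed = 1))
  ev0 <- detect_saccades(vt0)
  expect_equal(nrow(ev0), 0L)

  # one 2 deg, ~30 ms saccade: exactly one event, bounds within 8 ms
  forced <- data.frame(onset_ms = 1500, amplitude = 2)
  rec <- simulate_gaze(tr, p0, seed = 1, forced_saccades = forced)
  truth <- attr(rec, "truth")$saccades
  ev <- detect_saccades(central_difference_velocity(rec))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$detected_by, "acceleration")
  expect_lte(abs(ev$onset_ms - truth$onset_ms), 8)
  expect_lte(abs(ev$offset_ms - truth$offset_ms), 8)
  expect_equal(ev$amplitude, 2, tolerance = 0.1)
  # smoothed peak velocity near (below) the pulse peak 2 * amplitude / D
  expect_gt(ev$peak_velocity, 0.6 * 125)
  expect_lt(ev$peak_velocity, 1.05 * 125)
})

test_that("the fallback rule enforces the amplitude floor", {
  # The fallback (velocity > 40 deg/s within amplitude 0.3-5 deg) is
  # exercised with the acceleration rule disabled via its threshold
  # override, on a fine 1 kHz grid with a 2 ms half-window so a small
  # event's velocity survives the differentiation smoothing.
  fs <- 1000
  pulse_at <- function(amp) {
    vx <- rep(8, 2000)
    i <- 1000:1007
    vx[i] <- vx[i] + amp / (8 / fs) * (1 - cos(2 * pi * (1:8 - 0.5) / 8))
    make_rec(cumsum(vx) / fs, fs = fs)
  }
  vt_small <- central_difference_velocity(pulse_at(0.25), half_window_ms = 2)
  ev_small <- detect_saccades(vt_small, accel_threshold = 1e9)
  expect_equal(nrow(ev_small), 0L)

  vt_big <- central_difference_velocity(pulse_at(0.5), half_window_ms = 2)
  ev_big <- detect_saccades(vt_big, accel_threshold = 1e9)
  expect_equal(nrow(ev_big), 1L)
  expect_equal(ev_big$detected_by, "velocity_amplitude")
  expect_gt(ev_big$amplitude, 0.3)
})

test_that("saccade excision masks the expected samples and is idempotent", {
  p0 <- observer_params(noise_sd = 0, saccade_trigger_error = Inf,
                        blink_rate = 0)
  tr <- make_trajectory()
  vt <- central_difference_velocity(simulate_gaze(tr, p0, seed = 1))

  # no events: unchanged, zero removal
  vt_id <- remove_saccades_and_artifacts(vt, detect_saccades(vt))
  expect_equal(attr(vt_id, "removed_fraction"), 0)
  expect_equal(vt_id$mask, vt$mask)

  # a grid-aligned 30 ms event masks samples in [onset, offset] -> 8
  ev <- data.frame(onset_ms = 1000, offset_ms = 1030)
  masked <- remove_saccades_and_artifacts(vt, ev, pad_ms = 0)
  expect_equal(sum(masked$mask == "saccade"), 8L)

  twice <- remove_saccades_and_artifacts(masked, ev, pad_ms = 0)
  expect_identical(twice$mask, masked$mask)
})

test_that("desaccaded averages recover the smooth pursuit velocity", {
  # pursuit at 8 deg/s with one large saccade: desaccaded mean within 1%
  fs <- 250
  n <- 1000
  vx_true <- rep(8, n)
  sacc <- 200:207
  vx <- vx_true
  vx[sacc] <- vx[sacc] + 2 / (8 / fs) * (1 - cos(2 * pi * (1:8 - 0.5) / 8))
  rec <- make_rec(cumsum(vx) / fs)
  vt <- central_difference_velocity(rec)
  ev <- detect_saccades(vt)
  m <- remove_saccades_and_artifacts(vt, ev)
  expect_equal(mean(m$vx[m$mask == "ok"]), 8, tolerance = 0.01 * 8)
})

test_that("blink samples are masked with a guard band", {
  p <- observer_params(noise_sd = 0, saccade_trigger_error = Inf,
                       blink_rate = 0)
  tr <- make_trajectory()
  rec <- simulate_gaze(tr, p, seed = 1)
  rec$valid[500:530] <- FALSE
  vt <- central_difference_velocity(rec)
  # 40 ms guard = 10 samples on each side
  expect_true(all(vt$mask[490:540] == "blink"))
  expect_equal(vt$mask[489], "ok")
  expect_equal(vt$mask[541], "ok")
})

test_that("unusable trials are flagged when too much is masked", {
  p0 <- observer_params(noise_sd = 0, saccade_trigger_error = Inf,
                        blink_rate = 0)
  tr <- make_trajectory()
  vt <- central_difference_velocity(simulate_gaze(tr, p0, seed = 1))
  ev <- data.frame(onset_ms = 0, offset_ms = 4000)
  flagged <- remove_saccades_and_artifacts(vt, ev)
  expect_false(attr(flagged, "usable"))
  expect_gt(attr(flagged, "removed_fraction"), 0.5)
})
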