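test_that("gain profile reproduces the configured window means", {
  p <- observer_params()
  expect_equal(gain_profile(0, "blank", p), 0)
  # steady state, late visible window
  expect_equal(gain_profile(2875, "consistent", p), 0.86)
  expect_equal(gain_profile(2875, "inconsistent", p), 0.79)
  # early window plateau
  expect_equal(gain_profile(175, "consistent", p), 0.78)
  expect_equal(gain_profile(175, "blank", p), 0.69)
  # terminal window
  expect_equal(gain_profile(5900, "consistent", p), 0.41)
  expect_equal(gain_profile(5900, "blank", p), 0.34)
})

test_that("gain profile is continuous on the 4 ms grid", {
  p <- observer_params()
  t <- seq(0, 6000, by = 4)
  for (bg in c("blank", "inconsistent", "consistent")) {
    g <- gain_profile(t, bg, p)
    expect_lt(max(abs(diff(g))), 0.05)
    expect_true(all(g >= 0 & g <= 1.5))
  }
})

test_that("an identity observer tracks the wheel centre", {
  ones <- c(blank = 1, inconsistent = 1, consistent = 1)
  p <- observer_params(steady_gain = ones, onset_gain = ones,
                       terminal_gain = ones, occlusion_residual_gain = ones,
                       noise_sd = 0, saccade_trigger_error = Inf,
                       blink_rate = 0)
  tr <- make_trajectory()
  rec <- simulate_gaze(tr, p, seed = 1)
  v <- tr$geometry$translation_speed
  # velocity equals the centre's after the open-loop ramp
  sm <- attr(rec, "truth")$smooth_vx
  expect_equal(sm[tr$t_ms >= 100], rep(v, sum(tr$t_ms >= 100)))
  # position runs parallel to the centre (constant ramp deficit)
  lag <- tr$center_x - rec$x
  late <- tr$t_ms >= 100
  expect_lt(diff(range(lag[late])), 1e-9)
  expect_lt(max(abs(lag[late])), v * 0.1)
})

test_that("gaze simulation is deterministic and triggers catch-up saccades", {
  p <- observer_params()
  tr <- make_trajectory()
  a <- simulate_gaze(tr, p, seed = 9)
  b <- simulate_gaze(tr, p, seed = 9)
  expect_identical(a$x, b$x)
  expect_identical(attr(a, "truth")$saccades, attr(b, "truth")$saccades)

  # steady gain 0.8, trigger 1 deg: the 0.2 * v deg/s lag crosses 1 deg
  # well within the 3000 ms visible phase
  g8 <- c(blank = 0.8, inconsistent = 0.8, consistent = 0.8)
  p8 <- observer_params(steady_gain = g8, onset_gain = g8,
                        terminal_gain = g8, occlusion_residual_gain = g8,
                        noise_sd = 0, saccade_trigger_error = 1,
                        blink_rate = 0)
  rec <- simulate_gaze(tr, p8, seed = 2)
  truth <- attr(rec, "truth")$saccades
  expect_gte(sum(truth$onset_ms < 3000), 1L)
  # injected amplitude matches the trigger error up to its +/-20% jitter
  expect_gt(truth$amplitude[1], 0.75)
  expect_lt(truth$amplitude[1], 1.25)
})

test_that("blinks appear as invalid gaps at the configured rate", {
  p <- observer_params(blink_rate = 20)
  tr <- make_trajectory()
  rec <- simulate_gaze(tr, p, seed = 3)
  expect_true(any(!rec$valid))
  p0 <- observer_params(blink_rate = 0)
  rec0 <- simulate_gaze(tr, p0, seed = 3)
  expect_true(all(rec0$valid))
})

test_that("responses satisfy the first/second moment contract", {
  tr <- make_trajectory(background = "consistent")

  # degenerate spread: presses exactly at bias
  ce150 <- matrix(150, 2, 3,
                  dimnames = list(c("visible", "occluded"),
                                  c("blank", "inconsistent", "consistent")))
  p_exact <- observer_params(ce_mean = ce150, ve_sd = 0 * ce150)
  r <- simulate_response(tr, p_exact, seed = 4)
  expect_equal(r$press1_ms, tr$t_entry + 150)
  expect_equal(r$press2_ms, tr$t_arrival + 150)

  # ideal observer
  p_ideal <- observer_params(ce_mean = 0 * ce150, ve_sd = 0 * ce150)
  r0 <- simulate_response(tr, p_ideal, seed = 4)
  expect_equal(r0$press1_ms, tr$t_entry)
  expect_equal(r0$press2_ms, tr$t_arrival)

  # Monte Carlo moments: ce 100, ve 50, n = 10000 -> mean within 3 SE
  ce100 <- matrix(100, 2, 3, dimnames = dimnames(ce150))
  ve50 <- matrix(50, 2, 3, dimnames = dimnames(ce150))
  p_mc <- observer_params(ce_mean = ce100, ve_sd = ve50)
  n <- 10000L
  e1 <- numeric(n)
  set.seed(991)
  for (i in seq_len(n)) {
    r <- simulate_response(tr, p_mc, seed = NULL)
    e1[i] <- r$press1_ms - tr$t_entry
  }
  se <- 50 / sqrt(n)
  expect_lt(abs(mean(e1) - 100), 3 * se)
  expect_lt(abs(sd(e1) - 50), 3 * 50 / sqrt(2 * n))
})

test_that("press order and window bounds always hold", {
  p <- observer_params()
  for (bg in c("blank", "consistent")) {
    tr <- make_trajectory(background = bg)
    for (i in 1:50) {
      r <- simulate_response(tr, p, seed = 100 + i)
      expect_lt(r$press1_ms, r$press2_ms)
      expect_gte(r$press1_ms, 0)
    }
  }
})

test_that("gaze CSV round-trips and irregular grids are rejected", {
  tr <- make_trajectory()
  rec <- simulate_gaze(tr, observer_params(), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze(rec, path, trial_id = 7L)
  back <- read_gaze(path)
  expect_equal(back$x, rec$x, tolerance = 1e-9)
  expect_equal(attr(back, "fs"), 250)

  bad <- utils::read.csv(path)
  bad$t_ms[10] <- bad$t_ms[10] + 1
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_gaze(path2), "irregular")
})
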