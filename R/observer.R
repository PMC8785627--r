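#' Synthetic observer parameters
#'
#' Parameters of the forward model that generates gaze recordings and
#' button-press responses with the statistical structure the analysis
#' pipeline assumes. All per-background vectors are named
#' `blank`, `inconsistent`, `consistent`.
#'
#' The pursuit gain profile is piecewise smooth: a linear open-loop ramp from
#' 0 to `onset_gain` over the first `openloop_ramp_ms`, a hold at
#' `onset_gain` to 250 ms, a linear rise to `steady_gain` by 500 ms, a
#' steady-state plateau until occlusion onset, an exponential decay (time
#' constant `occlusion_decay_ms`) towards `occlusion_residual_gain`, and a
#' linear decline starting at `decline_start_ms` that reaches
#' `terminal_gain` at `terminal_start_ms` and holds it to trial end.
#' Default gain levels follow the published per-background means for the
#' early (100-250 ms), late-visible (2750-3000 ms) and terminal
#' (5750-6000 ms) windows; the occlusion residual is unconstrained by those
#' reports and defaults to `steady_gain - 0.2`.
#'
#' Timing responses are `press1 = t_entry + N(ce_mean_visible, ve_sd_visible)`
#' and `press2 = t_arrival + N(ce_mean_occluded, ve_sd_occluded)`; the
#' defaults are the published circle-target condition means.
#'
#' @param steady_gain,onset_gain,terminal_gain,occlusion_residual_gain
#'   named per-background pursuit gains (ratios in `[0, 1.5]`).
#' @param openloop_ramp_ms open-loop ramp duration, ms.
#' @param occlusion_decay_ms exponential decay time constant after
#'   occlusion onset, ms.
#' @param decline_start_ms,terminal_start_ms bounds of the terminal linear
#'   decline, ms.
#' @param noise_sd white velocity-noise SD, deg/s.
#' @param saccade_trigger_error position error (deg) at which a catch-up
#'   saccade is injected.
#' @param saccade_duration_ms catch-up saccade duration, ms.
#' @param blink_rate blinks per minute; `blink_duration_ms` their length.
#' @param blink_duration_ms blink duration, ms.
#' @param ce_mean,ve_sd 2 x 3 matrices (rows `visible`, `occluded`; columns
#'   backgrounds) of response bias means and spreads, ms.
#' @param subject_gain_sd,subject_ce_sd between-subject SDs: a single gain
#'   offset SD and per-phase CE offset SDs `c(visible, occluded)`.
#' @return Object of class `observer_params` (a list).
#' @export
observer_params <- function(steady_gain = c(blank = 0.79, inconsistent = 0.79,
                                            consistent = 0.86),
                            onset_gain = c(blank = 0.69, inconsistent = 0.77,
                                           consistent = 0.78),
                            terminal_gain = c(blank = 0.34,
                                              inconsistent = 0.34,
                                              consistent = 0.41),
                            occlusion_residual_gain = steady_gain - 0.2,
                            openloop_ramp_ms = 100,
                            occlusion_decay_ms = 300,
                            decline_start_ms = 5000,
                            terminal_start_ms = 5750,
                            noise_sd = 2,
                            saccade_trigger_error = 1.0,
                            saccade_duration_ms = 32,
                            blink_rate = 2,
                            blink_duration_ms = 150,
                            ce_mean = rbind(
                              visible = c(blank = 123.87,
                                          inconsistent = 108.64,
                                          consistent = 101.89),
                              occluded = c(blank = 437.53,
                                           inconsistent = 421.89,
                                           consistent = 312.41)),
                            ve_sd = rbind(
                              visible = c(blank = 90.12,
                                          inconsistent = 91.13,
                                          consistent = 82.26),
                              occluded = c(blank = 419.04,
                                           inconsistent = 395.01,
                                           consistent = 255.42)),
                            subject_gain_sd = 0.03,
                            subject_ce_sd = c(visible = 8, occluded = 30)) {
  gains <- c(steady_gain, onset_gain, terminal_gain, occlusion_residual_gain)
  stopifnot(all(gains >= 0 & gains <= 1.5),
            all(ve_sd >= 0),
            openloop_ramp_ms > 0, occlusion_decay_ms > 0,
            decline_start_ms < terminal_start_ms)
  structure(list(steady_gain = steady_gain, onset_gain = onset_gain,
                 terminal_gain = terminal_gain,
                 occlusion_residual_gain = occlusion_residual_gain,
                 openloop_ramp_ms = openloop_ramp_ms,
                 occlusion_decay_ms = occlusion_decay_ms,
                 decline_start_ms = decline_start_ms,
                 terminal_start_ms = terminal_start_ms,
                 noise_sd = noise_sd,
                 saccade_trigger_error = saccade_trigger_error,
                 saccade_duration_ms = saccade_duration_ms,
                 blink_rate = blink_rate,
                 blink_duration_ms = blink_duration_ms,
                 ce_mean = ce_mean, ve_sd = ve_sd,
                 subject_gain_sd = subject_gain_sd,
                 subject_ce_sd = subject_ce_sd),
            class = "observer_params")
}

#' Draw a per-subject parameter set
#'
#' Adds Gaussian between-subject offsets (a common offset on all gain levels,
#' clipped to keep gains in `[0, 1.5]`, and per-phase offsets on the CE
#' means) so a simulated group has a realistic repeated-measures error
#' structure.
#'
#' @param params group-level [observer_params()].
#' @return An `observer_params` for one subject.
#' @export
subject_params <- function(params) {
  stopifnot(inherits(params, "observer_params"))
  g_off <- stats::rnorm(1, 0, params$subject_gain_sd)
  clip <- function(g) pmin(pmax(g + g_off, 0), 1.5)
  out <- params
  out$steady_gain <- clip(params$steady_gain)
  out$onset_gain <- clip(params$onset_gain)
  out$terminal_gain <- clip(params$terminal_gain)
  out$occlusion_residual_gain <- clip(params$occlusion_residual_gain)
  ce_off <- stats::rnorm(2, 0, params$subject_ce_sd)
  out$ce_mean <- params$ce_mean + ce_off
  out$subject_gain_sd <- 0
  out$subject_ce_sd <- c(visible = 0, occluded = 0)
  out
}

#' Pursuit gain profile
#'
#' Evaluates the condition-dependent pursuit-gain profile at times `t_ms`
#' (see [observer_params()] for the shape). Continuous everywhere.
#'
#' @param t_ms times in ms (vectorized), within `[0, 6000]`.
#' @param background background condition.
#' @param params an [observer_params()].
#' @param t_entry occlusion onset, ms.
#' @return numeric vector of gains.
#' @examples
#' p <- observer_params()
#' gain_profile(2875, "consistent", p)  # 0.86
#' @export
gain_profile <- function(t_ms, background, params = observer_params(),
                         t_entry = 3000) {
  stopifnot(background %in% names(params$steady_gain))
  g_on <- params$onset_gain[[background]]
  g_st <- params$steady_gain[[background]]
  g_res <- params$occlusion_residual_gain[[background]]
  g_term <- params$terminal_gain[[background]]
  ramp <- params$openloop_ramp_ms
  tau <- params$occlusion_decay_ms
  t_dec <- params$decline_start_ms
  t_term <- params$terminal_start_ms
  g_at_dec <- g_res + (g_st - g_res) * exp(-(t_dec - t_entry) / tau)

  g <- numeric(length(t_ms))
  seg1 <- t_ms < ramp
  g[seg1] <- g_on * t_ms[seg1] / ramp
  seg2 <- t_ms >= ramp & t_ms < 250
  g[seg2] <- g_on
  seg3 <- t_ms >= 250 & t_ms < 500
  g[seg3] <- g_on + (g_st - g_on) * (t_ms[seg3] - 250) / 250
  seg4 <- t_ms >= 500 & t_ms < t_entry
  g[seg4] <- g_st
  seg5 <- t_ms >= t_entry & t_ms < t_dec
  g[seg5] <- g_res + (g_st - g_res) * exp(-(t_ms[seg5] - t_entry) / tau)
  seg6 <- t_ms >= t_dec & t_ms < t_term
  g[seg6] <- g_at_dec + (g_term - g_at_dec) * (t_ms[seg6] - t_dec) /
    (t_term - t_dec)
  g[t_ms >= t_term] <- g_term
  unname(g)
}

# raised-cosine saccade velocity waveform: displacement `amplitude` over
# `n` samples; peak velocity = 2 * amplitude / duration
saccade_pulse <- function(amplitude, n, dt_s) {
  tau <- (seq_len(n) - 0.5) / n
  amplitude / (n * dt_s) * (1 - cos(2 * pi * tau))
}

# catch-up saccade schedule driven by the deterministic pursuit lag (the
# gain-deficit integral), with a jittered trigger threshold per event.
# Keeping the schedule independent of the velocity noise means saccade
# excision cannot select on the noise, so desaccaded averages stay
# unbiased estimators of the smooth velocity.
schedule_saccades <- function(det_err, trigger, sacc_n, n) {
  onsets <- integer(0); amps <- numeric(0)
  from <- 1L
  carried <- 0  # displacement already corrected by earlier saccades
  repeat {
    idx <- which(det_err[from:n] - carried >
                   trigger * stats::runif(1, 0.8, 1.2))
    if (length(idx) == 0L) break
    i0 <- from + idx[1] - 1L
    if (i0 + sacc_n > n) break
    a <- det_err[i0] - carried
    onsets <- c(onsets, i0); amps <- c(amps, a)
    carried <- carried + a
    from <- i0 + sacc_n
    if (from >= n) break
  }
  list(onsets = onsets, amps = amps)
}

#' Simulate a gaze recording for one trial
#'
#' Forward model of the measurement process: horizontal eye velocity is the
#' gain profile times the translation speed plus white Gaussian noise;
#' position is integrated from velocity. Whenever the deterministic pursuit
#' lag behind the (extrapolated) wheel centre -- the integrated gain
#' deficit, uncorrupted by the noise -- exceeds `saccade_trigger_error`
#' (jittered by +/-20% per event), a catch-up saccade is injected as a
#' raised-cosine velocity pulse whose displacement equals the lag; keeping
#' the schedule noise-independent makes desaccaded averages unbiased.
#' Blinks are inserted as invalid gaps at
#' `blink_rate` per minute. Vertical gaze copies the target's y at the
#' steady gain. All injected events are recorded as ground truth.
#'
#' @param trajectory a [make_trajectory()] result.
#' @param params an [observer_params()] (typically [subject_params()]).
#' @param seed integer seed; the recording is a deterministic function of
#'   it. `NULL` draws from the current RNG state, for simulation suites
#'   that share one seeded stream.
#' @param forced_saccades optional data.frame with columns `onset_ms` and
#'   `amplitude` (degrees): saccades injected at prescribed times in
#'   addition to the error-triggered ones (set
#'   `params$saccade_trigger_error = Inf` to use only these). Used to build
#'   detector-validation suites with known ground truth.
#' @return Object of class `gaze_recording`: data.frame with columns `t_ms`,
#'   `x`, `y`, `valid`, and attributes `fs`, `params`, `trajectory_meta`,
#'   `truth` (list with `saccades` data.frame, `blinks`, `smooth_vx`).
#' @export
simulate_gaze <- function(trajectory, params = observer_params(), seed = 1L,
                          forced_saccades = NULL) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (!is.null(seed)) set.seed(seed)
  t_ms <- trajectory$t_ms
  n <- length(t_ms)
  fs <- trajectory$fs
  dt_s <- 1 / fs
  v <- trajectory$geometry$translation_speed
  g <- gain_profile(t_ms, trajectory$background, params,
                    t_entry = trajectory$t_entry)
  smooth_vx <- g * v +
    if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else 0
  vx <- smooth_vx
  center_x <- trajectory$center_x

  # catch-up saccade injection against the deterministic pursuit lag
  sacc_n <- max(2L, round(params$saccade_duration_ms / 1000 * fs))
  onsets <- integer(0); amps <- numeric(0)
  if (!is.null(forced_saccades) && nrow(forced_saccades) > 0) {
    for (r in seq_len(nrow(forced_saccades))) {
      i0 <- which.min(abs(t_ms - forced_saccades$onset_ms[r]))
      if (i0 + sacc_n > n) next
      onsets <- c(onsets, i0)
      amps <- c(amps, forced_saccades$amplitude[r])
    }
  }
  if (is.finite(params$saccade_trigger_error)) {
    x_det <- center_x[1] + cumsum(g * v) * dt_s - g[1] * v * dt_s
    det_err <- center_x - x_det
    sch <- schedule_saccades(det_err, params$saccade_trigger_error,
                             sacc_n, n)
    onsets <- c(onsets, sch$onsets)
    amps <- c(amps, sch$amps)
  }
  for (j in seq_along(onsets)) {
    i0 <- onsets[j]
    vx[i0:(i0 + sacc_n - 1L)] <- vx[i0:(i0 + sacc_n - 1L)] +
      saccade_pulse(amps[j], sacc_n, dt_s)
  }
  x_eye <- center_x[1] + cumsum(vx) * dt_s - vx[1] * dt_s

  # blinks as invalid gaps
  valid <- rep(TRUE, n)
  n_blinks <- stats::rpois(1, params$blink_rate * (max(t_ms) / 60000))
  blink_onsets <- sort(sample.int(n, n_blinks))
  blink_len <- max(1L, round(params$blink_duration_ms / 1000 * fs))
  for (b in blink_onsets)
    valid[b:min(n, b + blink_len - 1L)] <- FALSE

  y_eye <- trajectory$geometry$start_y +
    (trajectory$target_y - trajectory$geometry$start_y) *
      params$steady_gain[[trajectory$background]]

  rec <- data.frame(t_ms = t_ms, x = x_eye, y = y_eye, valid = valid)
  attr(rec, "fs") <- fs
  attr(rec, "params") <- params
  attr(rec, "trajectory_meta") <- list(
    background = trajectory$background,
    start_orientation = trajectory$start_orientation,
    t_entry = trajectory$t_entry, t_arrival = trajectory$t_arrival,
    translation_speed = v)
  ord <- order(onsets)
  attr(rec, "truth") <- list(
    saccades = data.frame(
      onset_ms = t_ms[onsets[ord]],
      offset_ms = t_ms[pmin(onsets[ord] + sacc_n - 1L, n)],
      amplitude = amps[ord]),
    blinks = t_ms[blink_onsets],
    smooth_vx = smooth_vx,
    gain = g)
  class(rec) <- c("gaze_recording", "data.frame")
  rec
}

#' Simulate the two button presses of one trial
#'
#' `press1` judges occluder entry, `press2` the (unseen) arrival at the far
#' edge: each is the ground-truth event time plus a Gaussian error with the
#' condition's CE mean and VE spread. Draws falling outside the trial window
#' are resampled (count recorded in attribute `n_resampled`). The
#' `"extrapolation"` mode couples the occluded-phase bias to the terminal
#' pursuit gain (lower gain, later press), with the same first two moments
#' at the default gains.
#'
#' @param trajectory a [make_trajectory()] result.
#' @param params an [observer_params()].
#' @param seed integer seed; `NULL` draws from the current RNG state.
#' @param mode `"clocking"` (independent Gaussian errors) or
#'   `"extrapolation"` (gain-coupled occluded bias).
#' @param window trial response window `c(min_ms, max_ms)`.
#' @return data.frame with one row: `press1_ms`, `press2_ms`; attribute
#'   `n_resampled`.
#' @export
simulate_response <- function(trajectory, params = observer_params(),
                              seed = 1L,
                              mode = c("clocking", "extrapolation"),
                              window = c(0, 7000)) {
  mode <- match.arg(mode)
  stopifnot(inherits(trajectory, "trajectory"))
  if (!is.null(seed)) set.seed(seed)
  bg <- trajectory$background
  ce_v <- params$ce_mean["visible", bg]
  ce_o <- params$ce_mean["occluded", bg]
  if (mode == "extrapolation") {
    # occluded-phase bias rises as terminal pursuit gain falls short of the
    # across-condition mean; centred so defaults keep the same mean
    g_term <- params$terminal_gain[[bg]]
    ce_o <- ce_o + 1000 * (mean(params$terminal_gain) - g_term)
  }
  n_resampled <- 0L
  draw <- function(mu, sd, lo, hi) {
    repeat {
      x <- stats::rnorm(1, mu, sd)
      if (x >= lo && x <= hi) return(x)
      n_resampled <<- n_resampled + 1L
      if (n_resampled > 1000L) stop("response resampling did not converge")
    }
  }
  p1 <- draw(trajectory$t_entry + ce_v, params$ve_sd["visible", bg],
             window[1], window[2])
  p2 <- draw(trajectory$t_arrival + ce_o, params$ve_sd["occluded", bg],
             max(p1, window[1]), window[2] + 1000)
  out <- data.frame(press1_ms = p1, press2_ms = p2)
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Write a gaze recording as CSV
#'
#' Columns `t_ms`, `x_deg`, `y_deg`, `valid`, `trial_id`.
#'
#' @param rec a `gaze_recording`.
#' @param path file path.
#' @param trial_id trial identifier column value.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(rec, path, trial_id = 1L) {
  utils::write.csv(data.frame(t_ms = rec$t_ms, x_deg = rec$x, y_deg = rec$y,
                              valid = rec$valid, trial_id = trial_id),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a gaze CSV into a `gaze_recording`
#'
#' Accepts external sample logs with columns `t_ms`, `x_deg`, `y_deg`,
#' `valid` (and optionally `trial_id`). Timestamps must form a regular grid.
#'
#' @param path file path.
#' @return a `gaze_recording` (without ground-truth attributes).
#' @export
read_gaze <- function(path) {
  df <- utils::read.csv(path)
  dt <- diff(df$t_ms)
  if (length(dt) > 0 && max(abs(dt - dt[1])) > 1e-6)
    stop("irregular gaze timestamps; resample before analysis", call. = FALSE)
  rec <- data.frame(t_ms = df$t_ms, x = df$x_deg, y = df$y_deg,
                    valid = as.logical(df$valid))
  attr(rec, "fs") <- if (length(dt) > 0) 1000 / dt[1] else NA_real_
  class(rec) <- c("gaze_recording", "data.frame")
  rec
}
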