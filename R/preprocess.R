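#' Central-difference velocity and acceleration
#'
#' Differentiates horizontal gaze position with a central difference over a
#' +/- `half_window_ms` interval:
#' `vx(t_i) = (x(t_{i+k}) - x(t_{i-k})) / (2 k / fs)` with
#' `k = round(half_window_ms * fs / 1000)`, forced to at least 1 and rounded
#' up from half-samples (k = 3 at 250 Hz for the nominal +/-10 ms).
#' Acceleration is obtained by applying the same operator to the velocity.
#' The first/last `k` samples of each derivative are masked `edge`; samples
#' invalid in the recording (blinks) are masked `blink` together with a
#' guard band of `blink_guard_ms` on each side.
#'
#' @param rec a `gaze_recording` (see [simulate_gaze()] / [read_gaze()]).
#' @param half_window_ms differentiation half-window, ms.
#' @param blink_guard_ms guard band masked around invalid samples, ms.
#' @return Object of class `velocity_trace`: data.frame with `t_ms`, `vx`,
#'   `ax`, `mask` (`ok`, `saccade`, `blink`, `artifact`, `edge`); attributes
#'   `fs`, `k`, `meta` (copied trajectory metadata, if present).
#' @examples
#' tr <- make_trajectory()
#' rec <- simulate_gaze(tr, observer_params(noise_sd = 0, blink_rate = 0))
#' vt <- central_difference_velocity(rec)
#' @export
central_difference_velocity <- function(rec, half_window_ms = 10,
                                        blink_guard_ms = 40) {
  fs <- attr(rec, "fs")
  stopifnot(is.numeric(fs), fs > 0)
  dt <- diff(rec$t_ms)
  if (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-6)
    stop("irregular sampling grid; resample before differentiation",
         call. = FALSE)
  k <- max(1L, as.integer(ceiling(half_window_ms * fs / 1000 - 1e-9)))
  if (2L * k + 1L > nrow(rec))
    stop("too few samples for the differentiation window", call. = FALSE)
  n <- nrow(rec)
  cd <- function(x) {
    out <- rep(NA_real_, n)
    i <- (k + 1L):(n - k)
    out[i] <- (x[i + k] - x[i - k]) / (2 * k / fs)
    out
  }
  vx <- cd(rec$x)
  ax <- cd(vx)
  mask <- rep("ok", n)
  mask[is.na(vx) | is.na(ax)] <- "edge"
  if (any(!rec$valid)) {
    guard <- max(0L, round(blink_guard_ms * fs / 1000))
    bad <- which(!rec$valid)
    band <- unique(unlist(lapply(bad, function(i)
      max(1L, i - guard):min(n, i + guard))))
    mask[band] <- ifelse(mask[band] == "edge", "edge", "blink")
  }
  out <- data.frame(t_ms = rec$t_ms, vx = vx, ax = ax, mask = mask,
                    stringsAsFactors = FALSE)
  attr(out, "fs") <- fs
  attr(out, "k") <- k
  attr(out, "meta") <- attr(rec, "trajectory_meta")
  class(out) <- c("velocity_trace", "data.frame")
  out
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("Velocity trace: %d samples at %g Hz (k = %d)\n",
              nrow(x), attr(x, "fs"), attr(x, "k")))
  print(table(x$mask))
  invisible(x)
}

#' Baseline acceleration noise and saccade threshold
#'
#' Estimates the SD of the acceleration trace over a saccade-free baseline
#' window of steady pursuit (default 300-1300 ms), iteratively discarding
#' samples beyond 2.5 SD until stable, and returns the adaptive saccade
#' threshold `2.5 * SD` clamped to the `clamp` range (defaults approximately
#' 750-1500 deg/s^2).
#'
#' @param vt a `velocity_trace`.
#' @param window baseline window `c(start_ms, end_ms)`.
#' @param k_sd threshold multiplier.
#' @param clamp threshold clamp range, deg/s^2.
#' @param min_samples minimum usable baseline samples.
#' @return list with `baseline_sd` and `threshold`.
#' @export
estimate_baseline_noise <- function(vt, window = c(300, 1300), k_sd = 2.5,
                                    clamp = c(750, 1500),
                                    min_samples = 100L) {
  in_win <- vt$t_ms >= window[1] & vt$t_ms < window[2] & vt$mask == "ok"
  a <- vt$ax[in_win]
  a <- a[!is.na(a)]
  if (length(a) < min_samples)
    stop("too few baseline samples for noise estimation", call. = FALSE)
  s <- stats::sd(a)
  for (i in 1:10) {
    keep <- abs(a) <= k_sd * s | s == 0
    s_new <- stats::sd(a[keep])
    if (!is.finite(s_new) || abs(s_new - s) < 1e-9 * max(s, 1)) break
    s <- s_new
  }
  list(baseline_sd = s,
       threshold = min(max(k_sd * s, clamp[1]), clamp[2]))
}

# expand index run [i0, i1] outward to the flanking sign changes of a,
# by at most max_expand samples per side (a slow monotone deceleration
# need not carry a sign change for seconds)
expand_to_zero_crossings <- function(a, i0, i1, max_expand = 25L) {
  s0 <- sign(a[i0])
  lim0 <- i0 - max_expand
  while (i0 > max(1L, lim0) && !is.na(a[i0 - 1]) &&
         sign(a[i0 - 1]) == s0 && s0 != 0)
    i0 <- i0 - 1L
  s1 <- sign(a[i1])
  n <- length(a)
  lim1 <- i1 + max_expand
  while (i1 < min(n, lim1) && !is.na(a[i1 + 1]) &&
         sign(a[i1 + 1]) == s1 && s1 != 0)
    i1 <- i1 + 1L
  c(i0, i1)
}

runs_from_logical <- function(z) {
  z[is.na(z)] <- FALSE
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect saccades in a velocity trace
#'
#' Two-stage detector. Primary rule: contiguous runs where the magnitude of
#' acceleration exceeds the adaptive threshold (2.5 SD of baseline noise,
#' clamped to approximately 750-1500 deg/s^2), expanded outward to the
#' flanking zero-crossings of the acceleration and padded by the
#' differentiation half-window. Fallback rule, applied to samples not already
#' claimed: runs where the velocity deviates from the local pursuit velocity
#' (median in a +/-100 ms neighbourhood excluding candidates) by more than
#' `vel_threshold`, kept only when the displacement amplitude (net of the
#' local pursuit drift) lies within `amp_range`. Overlapping events are merged; each is tagged with the rule
#' that fired.
#'
#' @param vt a `velocity_trace`.
#' @param accel_threshold override for the acceleration threshold
#'   (deg/s^2); `NULL` uses [estimate_baseline_noise()].
#' @param vel_threshold fallback velocity threshold, deg/s.
#' @param amp_range fallback amplitude acceptance range, degrees.
#' @param local_window_ms half-width of the local pursuit-velocity window.
#' @param merge_gap_ms events closer than this are merged.
#' @return data.frame of class `saccade_events`: `onset_ms`, `offset_ms`,
#'   `amplitude`, `peak_velocity`, `detected_by`; attribute `threshold`.
#' @export
detect_saccades <- function(vt, accel_threshold = NULL, vel_threshold = 40,
                            amp_range = c(0.3, 5), local_window_ms = 100,
                            merge_gap_ms = 12) {
  fs <- attr(vt, "fs")
  k <- attr(vt, "k")
  dt_ms <- 1000 / fs
  if (is.null(accel_threshold))
    accel_threshold <- estimate_baseline_noise(vt)$threshold
  n <- nrow(vt)
  usable <- vt$mask %in% c("ok", "saccade")

  cand <- abs(vt$ax) > accel_threshold & usable
  runs <- runs_from_logical(cand)
  events <- list()
  claimed <- rep(FALSE, n)
  if (nrow(runs) > 0) {
    for (r in seq_len(nrow(runs))) {
      span <- expand_to_zero_crossings(vt$ax, runs[r, 1], runs[r, 2])
      events[[length(events) + 1L]] <- c(span[1], span[2], 1L)  # acceleration
      claimed[span[1]:span[2]] <- TRUE
    }
  }

  # fallback: velocity deviation from local pursuit, amplitude-gated.
  # The local pursuit velocity (median in a +/- local_window_ms
  # neighbourhood, candidates excluded) is only evaluated where a deviation
  # is possible at all.
  vx_bg <- vt$vx
  vx_bg[claimed | !usable] <- NA
  half <- round(local_window_ms / dt_ms)
  med_global <- stats::median(vx_bg, na.rm = TRUE)
  maybe <- which(usable & !claimed &
                   abs(vt$vx - med_global) > vel_threshold / 2)
  dev <- rep(FALSE, n)
  if (length(maybe) > 0) {
    local_med <- vapply(maybe, function(i) {
      w <- vx_bg[max(1L, i - half):min(n, i + half)]
      stats::median(w, na.rm = TRUE)
    }, numeric(1))
    local_med[is.na(local_med)] <- med_global
    dev[maybe] <- abs(vt$vx[maybe] - local_med) > vel_threshold
  }
  vruns <- runs_from_logical(dev)
  if (nrow(vruns) > 0) {
    pos <- integrate_positions(vt)
    for (r in seq_len(nrow(vruns))) {
      i0 <- vruns[r, 1]; i1 <- vruns[r, 2]
      amp <- event_amplitude(vt, pos, i0, i1, usable)
      if (amp >= amp_range[1] && amp <= amp_range[2]) {
        events[[length(events) + 1L]] <- c(i0, i1, 2L)  # 2 = velocity/amp
        claimed[i0:i1] <- TRUE
      }
    }
  }

  if (length(events) == 0L) {
    out <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0),
                      detected_by = character(0), stringsAsFactors = FALSE)
  } else {
    ev <- do.call(rbind, events)
    ev <- ev[order(ev[, 1]), , drop = FALSE]
    # merge overlapping / near-adjacent events (acceleration rule wins tags)
    gap <- round(merge_gap_ms / dt_ms)
    merged <- ev[1, , drop = FALSE]
    if (nrow(ev) > 1) for (r in 2:nrow(ev)) {
      last <- nrow(merged)
      if (ev[r, 1] <= merged[last, 2] + gap) {
        merged[last, 2] <- max(merged[last, 2], ev[r, 2])
        merged[last, 3] <- min(merged[last, 3], ev[r, 3])
      } else merged <- rbind(merged, ev[r, , drop = FALSE])
    }
    pos <- integrate_positions(vt)
    # refine event bounds on the velocity profile: the acceleration span is
    # smeared by the differentiation window, so onset/offset are taken at
    # the 20%-of-peak-deviation crossings of |vx - local pursuit|
    refined <- t(vapply(seq_len(nrow(merged)), function(r) {
      i0 <- merged[r, 1]; i1 <- merged[r, 2]
      ctx <- setdiff(max(1L, i0 - 50L):min(n, i1 + 50L), i0:i1)
      ctx <- ctx[usable[ctx] & !is.na(vt$vx[ctx])]
      base <- if (length(ctx) >= 5L) stats::median(vt$vx[ctx]) else 0
      dev_ <- abs(vt$vx[i0:i1] - base)
      dev_[is.na(dev_)] <- 0
      hi <- which(dev_ >= 0.2 * max(dev_))
      c(i0 + hi[1] - 1L, i0 + hi[length(hi)] - 1L)
    }, integer(2)))
    out <- data.frame(
      onset_ms = vt$t_ms[refined[, 1]],
      offset_ms = vt$t_ms[refined[, 2]],
      amplitude = vapply(seq_len(nrow(merged)), function(r)
        event_amplitude(vt, pos, merged[r, 1], merged[r, 2], usable),
        numeric(1)),
      peak_velocity = vapply(seq_len(nrow(merged)), function(r)
        max(abs(vt$vx[merged[r, 1]:merged[r, 2]]), na.rm = TRUE), numeric(1)),
      detected_by = c("acceleration", "velocity_amplitude")[merged[, 3]],
      stringsAsFactors = FALSE)
  }
  class(out) <- c("saccade_events", "data.frame")
  attr(out, "threshold") <- accel_threshold
  out
}

# saccadic displacement across an index span, net of the local smooth
# pursuit drift (median velocity in the surrounding context)
event_amplitude <- function(vt, pos, i0, i1, usable) {
  n <- nrow(vt)
  fs <- attr(vt, "fs")
  j0 <- max(1L, i0 - 1L); j1 <- min(n, i1 + 1L)
  ctx <- setdiff(max(1L, i0 - 50L):min(n, i1 + 50L), i0:i1)
  ctx <- ctx[usable[ctx] & !is.na(vt$vx[ctx])]
  base <- if (length(ctx) >= 5L) stats::median(vt$vx[ctx]) else 0
  abs((pos[j1] - pos[j0]) - base * (j1 - j0) / fs)
}

# cumulative position implied by the velocity trace (arbitrary origin),
# used for displacement amplitudes
integrate_positions <- function(vt) {
  fs <- attr(vt, "fs")
  v <- vt$vx
  v[is.na(v)] <- 0
  cumsum(v) / fs
}

#' Excise saccades and artifacts from a velocity trace
#'
#' Masks samples inside detected saccade events as `saccade`, widening each
#' event by `pad_ms` on both sides so velocity leakage from the
#' central-difference window is excised with it; blink samples are already
#' masked by [central_difference_velocity()]. Masked samples are excluded
#' from all downstream averages; no interpolation. Running removal twice
#' with the same events is a no-op.
#'
#' @param vt a `velocity_trace`.
#' @param events a `saccade_events` data.frame.
#' @param pad_ms excision guard band around each event, ms (default one
#'   sample beyond the 12 ms differentiation half-window at 250 Hz, which
#'   covers the velocity leakage of the central difference even when the
#'   event bounds sit a sample inside the true pulse).
#' @param max_masked_fraction above this fraction of non-edge samples
#'   masked, the trial is flagged unusable.
#' @return The masked `velocity_trace`, with attributes `removed_fraction`
#'   and `usable`.
#' @export
remove_saccades_and_artifacts <- function(vt, events, pad_ms = 16,
                                          max_masked_fraction = 0.5) {
  stopifnot(inherits(vt, "velocity_trace"))
  if (nrow(events) > 0) {
    for (r in seq_len(nrow(events))) {
      sel <- vt$t_ms >= events$onset_ms[r] - pad_ms &
        vt$t_ms <= events$offset_ms[r] + pad_ms & vt$mask == "ok"
      vt$mask[sel] <- "saccade"
    }
  }
  non_edge <- vt$mask != "edge"
  frac <- sum(vt$mask %in% c("saccade", "blink", "artifact")) /
    max(1L, sum(non_edge))
  attr(vt, "removed_fraction") <- frac
  attr(vt, "usable") <- frac <= max_masked_fraction
  vt
}

#' One-call preprocessing of a gaze recording
#'
#' Runs [central_difference_velocity()], [estimate_baseline_noise()],
#' [detect_saccades()] and [remove_saccades_and_artifacts()] in order.
#'
#' @param rec a `gaze_recording`.
#' @param ... passed to [detect_saccades()].
#' @return list with `trace` (masked `velocity_trace`) and `events`.
#' @export
preprocess_gaze <- function(rec, ...) {
  vt <- central_difference_velocity(rec)
  ev <- detect_saccades(vt, ...)
  list(trace = remove_saccades_and_artifacts(vt, ev), events = ev)
}

#' Write detected saccade events as TSV
#'
#' Columns `onset_ms`, `offset_ms`, `amplitude_deg`, `peak_vel_dps`, `rule`.
#'
#' @param events a `saccade_events` data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_saccade_events <- function(events, path) {
  utils::write.table(
    data.frame(onset_ms = events$onset_ms, offset_ms = events$offset_ms,
               amplitude_deg = events$amplitude,
               peak_vel_dps = events$peak_velocity,
               rule = events$detected_by),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
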