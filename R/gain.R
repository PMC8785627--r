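#' Interval segmentation of the tracking period
#'
#' Partitions `[0, duration_ms)` into consecutive half-open bins of
#' `width_ms` (default: 24 intervals of 250 ms over the 6000 ms tracking
#' period).
#'
#' @param duration_ms total duration, ms.
#' @param width_ms bin width, ms; must divide `duration_ms`.
#' @return data.frame with columns `interval` (1-based), `start_ms`,
#'   `end_ms` (half-open `[start, end)`).
#' @examples
#' nrow(interval_segments())  # 24
#' @export
interval_segments <- function(duration_ms = 6000, width_ms = 250) {
  if (duration_ms %% width_ms != 0)
    stop("`width_ms` must divide `duration_ms`", call. = FALSE)
  n <- duration_ms / width_ms
  data.frame(interval = seq_len(n),
             start_ms = (seq_len(n) - 1) * width_ms,
             end_ms = seq_len(n) * width_ms)
}

#' Smooth-pursuit velocity gain over a window
#'
#' The ratio of the average desaccaded horizontal eye velocity to the target
#' velocity over `bounds` (half-open `[start, end)` ms). Only samples with
#' mask `ok` contribute. By default the denominator is the constant
#' translation speed of the wheel centre; `instantaneous = TRUE` instead
#' divides each sample by the magnitude of the instantaneous horizontal
#' target velocity (carrier plus rotational component) before averaging, for
#' sensitivity analysis.
#'
#' @param vt a masked `velocity_trace`.
#' @param target_velocity translation speed, deg/s (> 0); defaults to the
#'   value recorded on the trace.
#' @param bounds `c(start_ms, end_ms)`.
#' @param min_samples minimum `ok` samples for a defined gain.
#' @param instantaneous use the instantaneous cycloidal denominator.
#' @param geometry,start_orientation needed only when `instantaneous`.
#' @return list with `gain` (NA when undefined) and `n_ok`.
#' @export
velocity_gain <- function(vt, target_velocity = NULL, bounds = c(0, 6000),
                          min_samples = 10L, instantaneous = FALSE,
                          geometry = NULL, start_orientation = NULL) {
  if (is.null(target_velocity)) {
    meta <- attr(vt, "meta")
    target_velocity <- if (!is.null(meta)) meta$translation_speed else NULL
  }
  if (is.null(target_velocity) || !is.finite(target_velocity) ||
      target_velocity <= 0)
    stop("`target_velocity` must be a positive number", call. = FALSE)
  sel <- vt$t_ms >= bounds[1] & vt$t_ms < bounds[2] & vt$mask == "ok"
  n_ok <- sum(sel)
  if (n_ok < min_samples) return(list(gain = NA_real_, n_ok = n_ok))
  if (instantaneous) {
    stopifnot(!is.null(geometry), !is.null(start_orientation))
    t_s <- vt$t_ms[sel] / 1000
    omega_rad <- geometry$rotation_speed * pi / 180
    theta <- (start_orientation * pi / 180) - omega_rad * t_s
    v_inst <- geometry$translation_speed + geometry$wheel_radius *
      omega_rad * sin(theta)
    g <- mean(vt$vx[sel] / abs(v_inst))
  } else {
    g <- mean(vt$vx[sel]) / target_velocity
  }
  list(gain = g, n_ok = n_ok)
}

#' Per-trial, per-interval gain table
#'
#' Computes the velocity gain of every preprocessed trial in every 250 ms
#' interval. `trials` carries one row of metadata per element of `traces`.
#'
#' @param traces list of masked `velocity_trace` objects.
#' @param trials data.frame with columns `subject`, `trial`, `background`
#'   (recycled row-wise over `traces`).
#' @param segments interval table from [interval_segments()].
#' @param min_samples minimum `ok` samples per interval.
#' @return data.frame of class `gain_table`: `subject`, `trial`,
#'   `background`, `interval`, `start_ms`, `end_ms`, `gain`, `n_ok`.
#' @export
build_gain_table <- function(traces, trials,
                             segments = interval_segments(),
                             min_samples = 10L) {
  stopifnot(length(traces) == nrow(trials))
  if (length(traces) == 0L) {
    out <- data.frame(subject = integer(0), trial = integer(0),
                      background = character(0), interval = integer(0),
                      start_ms = numeric(0), end_ms = numeric(0),
                      gain = numeric(0), n_ok = integer(0))
    class(out) <- c("gain_table", "data.frame")
    return(out)
  }
  breaks <- c(segments$start_ms, segments$end_ms[nrow(segments)])
  n_seg <- nrow(segments)
  rows <- lapply(seq_along(traces), function(i) {
    vt <- traces[[i]]
    meta <- attr(vt, "meta")
    v <- meta$translation_speed
    stopifnot(is.numeric(v), v > 0)
    ok <- vt$mask == "ok"
    bin <- findInterval(vt$t_ms, breaks, left.open = FALSE,
                        rightmost.closed = FALSE)
    use <- ok & bin >= 1L & bin <= n_seg & vt$t_ms < breaks[n_seg + 1L]
    f <- factor(bin[use], levels = seq_len(n_seg))
    n_ok <- as.integer(tabulate(f, nbins = n_seg))
    sums <- vapply(split(vt$vx[use], f), sum, numeric(1))
    gain <- ifelse(n_ok >= min_samples, sums / n_ok / v, NA_real_)
    cbind(trials[rep(i, n_seg), c("subject", "trial", "background"),
                 drop = FALSE],
          data.frame(interval = segments$interval,
                     start_ms = segments$start_ms,
                     end_ms = segments$end_ms,
                     gain = gain, n_ok = n_ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gain_table", "data.frame")
  out
}

#' Aggregate a gain table to subject x condition x interval means
#'
#' @param gt a `gain_table`.
#' @return data.frame `subject`, `background`, `interval`, `gain`
#'   (mean over that subject's usable trials).
#' @export
aggregate_gains <- function(gt) {
  ok <- !is.na(gt$gain)
  agg <- stats::aggregate(gain ~ subject + background + interval,
                          data = gt[ok, , drop = FALSE], FUN = mean)
  agg[order(agg$subject, agg$background, agg$interval), , drop = FALSE]
}

#' Write a gain table as TSV
#'
#' @param gt a `gain_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gain_table <- function(gt, path) {
  utils::write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
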