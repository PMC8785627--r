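#' Rolling-wheel stimulus geometry
#'
#' Geometry of the rolling-wheel display: a target on the rim of an imaginary
#' wheel of radius `wheel_radius` that rotates clockwise at `rotation_speed`
#' while its centre translates rightward at `translation_speed`, tracing a
#' cycloid. Eight background elements share the ring, so target plus elements
#' occupy nine equally spaced ring positions. Coordinates are degrees of
#' visual angle, origin at display centre, x rightward, y upward; time is ms
#' from tracking onset.
#'
#' By default the translation speed is derived from the trial timeline so the
#' wheel centre reaches the occluder's left edge at exactly 3000 ms and its
#' right edge at 6000 ms. With `rolling = TRUE` the translation speed is
#' instead tied to the rim's tangential speed (rolling without slipping),
#' `v = omega * pi/180 * r`, approximately 10 deg/s at the defaults.
#'
#' @param wheel_radius wheel radius, degrees (half the 3.82 deg ring diameter).
#' @param rotation_speed rotation rate, deg/s (positive = clockwise when the
#'   wheel rolls rightward).
#' @param start_x,start_y initial wheel-centre position, degrees.
#' @param occluder_left_x,occluder_right_x occluder edges, degrees.
#' @param translation_speed deg/s; `NULL` derives it from the timeline.
#' @param rolling if `TRUE`, use the rolling-without-slipping translation
#'   speed instead of the timeline-derived one.
#' @param display_w,display_h display extent, degrees.
#' @param n_elements number of background elements on the ring.
#' @param target_diameter_deg,element_size_deg sizes, metadata only.
#' @return An object of class `stimulus_geometry` (a list).
#' @examples
#' g <- stimulus_geometry()
#' g$translation_speed  # 4 deg/s: 12 deg to the occluder in 3000 ms
#' @export
stimulus_geometry <- function(wheel_radius = 1.91,
                              rotation_speed = 298.8,
                              start_x = -12, start_y = 0,
                              occluder_left_x = 0, occluder_right_x = 12,
                              translation_speed = NULL,
                              rolling = FALSE,
                              display_w = 25.99, display_h = 19.64,
                              n_elements = 8L,
                              target_diameter_deg = 0.38,
                              element_size_deg = c(0.44, 0.38)) {
  stopifnot(wheel_radius > 0, rotation_speed > 0,
            occluder_left_x < occluder_right_x,
            occluder_right_x <= display_w / 2 + 1e-9)
  if (rolling) {
    translation_speed <- rotation_speed * pi / 180 * wheel_radius
  } else if (is.null(translation_speed)) {
    translation_speed <-
      (occluder_left_x - start_x) / (trial_timeline()[["visible_ms"]] / 1000)
  }
  stopifnot(translation_speed > 0)
  structure(list(wheel_radius = wheel_radius,
                 rotation_speed = rotation_speed,
                 translation_speed = translation_speed,
                 start_x = start_x, start_y = start_y,
                 occluder_left_x = occluder_left_x,
                 occluder_right_x = occluder_right_x,
                 display_w = display_w, display_h = display_h,
                 n_elements = as.integer(n_elements),
                 target_diameter_deg = target_diameter_deg,
                 element_size_deg = element_size_deg),
            class = "stimulus_geometry")
}

#' @export
print.stimulus_geometry <- function(x, ...) {
  cat("Rolling-wheel geometry:\n")
  cat(sprintf("  radius %.2f deg, rotation %.1f deg/s, translation %.3f deg/s\n",
              x$wheel_radius, x$rotation_speed, x$translation_speed))
  cat(sprintf("  start (%.2f, %.2f), occluder [%.2f, %.2f] deg\n",
              x$start_x, x$start_y, x$occluder_left_x, x$occluder_right_x))
  invisible(x)
}

#' Target position on the rolling wheel
#'
#' Position of the tracked element at time `t`:
#' `x(t) = start_x + v t + r cos(theta(t))`,
#' `y(t) = start_y + r sin(theta(t))` with
#' `theta(t) = start_orientation - omega t` (clockwise rotation for a wheel
#' rolling rightward). Angles use the convention 0 deg = rightward,
#' 90 deg = up.
#'
#' @param t_ms time(s) in ms, >= 0; vectorized.
#' @param geometry a [stimulus_geometry()].
#' @param start_orientation wheel phase at t = 0, degrees.
#' @return matrix with columns `x`, `y` (one row per time point).
#' @export
target_position <- function(t_ms, geometry, start_orientation = 90) {
  stopifnot(all(t_ms >= 0))
  t_s <- t_ms / 1000
  theta <- (start_orientation - geometry$rotation_speed * t_s) * pi / 180
  cbind(x = geometry$start_x + geometry$translation_speed * t_s +
          geometry$wheel_radius * cos(theta),
        y = geometry$start_y + geometry$wheel_radius * sin(theta))
}

#' Background element positions
#'
#' The eight background elements ride the same ring as the target, rigidly
#' rotating with it at ring angles `start_orientation + k * 40` degrees
#' (k = 1..8), so target plus elements form nine equally spaced ring points.
#' The consistent and inconsistent backgrounds differ only in element shape
#' labels, not kinematics; the blank background has no elements.
#'
#' @param t_ms a single time in ms.
#' @param geometry a [stimulus_geometry()].
#' @param background `"blank"`, `"inconsistent"` or `"consistent"`.
#' @param start_orientation wheel phase at t = 0, degrees.
#' @return matrix with columns `x`, `y`; zero rows for the blank background.
#' @export
element_positions <- function(t_ms, geometry,
                              background = c("consistent", "inconsistent",
                                             "blank"),
                              start_orientation = 90) {
  background <- match.arg(background)
  if (background == "blank")
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  k <- seq_len(geometry$n_elements)
  spacing <- 360 / (geometry$n_elements + 1)
  t_s <- t_ms / 1000
  theta <- (start_orientation + k * spacing -
              geometry$rotation_speed * t_s) * pi / 180
  cbind(x = geometry$start_x + geometry$translation_speed * t_s +
          geometry$wheel_radius * cos(theta),
        y = geometry$start_y + geometry$wheel_radius * sin(theta))
}

#' Synthesize a full stimulus trajectory
#'
#' Samples target and element positions on a regular grid (default 250 Hz,
#' matching the gaze clock), marks visibility (an element disappears when its
#' own x first crosses the occluder's left edge; the target's ground-truth
#' occlusion uses the wheel centre), and records the ground-truth occlusion
#' events.
#'
#' @param geometry a [stimulus_geometry()].
#' @param start_orientation wheel phase at t = 0, degrees.
#' @param background background condition (element kinematics are identical
#'   for consistent/inconsistent; blank has no elements).
#' @param duration_ms tracking duration, ms.
#' @param fs sampling rate, Hz.
#' @return Object of class `trajectory`: list with `t_ms`, `center_x`,
#'   `target_x`, `target_y`, `target_visible`, `element_x`/`element_y`
#'   (matrices frame x element), `element_visible`, `t_entry`, `t_arrival`,
#'   `geometry`, `background`, `start_orientation`.
#' @examples
#' tr <- make_trajectory(stimulus_geometry(), 90, "consistent")
#' c(tr$t_entry, tr$t_arrival)  # 3000 6000
#' @export
make_trajectory <- function(geometry = stimulus_geometry(),
                            start_orientation = 90,
                            background = c("consistent", "inconsistent",
                                           "blank"),
                            duration_ms = 6000, fs = 250) {
  background <- match.arg(background)
  dt <- 1000 / fs
  t_ms <- seq(0, duration_ms, by = dt)
  t_ms <- t_ms[t_ms < duration_ms + dt / 2]
  pos <- target_position(t_ms, geometry, start_orientation)
  center_x <- geometry$start_x + geometry$translation_speed * t_ms / 1000
  ev <- occlusion_events_center(center_x, t_ms, geometry)

  n_el <- if (background == "blank") 0L else geometry$n_elements
  if (n_el > 0L) {
    spacing <- 360 / (geometry$n_elements + 1)
    k <- seq_len(n_el)
    theta <- outer(t_ms / 1000, k,
                   function(ts, kk) (start_orientation + kk * spacing -
                                       geometry$rotation_speed * ts) * pi / 180)
    element_x <- center_x + geometry$wheel_radius * cos(theta)
    element_y <- geometry$start_y + geometry$wheel_radius * sin(theta)
    # visible until the element's own x first crosses the occluder edge
    element_visible <- apply(element_x >= geometry$occluder_left_x, 2,
                             function(z) cummax(z) == 0)
  } else {
    element_x <- element_y <- matrix(numeric(0), nrow = length(t_ms), ncol = 0)
    element_visible <- matrix(logical(0), nrow = length(t_ms), ncol = 0)
  }

  structure(list(t_ms = t_ms,
                 center_x = center_x,
                 target_x = pos[, "x"], target_y = pos[, "y"],
                 target_visible = t_ms < ev[["t_entry"]],
                 element_x = element_x, element_y = element_y,
                 element_visible = element_visible,
                 t_entry = ev[["t_entry"]], t_arrival = ev[["t_arrival"]],
                 fs = fs, geometry = geometry, background = background,
                 start_orientation = start_orientation),
            class = "trajectory")
}

occlusion_events_center <- function(center_x, t_ms, geometry) {
  v <- geometry$translation_speed
  t_entry <- (geometry$occluder_left_x - geometry$start_x) / v * 1000
  t_arrival <- (geometry$occluder_right_x - geometry$start_x) / v * 1000
  if (t_entry > max(t_ms) + 1e-9)
    stop("trajectory never reaches the occluder", call. = FALSE)
  c(t_entry = max(t_entry, 0), t_arrival = t_arrival)
}

#' Ground-truth occlusion events of a trajectory
#'
#' Entry is the first time the wheel centre reaches the occluder's left edge;
#' arrival the first time it reaches the right edge (where the target would
#' reappear, though it never does). Under the default geometry these are
#' 3000 ms and 6000 ms.
#'
#' @param trajectory a [make_trajectory()] result.
#' @return named numeric vector `c(t_entry, t_arrival)` in ms.
#' @export
occlusion_events <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  c(t_entry = trajectory$t_entry, t_arrival = trajectory$t_arrival)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames at %g Hz, background %s\n",
              length(x$t_ms), x$fs, x$background))
  cat(sprintf("  occluder entry %.0f ms, arrival %.0f ms\n",
              x$t_entry, x$t_arrival))
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Columns: `t_ms`, `target_x_deg`, `target_y_deg`, `visible`, then for each
#' element `element_<k>_x`, `element_<k>_y`, `element_<k>_visible`.
#'
#' @param trajectory a `trajectory`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- data.frame(t_ms = trajectory$t_ms,
                   target_x_deg = trajectory$target_x,
                   target_y_deg = trajectory$target_y,
                   visible = trajectory$target_visible)
  n_el <- ncol(trajectory$element_x)
  for (k in seq_len(n_el)) {
    df[[sprintf("element_%d_x", k)]] <- trajectory$element_x[, k]
    df[[sprintf("element_%d_y", k)]] <- trajectory$element_y[, k]
    df[[sprintf("element_%d_visible", k)]] <- trajectory$element_visible[, k]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
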