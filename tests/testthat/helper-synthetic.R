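# shared fixtures, all built in code

# wrap a raw horizontal position series into a gaze_recording
make_rec <- function(x, fs = 250, valid = rep(TRUE, length(x))) {
  rec <- data.frame(t_ms = (seq_along(x) - 1) * 1000 / fs,
                    x = x, y = 0, valid = valid)
  attr(rec, "fs") <- fs
  class(rec) <- c("gaze_recording", "data.frame")
  rec
}

# the velocity the central-difference operator reports for a known
# sample-wise velocity series: mean of the 2k samples (i-k+1)..(i+k),
# because positions are cumulative sums of per-sample velocities
measured_smooth <- function(vx, k) {
  n <- length(vx)
  out <- rep(NA_real_, n)
  cs <- cumsum(vx)
  i <- (k + 1):(n - k)
  out[i] <- (cs[i + k] - cs[i - k]) / (2 * k)
  out
}

# mask-aware expected per-interval gains implied by a ground-truth gain
# profile, given the trace actually produced (its mask and k)
expected_bin_gains <- function(g_profile, vt,
                               segments = interval_segments()) {
  k <- attr(vt, "k")
  sm <- measured_smooth(g_profile, k)
  vapply(seq_len(nrow(segments)), function(j) {
    sel <- vt$t_ms >= segments$start_ms[j] & vt$t_ms < segments$end_ms[j] &
      vt$mask == "ok"
    mean(sm[sel])
  }, numeric(1))
}

# match detected saccade events against injected ground truth; returns
# counts and signed onset errors (ms)
match_saccades <- function(events, truth, slack_ms = 24) {
  matched <- rep(FALSE, nrow(events))
  tp <- 0L; fn <- 0L
  onset_err <- numeric(0)
  for (j in seq_len(nrow(truth))) {
    hit <- which(!matched &
                   events$onset_ms <= truth$offset_ms[j] + slack_ms &
                   events$offset_ms >= truth$onset_ms[j] - slack_ms)
    if (length(hit) > 0) {
      matched[hit[1]] <- TRUE
      tp <- tp + 1L
      onset_err <- c(onset_err, events$onset_ms[hit[1]] - truth$onset_ms[j])
    } else fn <- fn + 1L
  }
  list(tp = tp, fn = fn, fp = sum(!matched), onset_err = onset_err)
}

# run the injected-saccade detection suite: n_trials trials, amplitudes
# uniform in amp_range, forced at fixed well-separated onsets
run_detection_suite <- function(n_trials, amp_range = c(0.5, 3),
                                seed = 20, noise_sd = 2) {
  params <- observer_params(noise_sd = noise_sd,
                            saccade_trigger_error = Inf, blink_rate = 0)
  traj <- make_trajectory()
  onsets <- c(700, 1600, 2500, 4200, 5100)
  set.seed(seed)
  tp <- 0L; fn <- 0L; fp <- 0L
  onset_err <- numeric(0)
  bias_num <- 0; bias_den <- 0
  for (i in seq_len(n_trials)) {
    amps <- stats::runif(length(onsets), amp_range[1], amp_range[2])
    forced <- data.frame(onset_ms = onsets, amplitude = amps)
    rec <- simulate_gaze(traj, params, seed = NULL,
                         forced_saccades = forced)
    pp <- preprocess_gaze(rec)
    m <- match_saccades(pp$events, attr(rec, "truth")$saccades)
    tp <- tp + m$tp; fn <- fn + m$fn; fp <- fp + m$fp
    onset_err <- c(onset_err, m$onset_err)
    vt <- pp$trace
    sel <- vt$mask == "ok"
    g <- attr(rec, "truth")$gain
    v <- traj$geometry$translation_speed
    bias_num <- bias_num + sum(vt$vx[sel])
    bias_den <- bias_den + sum(measured_smooth(g * v, attr(vt, "k"))[sel])
  }
  list(f1 = 2 * tp / (2 * tp + fp + fn),
       median_onset_err = stats::median(abs(onset_err)),
       tp = tp, fp = fp, fn = fn,
       velocity_bias = bias_num / bias_den - 1)
}

# a random balanced within-subject dataset (pure noise)
random_ws_design <- function(n_subj, levels, seed,
                             factor_names = letters[seq_along(levels)]) {
  set.seed(seed)
  args <- c(list(subject = seq_len(n_subj)),
            stats::setNames(lapply(levels, function(l)
              paste0("L", seq_len(l))), factor_names))
  d <- do.call(expand.grid, c(args, stringsAsFactors = FALSE))
  d$y <- rnorm(nrow(d))
  d
}

# within-subject ANOVA oracle: stats::aov with Error() strata
aov_oracle <- function(data, dv, within, subject = "subject") {
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  rhs <- paste(within, collapse = "*")
  f <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))", dv, rhs,
                                 subject, rhs))
  fit <- summary(stats::aov(f, data = data))
  out <- list()
  for (stratum in fit) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      eff <- paste(strsplit(terms[i], ":")[[1]], collapse = ":")
      out[[eff]] <- list(ss = tab$`Sum Sq`[i],
                         ss_err = tab$`Sum Sq`[terms == "Residuals"],
                         F = tab$`F value`[i],
                         p = tab$`Pr(>F)`[i])
    }
  }
  out
}

# simulate one scaled-down group experiment's per-trial timing errors
simulate_ce_experiment <- function(n_subjects, n_trials, params, seed) {
  backgrounds <- c("blank", "inconsistent", "consistent")
  traj <- lapply(backgrounds, function(bg)
    make_trajectory(background = bg))
  names(traj) <- backgrounds
  rows <- vector("list", n_subjects * 3L * n_trials)
  r <- 0L
  for (s in seq_len(n_subjects)) {
    set.seed(seed + 7919L * s)
    sp <- subject_params(params)
    for (bg in backgrounds) {
      for (tr in seq_len(n_trials)) {
        resp <- simulate_response(traj[[bg]], sp,
                                  seed = seed + 104729L * s + 389L * tr +
                                    match(bg, backgrounds))
        e <- trial_errors(resp$press1_ms, resp$press2_ms,
                          traj[[bg]]$t_entry, traj[[bg]]$t_arrival)
        r <- r + 1L
        rows[[r]] <- data.frame(subject = s, background = bg, trial = tr,
                                e_visible = e[["e_visible"]],
                                e_occluded = e[["e_occluded"]])
      }
    }
  }
  do.call(rbind, rows[seq_len(r)])
}
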