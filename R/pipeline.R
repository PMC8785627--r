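#' Run configuration for a simulated experiment
#'
#' Bundles everything one reproducible end-to-end run needs. Trial counts
#' default to scaled-down versions of the full sessions (the full designs
#' are available through [design_config()] / [enumerate_trials()]); gaze
#' simulation and preprocessing are the expensive stages, so the number of
#' gaze trials per condition is controlled separately from the number of
#' button-press trials per condition.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param n_subjects number of simulated subjects (defaults: 25 for exp1,
#'   22 for exp2).
#' @param n_response_trials button-press trials per condition per subject.
#' @param n_gaze_trials gaze trials per condition per subject.
#' @param params group-level [observer_params()].
#' @param geometry [stimulus_geometry()].
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir if non-NULL, stage outputs are persisted there as TSV/CSV.
#' @return list of class `run_config`.
#' @export
run_config <- function(experiment = c("exp2", "exp1"),
                       n_subjects = NULL,
                       n_response_trials = 20L,
                       n_gaze_trials = 2L,
                       params = observer_params(),
                       geometry = stimulus_geometry(),
                       seed = 1L,
                       out_dir = NULL) {
  experiment <- match.arg(experiment)
  if (is.null(n_subjects))
    n_subjects <- if (experiment == "exp1") 25L else 22L
  structure(list(experiment = experiment,
                 n_subjects = as.integer(n_subjects),
                 n_response_trials = as.integer(n_response_trials),
                 n_gaze_trials = as.integer(n_gaze_trials),
                 params = params, geometry = geometry,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i) %% 2147483647
  as.integer(s)
}

#' Simulate, preprocess and score one experiment
#'
#' Runs the full chain for a group of synthetic subjects: per-subject
#' parameter draws, trial simulation (button presses for the timing
#' analysis; gaze for the pursuit analysis), preprocessing, CE/VE tables
#' with 3-SD trimming, the per-interval gain table, within-subject ANOVAs,
#' Bonferroni pairwise comparisons and the 24-interval univariate table.
#' Fully deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return list of class `run_report` with elements `errors` (per-trial),
#'   `error_table`, `ce_summary`, `ve_summary`, `anova_ce`, `anova_ve`,
#'   `pairwise_ce`, `gain_table`, `gains` (subject-level means),
#'   `interval_table`, `qc` (masked fraction, outlier fraction), `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  backgrounds <- c("blank", "inconsistent", "consistent")
  shapes <- if (config$experiment == "exp1") c("circle", "triangle")
            else "circle"
  orientations <- c(0, 90, 180, 270)
  trajs <- lapply(orientations, function(o)
    lapply(backgrounds, function(bg)
      make_trajectory(config$geometry, o, bg)))
  names(trajs) <- as.character(orientations)
  for (i in seq_along(trajs)) names(trajs[[i]]) <- backgrounds

  err_rows <- list()
  traces <- list()
  trial_meta <- list()
  removed_fracs <- numeric(0)
  n_excluded_presses <- 0L

  for (s in seq_len(config$n_subjects)) {
    set.seed(derive_seed(config$seed, s, 1L))
    sp <- subject_params(config$params)
    for (bg_i in seq_along(backgrounds)) {
      bg <- backgrounds[bg_i]
      for (sh_i in seq_along(shapes)) {
        sh <- shapes[sh_i]
        for (tr in seq_len(config$n_response_trials)) {
          ori <- orientations[(tr - 1L) %% 4L + 1L]
          traj <- trajs[[as.character(ori)]][[bg]]
          resp <- simulate_response(
            traj, sp, seed = derive_seed(config$seed, s, bg_i, sh_i, tr, 2L))
          e <- trial_errors(resp$press1_ms, resp$press2_ms,
                            traj$t_entry, traj$t_arrival)
          err_rows[[length(err_rows) + 1L]] <- data.frame(
            subject = s, background = bg, target_shape = sh, trial = tr,
            e_visible = e[["e_visible"]], e_occluded = e[["e_occluded"]])
        }
        if (sh_i == 1L) {
          for (tr in seq_len(config$n_gaze_trials)) {
            ori <- orientations[(tr - 1L) %% 4L + 1L]
            traj <- trajs[[as.character(ori)]][[bg]]
            rec <- simulate_gaze(
              traj, sp, seed = derive_seed(config$seed, s, bg_i, tr, 3L))
            pp <- preprocess_gaze(rec)
            traces[[length(traces) + 1L]] <- pp$trace
            trial_meta[[length(trial_meta) + 1L]] <- data.frame(
              subject = s, trial = tr, background = bg)
            removed_fracs <- c(removed_fracs,
                               attr(pp$trace, "removed_fraction"))
          }
        }
      }
    }
  }

  errors <- do.call(rbind, err_rows)
  et <- build_error_table(errors)
  n_excluded_presses <- sum(et$n_excluded)

  # phase x background cell means per subject (shapes averaged out for the
  # exp2-style 2 x 3 ANOVA; the full 2 x 3 x 2 table is available for exp1)
  ce_cells <- stats::aggregate(ce ~ subject + phase + background, data = et,
                               FUN = mean)
  ve_cells <- stats::aggregate(ve ~ subject + phase + background, data = et,
                               FUN = mean)
  anova_within <- c("phase", "background")
  if (config$experiment == "exp1") {
    ce_cells3 <- stats::aggregate(ce ~ subject + phase + background +
                                    target_shape, data = et, FUN = mean)
    anova_ce <- rm_anova(ce_cells3, "ce",
                         c("phase", "background", "target_shape"))
    ve_cells3 <- stats::aggregate(ve ~ subject + phase + background +
                                    target_shape, data = et, FUN = mean)
    anova_ve <- rm_anova(ve_cells3, "ve",
                         c("phase", "background", "target_shape"))
  } else {
    anova_ce <- rm_anova(ce_cells, "ce", anova_within)
    anova_ve <- rm_anova(ve_cells, "ve", anova_within)
  }
  ce_by_bg <- stats::aggregate(ce ~ subject + background, data = ce_cells,
                               FUN = mean)
  pairwise_ce <- pairwise_bonferroni(ce_by_bg, "ce", "background")

  gt <- build_gain_table(traces, do.call(rbind, trial_meta))
  gains <- aggregate_gains(gt)
  interval_table <- interval_univariate(gains)

  report <- list(errors = errors, error_table = et,
                 ce_summary = summarize_errors(et, "ce"),
                 ve_summary = summarize_errors(et, "ve"),
                 anova_ce = anova_ce, anova_ve = anova_ve,
                 pairwise_ce = pairwise_ce,
                 gain_table = gt, gains = gains,
                 interval_table = interval_table,
                 qc = list(
                   mean_masked_fraction = mean(removed_fracs),
                   outlier_fraction = n_excluded_presses /
                     max(1L, nrow(errors) * 2L)),
                 config = config)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) persist_report(report, config$out_dir)
  report
}

persist_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$errors, file.path(dir, "trial_errors.csv"),
                   row.names = FALSE)
  write_error_table(report$error_table, file.path(dir, "error_table.tsv"))
  write_gain_table(report$gain_table, file.path(dir, "gain_table.tsv"))
  utils::write.table(as.data.frame(report$anova_ce),
                     file.path(dir, "anova_ce.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$anova_ve),
                     file.path(dir, "anova_ve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$pairwise_ce, file.path(dir, "pairwise_ce.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$interval_table,
                     file.path(dir, "interval_univariate.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated %s run: %d subjects, %d response + %d gaze trials per condition\n",
              cfg$experiment, cfg$n_subjects, cfg$n_response_trials,
              cfg$n_gaze_trials))
  cat("\nConstant error (ms), mean over subjects:\n")
  print(x$ce_summary, row.names = FALSE)
  cat("\nCE ANOVA:\n")
  print(x$anova_ce)
  cat("\nIntervals with a significant consistency effect:",
      paste(x$interval_table$interval[x$interval_table$significant],
            collapse = ", "), "\n")
  cat(sprintf("\nQC: %.1f%% of samples masked, %.2f%% of presses trimmed\n",
              100 * x$qc$mean_masked_fraction,
              100 * x$qc$outlier_fraction))
  invisible(x)
}
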