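#' Per-trial timing errors
#'
#' Signed timing errors of the two judgments of a trial, with the
#' convention `error = estimated - actual` (positive = late, negative =
#' anticipation). The visible-phase error references the occluder-entry
#' time, the occluded-phase error the ground-truth arrival time.
#'
#' @param press1_ms,press2_ms button-press times, ms (NA drops the trial).
#' @param t_entry,t_arrival ground-truth event times, ms.
#' @param convention `"estimated_minus_actual"` (default) or
#'   `"actual_minus_estimated"`.
#' @return named numeric vector `c(e_visible, e_occluded)` in ms.
#' @examples
#' trial_errors(3150, 6000, 3000, 6000)  # e_visible 150, e_occluded 0
#' @export
trial_errors <- function(press1_ms, press2_ms, t_entry, t_arrival,
                         convention = c("estimated_minus_actual",
                                        "actual_minus_estimated")) {
  convention <- match.arg(convention)
  s <- if (convention == "estimated_minus_actual") 1 else -1
  c(e_visible = s * (press1_ms - t_entry),
    e_occluded = s * (press2_ms - t_arrival))
}

#' Trim outliers at k standard deviations
#'
#' Single-pass exclusion of values outside `mean +/- k * SD`, both moments
#' computed on the unfiltered set. With SD zero only exact ties with the
#' mean are retained (vacuously, all values).
#'
#' @param x numeric vector of errors (one subject, one condition).
#' @param k SD multiplier (default 3; `Inf` disables trimming).
#' @return list with `kept`, `n_excluded`.
#' @export
exclude_outliers <- function(x, k = 3) {
  x <- x[!is.na(x)]
  if (length(x) < 3L)
    stop("need at least 3 trials to trim outliers", call. = FALSE)
  if (!is.finite(k)) return(list(kept = x, n_excluded = 0L))
  m <- mean(x)
  s <- stats::sd(x)
  keep <- if (s == 0) x == m else abs(x - m) <= k * s
  list(kept = x[keep], n_excluded = sum(!keep))
}

#' Constant and variable error
#'
#' CE is the arithmetic mean of the (trimmed) signed errors; VE their sample
#' standard deviation (n - 1 denominator).
#'
#' @param x numeric vector of trimmed errors, length >= 2 for a defined VE.
#' @return list with `ce`, `ve` (NA and flagged if n < 2), `n`.
#' @examples
#' ce_ve(c(90, 110))  # ce 100, ve 14.14
#' @export
ce_ve <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L)
    return(list(ce = if (length(x)) mean(x) else NA_real_,
                ve = NA_real_, n = length(x)))
  list(ce = mean(x), ve = stats::sd(x), n = length(x))
}

#' Per-subject, per-condition error table
#'
#' Applies the 3-SD trimming and CE/VE computation to per-trial errors,
#' within each subject x phase x background (x target shape, if present)
#' cell.
#'
#' @param errors data.frame with columns `subject`, `background`, optionally
#'   `target_shape`, `e_visible`, `e_occluded` (ms; one row per trial).
#' @param k trimming multiplier, SDs.
#' @return data.frame of class `error_table`: `subject`, `phase`,
#'   `background` (and `target_shape` if supplied), `ce`, `ve`,
#'   `n_trials_used`, `n_excluded`.
#' @export
build_error_table <- function(errors, k = 3) {
  stopifnot(all(c("subject", "background", "e_visible", "e_occluded") %in%
                  names(errors)))
  keys <- intersect(c("subject", "background", "target_shape"),
                    names(errors))
  cells <- unique(errors[keys])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(errors))
    for (kk in keys) sel <- sel & errors[[kk]] == cells[[kk]][i]
    do.call(rbind, lapply(c("visible", "occluded"), function(phase) {
      x <- errors[[paste0("e_", phase)]][sel]
      tr <- exclude_outliers(x, k = k)
      cv <- ce_ve(tr$kept)
      cbind(cells[i, , drop = FALSE],
            data.frame(phase = phase, ce = cv$ce, ve = cv$ve,
                       n_trials_used = cv$n, n_excluded = tr$n_excluded))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("error_table", "data.frame")
  out
}

#' Group summary of an error table
#'
#' Means and standard deviations of per-subject CE (or VE) across subjects,
#' per phase x background (x target shape) cell -- the layout of the
#' published condition tables.
#'
#' @param et an `error_table`.
#' @param measure `"ce"` or `"ve"`.
#' @return data.frame with `phase`, `background` (and `target_shape`),
#'   `mean`, `sd`, `n_subjects`.
#' @export
summarize_errors <- function(et, measure = c("ce", "ve")) {
  measure <- match.arg(measure)
  keys <- intersect(c("phase", "background", "target_shape"), names(et))
  f <- stats::as.formula(paste(measure, "~",
                               paste(keys, collapse = " + ")))
  m <- stats::aggregate(f, data = et, FUN = mean)
  s <- stats::aggregate(f, data = et, FUN = stats::sd)
  n <- stats::aggregate(f, data = et, FUN = length)
  out <- m
  names(out)[names(out) == measure] <- "mean"
  out$sd <- s[[measure]]
  out$n_subjects <- n[[measure]]
  out
}

#' Write an error table as TSV
#'
#' @param et an `error_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_error_table <- function(et, path) {
  utils::write.table(et, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
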