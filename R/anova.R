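#' Repeated-measures (within-subject) ANOVA
#'
#' Full factorial decomposition of a balanced, complete within-subject
#' design, computed from first principles. For each effect (any non-empty
#' subset of the within factors) the effect estimates are obtained by
#' inclusion-exclusion over marginal means, the sum of squares is the
#' replication-weighted sum of their squares, and the error stratum is the
#' corresponding effect-by-subject interaction:
#' `F = MS_effect / MS_(effect x subject)` with
#' `df1 = prod(levels - 1)` and `df2 = df1 * (n_subjects - 1)`.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`. No
#' sphericity correction is applied by default; `gg_correction = TRUE`
#' applies Greenhouse-Geisser to each multi-df effect.
#'
#' @param data data.frame of cell means: one row per subject x cell.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor columns.
#' @param subject name of the subject identifier column.
#' @param gg_correction apply the Greenhouse-Geisser epsilon to the dfs and
#'   p-value of effects with `df1 > 1`.
#' @return Object of class `rm_anova`: data.frame with one row per effect
#'   (`effect`, `df1`, `df2`, `ss_effect`, `ss_error`, `F`, `p`,
#'   `partial_eta_sq`, and `epsilon` when corrected), plus attributes
#'   `n_subjects` and `factors`.
#' @examples
#' d <- expand.grid(subject = 1:6, a = c("x", "y"), b = c("p", "q", "r"))
#' set.seed(1); d$y <- rnorm(nrow(d))
#' rm_anova(d, "y", c("a", "b"))
#' @export
rm_anova <- function(data, dv, within, subject = "subject",
                     gg_correction = FALSE) {
  stopifnot(all(c(dv, within, subject) %in% names(data)))
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  levs <- vapply(within, function(w) nlevels(data[[w]]), integer(1))
  n_subj <- nlevels(data[[subject]])
  n_cells <- prod(levs)
  if (nrow(data) != n_subj * n_cells ||
      anyDuplicated(data[c(subject, within)]) > 0 ||
      anyNA(data[[dv]]))
    stop("design must be complete and balanced (one value per subject ",
         "per cell, no missing cells); imputation refused", call. = FALSE)
  if (n_subj < 2L) stop("need at least 2 subjects", call. = FALSE)

  y <- data[[dv]]
  N <- length(y)
  # marginal-mean cache keyed by sorted factor subsets (subject included
  # as a pseudo-factor for the error strata)
  marg <- function(facs) {
    if (length(facs) == 0L) return(mean(y))
    tapply(y, data[facs], mean)
  }
  subsets <- function(v) {
    if (length(v) == 0L) return(list(character(0)))
    unlist(lapply(0:length(v), function(m)
      utils::combn(v, m, simplify = FALSE)), recursive = FALSE)
  }
  ss_term <- function(facs) {
    # inclusion-exclusion effect estimates on the term's level grid
    grid <- marg(facs)
    delta <- array(0, dim = dim(grid), dimnames = dimnames(grid))
    for (s in subsets(facs)) {
      m_s <- marg(s)
      sign_ <- (-1)^(length(facs) - length(s))
      if (length(s) == 0L) {
        delta <- delta + sign_ * m_s
      } else {
        perm <- match(s, facs)
        expand <- m_s[as.vector(slice.index(delta, perm))]
        dim(expand) <- dim(delta)
        delta <- delta + sign_ * expand
      }
    }
    reps <- N / length(grid)
    reps * sum(delta^2)
  }

  effects <- subsets(within)
  effects <- effects[lengths(effects) > 0L]
  rows <- lapply(effects, function(eff) {
    ss_e <- ss_term(eff)
    ss_err <- ss_term(c(eff, subject))
    df1 <- prod(levs[eff] - 1)
    df2 <- df1 * (n_subj - 1)
    Fv <- if (ss_e == 0) 0 else (ss_e / df1) / (ss_err / df2)
    eps <- 1
    df1a <- df1; df2a <- df2
    if (gg_correction && df1 > 1) {
      eps <- gg_epsilon(data, dv, eff, subject)
      df1a <- df1 * eps; df2a <- df2 * eps
    }
    data.frame(effect = paste(eff, collapse = ":"),
               df1 = df1, df2 = df2,
               ss_effect = ss_e, ss_error = ss_err,
               F = Fv,
               p = stats::pf(Fv, df1a, df2a, lower.tail = FALSE),
               partial_eta_sq = partial_eta_sq(ss_e, ss_err),
               epsilon = eps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!gg_correction) out$epsilon <- NULL
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  attr(out, "n_subjects") <- n_subj
  attr(out, "factors") <- levs
  out
}

# Greenhouse-Geisser epsilon for one effect, from the covariance matrix of
# the subject-by-effect cell means (averaged over the other factors)
gg_epsilon <- function(data, dv, eff, subject) {
  m <- tapply(data[[dv]], data[c(subject, eff)], mean)
  m <- matrix(m, nrow = dim(m)[1])
  S <- stats::cov(m)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  SC <- C %*% S %*% C
  sum(diag(SC))^2 / ((k - 1) * sum(SC^2))
}

#' @export
print.rm_anova <- function(x, digits = 3, ...) {
  cat(sprintf("Within-subject ANOVA (%d subjects)\n",
              attr(x, "n_subjects")))
  df <- as.data.frame(x)
  df$F <- round(df$F, digits)
  df$p <- signif(df$p, digits)
  df$partial_eta_sq <- round(df$partial_eta_sq, digits)
  df$ss_effect <- df$ss_error <- NULL
  print(df, row.names = FALSE)
  invisible(x)
}

#' Partial eta squared
#'
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param ss_effect,ss_error sums of squares, both >= 0 and not both 0.
#' @return the effect-size ratio in `[0, 1]`; `NA` (with a warning) when
#'   both inputs are zero.
#' @examples
#' partial_eta_sq(10, 30)  # 0.25
#' @export
partial_eta_sq <- function(ss_effect, ss_error) {
  stopifnot(ss_effect >= 0, ss_error >= 0)
  if (ss_effect == 0 && ss_error == 0) {
    warning("both sums of squares are zero; effect size undefined")
    return(NA_real_)
  }
  ss_effect / (ss_effect + ss_error)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Paired t-tests between all level pairs of a within-subject factor, with
#' p-values multiplied by the number of comparisons (capped at 1) and
#' confidence intervals widened to the Bonferroni-adjusted level
#' `1 - alpha / m`, so interval and adjusted p agree.
#'
#' @param data data.frame with one row per subject x level.
#' @param dv dependent-variable column name.
#' @param factor_name within-subject factor column name.
#' @param subject subject column name.
#' @param alpha family-wise error rate.
#' @return data.frame with `pair`, `mean_diff`, `ci_lower`, `ci_upper`,
#'   `t`, `df`, `p_raw`, `p_adjusted`.
#' @export
pairwise_bonferroni <- function(data, dv, factor_name, subject = "subject",
                                alpha = 0.05) {
  data[[subject]] <- factor(data[[subject]])
  levs <- unique(as.character(data[[factor_name]]))
  if (nlevels(data[[subject]]) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- data[data[[factor_name]] == pr[1], c(subject, dv)]
    b <- data[data[[factor_name]] == pr[2], c(subject, dv)]
    mrg <- merge(a, b, by = subject)
    d <- mrg[[paste0(dv, ".x")]] - mrg[[paste0(dv, ".y")]]
    if (stats::sd(d) == 0) {
      # degenerate pair: identical differences across subjects
      p_raw <- if (mean(d) == 0) 1 else 0
      return(data.frame(pair = paste(pr, collapse = " - "),
                        mean_diff = mean(d),
                        ci_lower = mean(d), ci_upper = mean(d),
                        t = if (mean(d) == 0) 0 else Inf,
                        df = length(d) - 1, p_raw = p_raw,
                        p_adjusted = min(1, p_raw * m),
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(d, conf.level = 1 - alpha / m)
    data.frame(pair = paste(pr, collapse = " - "),
               mean_diff = mean(d),
               ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_adjusted = min(1, tt$p.value * m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-interval univariate tests of the consistency effect
#'
#' For each time interval, a one-way analysis across the background
#' conditions treating the subject x condition interval means as
#' observations (with 22 subjects and 3 conditions: df 2 and 63). No
#' correction across intervals is applied by default;
#' `bonferroni_intervals = TRUE` multiplies the p-values by the number of
#' intervals.
#'
#' @param gains subject x condition x interval means, e.g. from
#'   [aggregate_gains()]: columns `subject`, `background`, `interval`,
#'   `gain`.
#' @param alpha flagging threshold.
#' @param bonferroni_intervals correct p across intervals.
#' @return data.frame with one row per interval: `interval`, `df1`, `df2`,
#'   `F`, `p`, `significant`.
#' @export
interval_univariate <- function(gains, alpha = 0.05,
                                bonferroni_intervals = FALSE) {
  stopifnot(all(c("subject", "background", "interval", "gain") %in%
                  names(gains)))
  ivs <- sort(unique(gains$interval))
  rows <- lapply(ivs, function(iv) {
    d <- gains[gains$interval == iv, , drop = FALSE]
    fit <- stats::anova(stats::lm(gain ~ factor(background), data = d))
    data.frame(interval = iv, df1 = fit$Df[1], df2 = fit$Df[2],
               F = fit$`F value`[1], p = fit$`Pr(>F)`[1])
  })
  out <- do.call(rbind, rows)
  if (bonferroni_intervals) out$p <- pmin(1, out$p * nrow(out))
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
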