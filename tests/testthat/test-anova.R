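test_that("within-subject F equals the aov Error-strata oracle", {
  configs <- list(list(n = 5, lv = c(2, 3)),
                  list(n = 8, lv = 3),
                  list(n = 6, lv = c(2, 2, 2)),
                  list(n = 4, lv = c(4, 2)))
  for (cfg in configs) {
    for (s in 1:5) {
      d <- random_ws_design(cfg$n, cfg$lv, seed = 100 * s + cfg$n)
      within <- setdiff(names(d), c("subject", "y"))
      mine <- rm_anova(d, "y", within)
      orc <- aov_oracle(d, "y", within)
      for (i in seq_len(nrow(mine))) {
        eff <- mine$effect[i]
        expect_equal(mine$ss_effect[i], orc[[eff]]$ss, tolerance = 1e-10)
        expect_equal(mine$ss_error[i], orc[[eff]]$ss_err, tolerance = 1e-10)
        expect_equal(mine$F[i], orc[[eff]]$F, tolerance = 1e-10)
        expect_equal(mine$p[i], orc[[eff]]$p, tolerance = 1e-10)
      }
    }
  }
})

test_that("flat cell means give zero effect sums of squares", {
  d <- expand.grid(subject = 1:6, a = c("x", "y"), b = c("p", "q", "r"),
                   stringsAsFactors = FALSE)
  d$y <- 2 + 0.5 * d$subject  # subject offsets only, no condition effects
  fit <- suppressWarnings(rm_anova(d, "y", c("a", "b")))
  expect_true(all(fit$ss_effect < 1e-20))
  expect_true(all(fit$F == 0))
})

test_that("degrees of freedom follow the factorial structure", {
  d <- random_ws_design(25, c(2, 3, 2), seed = 1,
                        factor_names = c("phase", "bg", "shape"))
  fit <- rm_anova(d, "y", c("phase", "bg", "shape"))
  expect_equal(fit$df1[fit$effect == "phase"], 1)
  expect_equal(fit$df2[fit$effect == "phase"], 24)
  expect_equal(fit$df1[fit$effect == "bg"], 2)
  expect_equal(fit$df2[fit$effect == "bg"], 48)
  expect_equal(fit$df1[fit$effect == "phase:bg:shape"], 2)
  expect_equal(fit$df2[fit$effect == "phase:bg:shape"], 48)
  expect_true(all(fit$partial_eta_sq >= 0 & fit$partial_eta_sq <= 1))
})

test_that("incomplete designs are refused, not imputed", {
  d <- random_ws_design(5, c(2, 3), seed = 2)
  expect_error(rm_anova(d[-1, ], "y", c("a", "b")), "balanced")
  d2 <- d
  d2$y[3] <- NA
  expect_error(rm_anova(d2, "y", c("a", "b")), "balanced")
})

test_that("null simulations keep the nominal type-I rate", {
  reps <- 400
  p_main <- vapply(seq_len(reps), function(r) {
    d <- random_ws_design(22, 3, seed = 5000 + r)
    rm_anova(d, "y", "a")$p[1]
  }, numeric(1))
  rate <- mean(p_main < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("partial eta squared matches its closed form", {
  expect_equal(partial_eta_sq(10, 30), 0.25)
  expect_equal(partial_eta_sq(0, 5), 0)
  expect_equal(partial_eta_sq(5, 0), 1)
  expect_warning(res <- partial_eta_sq(0, 0), "undefined")
  expect_true(is.na(res))
})

test_that("Bonferroni pairwise comparisons match closed forms", {
  set.seed(9)
  n <- 22
  d <- data.frame(subject = rep(1:n, 3),
                  cond = rep(c("A", "B", "C"), each = n),
                  y = rnorm(3 * n, rep(c(0, 1, 0.5), each = n), 2))
  pw <- pairwise_bonferroni(d, "y", "cond")
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_adjusted, pmin(1, pw$p_raw * 3))

  # closed form for one pair: d_bar +/- t(1 - alpha/(2m), n-1) * s/sqrt(n)
  dAB <- d$y[d$cond == "A"] - d$y[d$cond == "B"]
  tcrit <- qt(1 - 0.05 / (2 * 3), n - 1)
  lo <- mean(dAB) - tcrit * sd(dAB) / sqrt(n)
  hi <- mean(dAB) + tcrit * sd(dAB) / sqrt(n)
  row <- pw[pw$pair == "A - B", ]
  expect_equal(row$ci_lower, lo, tolerance = 1e-10)
  expect_equal(row$ci_upper, hi, tolerance = 1e-10)
  expect_true(row$ci_lower <= row$mean_diff & row$mean_diff <= row$ci_upper)

  # identical paired vectors: zero difference, adjusted p = 1
  d0 <- data.frame(subject = rep(1:n, 2),
                   cond = rep(c("A", "B"), each = n),
                   y = rep(rnorm(n), 2))
  pw0 <- pairwise_bonferroni(d0, "y", "cond")
  expect_equal(pw0$mean_diff, 0)
  expect_equal(pw0$p_adjusted, 1)
})

test_that("interval univariate tests use the subjects-as-replicates layout", {
  set.seed(13)
  gains <- expand.grid(subject = 1:22,
                       background = c("blank", "inconsistent", "consistent"),
                       interval = 1:24, stringsAsFactors = FALSE)
  gains$gain <- rnorm(nrow(gains), 0.8, 0.05)
  tab <- interval_univariate(gains)
  expect_equal(nrow(tab), 24L)
  expect_true(all(tab$df1 == 2))
  expect_true(all(tab$df2 == 63))

  # null rate over repeated draws: about 1.2 of 24 intervals flagged
  flagged <- vapply(1:40, function(r) {
    set.seed(200 + r)
    gains$gain <- rnorm(nrow(gains), 0.8, 0.05)
    sum(interval_univariate(gains)$significant)
  }, numeric(1))
  expect_gt(mean(flagged), 0.3)
  expect_lt(mean(flagged), 2.5)
})

test_that("localized consistency effects are flagged at the right intervals", {
  # subject offsets shared across conditions make the 66-observation
  # layout conservative at null intervals, so only the three bins that
  # truly differ should be flagged
  run_one <- function(seed) {
    set.seed(seed)
    gains <- expand.grid(subject = 1:22,
                         background = c("blank", "inconsistent",
                                        "consistent"),
                         interval = 1:24, stringsAsFactors = FALSE)
    subj_off <- rnorm(22, 0, 0.05)
    gains$gain <- 0.8 + subj_off[gains$subject] +
      rnorm(nrow(gains), 0, 0.01)
    bump <- gains$background == "consistent" &
      gains$interval %in% c(1, 12, 24)
    gains$gain[bump] <- gains$gain[bump] + 0.07
    interval_univariate(gains)$significant
  }
  hits <- vapply(1:30, function(s) {
    sig <- run_one(3000 + s)
    all(sig[c(1, 12, 24)]) && !any(sig[-c(1, 12, 24)])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("Greenhouse-Geisser correction shrinks the dfs when requested", {
  d <- random_ws_design(12, 4, seed = 77)
  fit <- rm_anova(d, "y", "a", gg_correction = TRUE)
  expect_true(fit$epsilon >= 1 / 3 - 1e-9 && fit$epsilon <= 1 + 1e-9)
  fit0 <- rm_anova(d, "y", "a")
  expect_equal(fit$F, fit0$F)  # correction affects p, not F
})
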