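# Mixed-effects inference: model fitting, likelihood-ratio tests, Tukey
# contrasts, percent-change summaries.

make_balanced <- function(n = 8, effects = c(`0` = 0, `45` = -5, `60` = -8),
                          psd = 6, rsd = 2, seed = 1) {
  simulate_endpoints(n, baseline = 30, participant_sd = psd,
                     residual_sd = rsd, additive = effects, seed = seed)
}

test_that("perfect-fit limit: zero noise recovers additive effects exactly", {
  d <- make_balanced(rsd = 1e-8, psd = 4, seed = 2)
  # near-zero residual variance trips lme4 convergence checks; harmless here
  m <- suppressWarnings(suppressMessages(fit_mixed_model(d, "condition")))
  fe <- lme4::fixef(m)
  expect_equal(unname(fe[["condition45"]]), -5, tolerance = 1e-4)
  expect_equal(unname(fe[["condition60"]]), -8, tolerance = 1e-4)
})

test_that("model guards: missing columns, single participant, single level", {
  d <- make_balanced()
  expect_error(fit_mixed_model(d[, c("condition", "value")], "condition"),
               "participant")
  d1 <- d[d$participant == "1", ]
  expect_error(fit_mixed_model(d1, "condition"), "2 participants")
  d2 <- d[d$condition == "0", ]
  expect_error(fit_mixed_model(d2, "condition"), "2 levels")
})

test_that("likelihood-ratio test: identical models give statistic 0, p 1", {
  d <- make_balanced(seed = 3)
  m <- fit_mixed_model(d, "condition")
  out <- lrt_effect(m, m)
  expect_equal(out$statistic, 0)
  expect_equal(out$df, 0)
  expect_equal(out$p_value, 1)
})

test_that("likelihood-ratio test agrees with anova() on nested lmer fits", {
  d <- make_balanced(seed = 4)
  full <- fit_mixed_model(d, "condition")
  red <- fit_mixed_model(d, character(0))
  mine <- lrt_effect(full, red)
  ref <- anova(full, red)
  expect_equal(mine$statistic, ref$Chisq[2], tolerance = 1e-8)
  expect_equal(mine$df, ref$Df[2])
  expect_equal(mine$p_value, ref$`Pr(>Chisq)`[2], tolerance = 1e-8)
})

test_that("LRT statistic is invariant to affine rescaling of the endpoint", {
  d <- make_balanced(seed = 5)
  s1 <- lrt_term(d, "condition")$statistic
  d$value <- 3.7 * d$value + 100
  s2 <- lrt_term(d, "condition")$statistic
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("REML fits are rejected for likelihood-ratio testing", {
  d <- make_balanced(seed = 6)
  full <- fit_mixed_model(d, "condition", reml = TRUE)
  red <- fit_mixed_model(d, character(0), reml = TRUE)
  expect_error(lrt_effect(full, red), "maximum-likelihood")
})

test_that("Tukey contrasts: two-level factor equals the unadjusted p", {
  d <- make_balanced(effects = c(`0` = 0, `45` = -5), seed = 7)
  m <- fit_mixed_model(d, "condition")
  tc <- tukey_contrasts(m, "condition")
  un <- emmeans::contrast(
    emmeans::emmeans(m, ~ condition, lmer.df = "satterthwaite"),
    method = "pairwise", adjust = "none")
  expect_equal(tc$contrasts$p.value, as.data.frame(un)$p.value,
               tolerance = 1e-10)
})

test_that("Tukey contrasts sum to zero over a closed loop and are adjusted upward", {
  d <- make_balanced(seed = 8)
  m <- fit_mixed_model(d, "condition")
  tc <- tukey_contrasts(m, "condition")
  est <- tc$contrasts$estimate
  # (A-B) + (B-C) - (A-C) = 0
  expect_equal(est[1] + est[3] - est[2], 0, tolerance = 1e-10)
  un <- emmeans::contrast(
    emmeans::emmeans(m, ~ condition, lmer.df = "satterthwaite"),
    method = "pairwise", adjust = "none")
  expect_true(all(tc$contrasts$p.value >= as.data.frame(un)$p.value - 1e-12))
})

test_that("least-squares means equal cell means on balanced zero-noise data", {
  d <- make_balanced(rsd = 1e-8, psd = 3, seed = 9)
  m <- suppressWarnings(suppressMessages(fit_mixed_model(d, "condition")))
  tc <- suppressWarnings(tukey_contrasts(m, "condition"))
  cm <- tapply(d$value, d$condition, mean)
  expect_equal(tc$lsmeans$emmean, as.numeric(cm), tolerance = 1e-4)
})

test_that("percent change: halving gives 50 +/- 0, zero reference excluded", {
  d <- expand.grid(participant = 1:6, condition = c("0", "45"))
  d$value <- ifelse(d$condition == "0", 10, 5)
  out <- percent_change_summary(d)
  expect_equal(out$mean_pct, 50)
  expect_equal(out$sd_pct, 0)
  d$value[d$participant == 3 & d$condition == "0"] <- 0
  expect_warning(out2 <- percent_change_summary(d), "zero reference")
  expect_equal(out2$n, 5)
})
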