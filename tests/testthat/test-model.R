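# Simulate a simple day table with a chosen coefficient vector (all other
# generator machinery bypassed) for model-level tests.
sim_days <- function(n_pp = 60, n_days = 10, beta_x = 1, sigma_u = 0.8,
                     intercept = -1, seed = 1) {
  set.seed(seed)
  n <- n_pp * n_days
  u <- rep(rnorm(n_pp, 0, sigma_u), each = n_days)
  x <- rnorm(n)
  data.frame(
    participant_id = rep(sprintf("P%03d", seq_len(n_pp)), each = n_days),
    x = x,
    alcohol = rbinom(n, 1, plogis(intercept + beta_x * x + u))
  )
}

test_that("glmm with zero between-person variance matches plain logistic fit", {
  d <- sim_days(n_pp = 80, n_days = 10, sigma_u = 0, seed = 2)
  f <- fit_alcohol_glmm(d, terms = "x")
  expect_lt(f$sigma_u2, 0.05)
  g <- glm(alcohol ~ x, data = d, family = binomial)
  bf <- setNames(f$coefficients$b, f$coefficients$term)
  expect_equal(unname(bf["x"]), unname(coef(g)["x"]), tolerance = 0.05)
  expect_equal(unname(bf["(Intercept)"]), unname(coef(g)["(Intercept)"]),
               tolerance = 0.05)
})

test_that("estimates agree with an independent mixed-model engine", {
  d <- sim_days(seed = 3)
  f <- fit_alcohol_glmm(d, terms = "x")
  tmb <- glmmTMB::glmmTMB(alcohol ~ x + (1 | participant_id), data = d,
                          family = binomial)
  expect_equal(unname(setNames(f$coefficients$b, f$coefficients$term)["x"]),
               unname(glmmTMB::fixef(tmb)$cond["x"]), tolerance = 1e-3)
  expect_equal(f$sigma_u2,
               unname(glmmTMB::VarCorr(tmb)$cond$participant_id[1, 1]),
               tolerance = 1e-2)
})

test_that("null comparison is a nested deviance test with df = removed terms", {
  cfg <- tiny_config(seed = 51, n_participants = 40, compliance_p = 1)
  d <- simulate_model_table(cfg, seed = 51)
  f <- fit_alcohol_glmm(d)
  n0 <- fit_null_model(f)
  cmp <- null_model_comparison(f, n0)
  expect_equal(cmp$df, 14)
  expect_gte(cmp$lr_chisq, 0)
  expect_equal(cmp$lr_chisq, n0$deviance - f$deviance, tolerance = 1e-8)
  # comparing the null model against itself gives chi-square 0, p = 1
  self_cmp <- null_model_comparison(n0, n0)
  expect_equal(self_cmp$lr_chisq, 0)
  expect_equal(self_cmp$p, 1)
})

test_that("pseudo-R2 components behave at their degenerate limits", {
  d <- sim_days(n_pp = 80, n_days = 10, sigma_u = 0, seed = 4)
  f <- fit_alcohol_glmm(d, terms = "x")
  r2 <- pseudo_r2(f)
  # near-zero fitted random-intercept variance: conditional ~ marginal
  expect_lt(r2$r2_conditional - r2$r2_marginal, 0.02)
  expect_gte(r2$r2_conditional, r2$r2_marginal)
  # a predictor with zero generating effect explains (almost) nothing
  d0 <- sim_days(n_pp = 80, n_days = 10, beta_x = 0, seed = 14)
  f0 <- fit_alcohol_glmm(d0, terms = "x")
  expect_lt(pseudo_r2(f0)$r2_marginal, 0.02)
})

test_that("Wald z-square approximates the LRT for one added predictor", {
  d <- sim_days(n_pp = 400, n_days = 20, beta_x = 0.5, seed = 5)
  f <- fit_alcohol_glmm(d, terms = "x")
  f0_dev <- {
    dat <- d
    ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
    m0 <- lme4::glmer(alcohol ~ 1 + (1 | participant_id), data = dat,
                      family = binomial, control = ctrl)
    -2 * as.numeric(logLik(m0))
  }
  lr <- f0_dev - f$deviance
  z2 <- f$coefficients$z[f$coefficients$term == "x"]^2
  expect_lt(abs(z2 - lr) / lr, 0.1)
})

test_that("the sensitivity series filters monotonically and matches direct fits", {
  cfg <- tiny_config(seed = 61, n_participants = 40, n_days = 14,
                     compliance_p = 0.85)
  d <- simulate_model_table(cfg, seed = 61)
  # attach synthetic answer counts so the prompt filter has bite
  set.seed(62)
  d$prompts_answered <- sample(0:6, nrow(d), replace = TRUE,
                               prob = c(0.02, 0.03, 0.05, 0.1, 0.2, 0.3,
                                        0.3))
  ser <- sensitivity_series(d)
  n_days <- vapply(ser$fits, function(f) f$n_days, 1L)
  expect_true(all(diff(n_days) <= 0))
  direct <- fit_alcohol_glmm(filter_model_days(d, 4))
  expect_equal(ser$fits$k4$coefficients$b, direct$coefficients$b,
               tolerance = 1e-10)
  tab <- summarize_series(ser)
  expect_equal(tab$min_prompts, 1:6)
})

test_that("model fitting rejects degenerate inputs", {
  d <- sim_days(seed = 6)
  d1 <- d[d$participant_id == "P001", ]
  expect_error(fit_alcohol_glmm(d1, terms = "x"), "2 participants")
  d$alcohol <- 0
  expect_error(fit_alcohol_glmm(d, terms = "x"), "constant")
  expect_error(fit_alcohol_glmm(d[, c("participant_id", "alcohol")]),
               "lacks columns")
})

test_that("pooled t test reproduces the textbook statistic and df", {
  # identical groups: t = 0, p = 1
  tt <- t_test_independent(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
  # study group sizes 24 + 28 give df = 50
  set.seed(7)
  tt <- t_test_independent(rnorm(52), rep(c("g14", "g16"), c(24, 28)))
  expect_equal(tt$df, 50)
  # hand computation on a 4 + 4 fixture
  x <- c(1, 2, 3, 4)
  y <- c(3, 5, 4, 6)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  tt <- t_test_independent(c(x, y), rep(c("x", "y"), each = 4))
  expect_equal(tt$statistic, t_hand, tolerance = 1e-12)
  expect_equal(tt$df, 6)
  expect_error(t_test_independent(1:5, c("a", "a", "a", "a", "b")),
               "at least 2")
})

test_that("Pearson correlation and Fisher-z interval match hand formulas", {
  x <- c(1.2, 2.8, 3.1, 4.9, 5.3, 6.8, 7.2, 8.9)
  y <- c(2.0, 2.5, 3.9, 4.1, 6.2, 6.0, 7.9, 8.1)
  out <- pearson_ci(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  z <- atanh(r_hand)
  half <- qnorm(0.975) / sqrt(length(x) - 3)
  expect_equal(out$ci, tanh(c(z - half, z + half)), tolerance = 1e-9)
  expect_equal(pearson_ci(x, x)$r, 1)
  expect_error(pearson_ci(x, rep(1, 8)), "zero variance")
  expect_error(pearson_ci(x[1:3], y[1:3]), "at least 4")
})
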