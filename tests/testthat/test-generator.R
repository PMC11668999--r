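test_that("variance components derived from the pseudo-R2 pair", {
  vc <- derive_variance_components(0.244, 0.405)
  # forward check: plugging the derived variances back into the two
  # Nakagawa formulas reproduces the pair exactly
  denom <- vc$sigma_f2 + vc$sigma_u2 + pi^2 / 3
  expect_equal(vc$sigma_f2 / denom, 0.244, tolerance = 1e-12)
  expect_equal((vc$sigma_f2 + vc$sigma_u2) / denom, 0.405,
               tolerance = 1e-12)
  expect_equal(vc$sigma_u, 0.9435, tolerance = 1e-4)
  expect_equal(vc$sigma_f2, 1.349, tolerance = 1e-3)
})

test_that("default calibration reproduces the target linear-predictor variance", {
  cfg <- generator_config()
  cp <- cfg$covariate_params
  beta <- cfg$beta
  dates <- cfg$start_date + 0:13
  w <- as.numeric(weekend_flag(dates))
  vars <- c(
    pa = cp$pa$sd^2, na = cp$na$sd^2, craving = cp$craving$sd^2,
    rumination = cp$rumination$sd^2, social_context = cp$social_context$sd^2,
    weekend = mean(w) * (1 - mean(w)),
    roaming_entropy = cp$roaming_entropy$sd^2,
    tp_culture = cp$tp_culture$lambda, tp_nightlife = cp$tp_nightlife$lambda,
    tp_leisure = cp$tp_leisure$lambda,
    tp_meeting_spots = cp$tp_meeting_spots$lambda,
    tp_peers = cp$tp_peers$lambda,
    age_group = cp$p_age16 * (1 - cp$p_age16),
    sex = cp$p_female * (1 - cp$p_female)
  )
  sf2 <- sum(beta[names(vars)]^2 * vars)
  expect_equal(sf2, derive_variance_components()$sigma_f2,
               tolerance = 1e-10)
})

test_that("config invariants are enforced", {
  expect_error(generator_config(n_participants = 0), "positive")
  expect_error(generator_config(n_days = 0), "n_days")
  expect_error(generator_config(compliance_p = 1.2), "compliance_p")
  expect_error(generator_config(sigma_u = -1), "sigma_u")
})

test_that("cohort composition matches the study sample", {
  cfg <- generator_config()
  cohort <- generate_cohort(cfg, seed = 3)
  expect_equal(nrow(cohort), 52)
  expect_equal(sum(cohort$age_group == 14), 24)
  expect_equal(sum(cohort$sex == "female"), 26)
  expect_equal(sum(cohort$covid_period == 0), 15)
  expect_true(all(cohort$audit_total >= 0 & cohort$audit_total <= 40))
  # zero random-intercept SD puts every intercept at exactly 0
  cfg0 <- generator_config(sigma_u = 0)
  expect_true(all(generate_cohort(cfg0, seed = 3)$u == 0))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$prompts, s2$prompts)
  expect_identical(s1$gps, s2$gps)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$participants, s2$participants)
})

test_that("full compliance yields 84 answered prompts per participant", {
  cfg <- generator_config(n_participants = 3, compliance_p = 1,
                          fixes_per_day = 24)
  cohort <- generate_cohort(cfg, seed = 5)
  ema <- generate_ema(cfg, cohort, seed = 6)
  answered <- unique(ema[, c("participant_id", "date", "slot")])
  expect_equal(as.vector(table(answered$participant_id)), rep(84, 3))
  expect_true(all(ema$slot %in% PROMPT_SLOTS))
  # zero compliance: nothing answered at all
  cfg0 <- generator_config(n_participants = 3, compliance_p = 0)
  expect_equal(nrow(generate_ema(cfg0, cohort, seed = 6)), 0)
})

test_that("generated daily construct scores calibrate to configured means", {
  # grand means over >= 10,000 participant-days within 3 MC standard errors
  cfg <- generator_config(n_participants = 800)
  d <- simulate_model_table(cfg, seed = 21)
  expect_gte(nrow(d), 10000)
  cp <- cfg$covariate_params
  for (v in c("pa", "na", "craving", "rumination")) {
    se <- cp[[v]]$sd / sqrt(cfg$n_participants)
    expect_lt(abs(mean(d[[v]]) - cp[[v]]$mean), 3 * se)
  }
  expect_lt(abs(mean(d$roaming_entropy) - cp$roaming_entropy$mean), 0.01)
})

test_that("trajectory profiles produce their defining entropy levels", {
  cfg <- tiny_config()
  st <- generate_trajectory(cfg, "P1", 1, "stationary", n_fixes = 100)
  expect_equal(roaming_entropy(st), 0)
  expect_equal(attr(st, "truth")$re, 0)
  ro <- generate_trajectory(cfg, "P1", 1, "roamer", n_fixes = 100)
  expect_equal(roaming_entropy(ro), 1)
  expect_equal(attr(ro, "truth")$re, 1)
  # two anchors, dwell 3:1, four fixes
  co <- generate_trajectory(cfg, "P1", 1, "commuter",
                            anchors = anchor_pool_fixture(cfg, 2),
                            dwell = c(3, 1), n_fixes = 4)
  expect_equal(attr(co, "truth")$re, 0.405639, tolerance = 1e-6)
  expect_equal(roaming_entropy(co), attr(co, "truth")$re,
               tolerance = 1e-12)
  expect_error(generate_trajectory(cfg, "P1", 1, "teleporter"),
               "unknown")
})

test_that("module-recomputed entropy matches generator truth to 1e-9", {
  cfg <- tiny_config(seed = 31)
  study <- simulate_study(cfg)
  geo <- geo_day_summaries(study$gps, study$pois)
  key_geo <- paste(geo$participant_id, geo$date)
  key_tr <- paste(study$truth$participant_id, study$truth$date)
  idx <- match(key_tr, key_geo)
  expect_false(anyNA(idx))
  expect_lt(max(abs(geo$roaming_entropy[idx] -
                      study$truth$roaming_entropy)), 1e-9)
  # trigger contacts from the geometry agree with the generator's plan
  for (cat in TP_CATEGORIES) {
    expect_equal(geo[[paste0("tp_", cat)]][idx],
                 study$truth[[paste0("tp_", cat)]])
  }
})

test_that("POI placement controls contact counts by construction", {
  cfg <- tiny_config()
  pool <- anchor_pool_fixture(cfg, 2)
  tr <- generate_trajectory(cfg, "P1", 1, "commuter", anchors = pool,
                            n_fixes = 40)
  # POI at the first anchor: at least one contact in its category
  poi_at <- data.frame(lat = pool$lat[1], lon = pool$lon[1],
                       category = "nightlife")
  expect_gte(tp_contacts(tr, poi_at)["nightlife"], 1)
  # POI ~20 m from everything: no contact
  poi_off <- data.frame(lat = pool$lat + 1.8e-4, lon = pool$lon,
                        category = rep("peers", 2))
  expect_equal(sum(tp_contacts(tr, poi_off)), 0)
  # zero POIs requested: all downstream counts zero
  cfg0 <- tiny_config(n_poi_near = 0, n_poi_far = 0)
  expect_equal(nrow(generate_poi_map(cfg0, seed = 1)), 0)
})

test_that("outcomes follow the logistic law of the linear predictor", {
  # all coefficients zero: the drinking rate is one half
  beta0 <- generator_config()$beta
  beta0[] <- 0
  cfg <- generator_config(n_participants = 200, beta = beta0, sigma_u = 0,
                          covariate_params = tweak_re_sd())
  d <- simulate_model_table(cfg, seed = 41)
  expect_true(all(d$eta == 0))
  expect_lt(abs(mean(d$alcohol) - 0.5), 3 * sqrt(0.25 / nrow(d)))
  # a hugely negative intercept switches drinking off entirely
  beta_neg <- generator_config()$beta
  beta_neg["intercept"] <- -40
  cfg2 <- generator_config(n_participants = 30, beta = beta_neg)
  expect_equal(sum(simulate_model_table(cfg2, seed = 42)$alcohol), 0)
  # empirical P(y = 1) tracks plogis(eta) within binomial error
  cfg3 <- generator_config(n_participants = 600)
  d3 <- simulate_model_table(cfg3, seed = 43)
  bucket <- cut(d3$eta, quantile(d3$eta, seq(0, 1, 0.2)),
                include.lowest = TRUE)
  for (b in levels(bucket)) {
    rows <- bucket == b
    p_hat <- mean(d3$alcohol[rows])
    p_true <- mean(d3$p_drink[rows])
    se <- sqrt(p_true * (1 - p_true) / sum(rows))
    expect_lt(abs(p_hat - p_true), 4 * se + 1e-9)
  }
})

test_that("missing model covariates fail naming the predictor", {
  cfg <- tiny_config()
  cohort <- generate_cohort(cfg, seed = 1)
  d <- simulate_model_table(cfg, seed = 1)
  d$rumination <- NULL
  expect_error(generate_outcomes(cfg, d, attr(d, "cohort")), "rumination")
})

test_that("default study conditions yield the observed drinking frequency", {
  # mean drinking days per participant across replicates in [0.5, 2.1]
  cfg <- generator_config()
  rates <- vapply(1:5, function(i) {
    d <- simulate_model_table(cfg, seed = 100 + i)
    mean(tapply(d$alcohol, d$participant_id, sum))
  }, numeric(1))
  expect_gt(mean(rates), 0.5)
  expect_lt(mean(rates), 2.1)
})
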