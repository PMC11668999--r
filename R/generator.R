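#' Variance components implied by a pseudo-R-squared pair
#'
#' Inverts the Nakagawa-Schielzeth equations for the logistic mixed model.
#' With marginal R2m = s_f2 / (s_f2 + s_u2 + pi^2/3) and conditional
#' R2c = (s_f2 + s_u2) / (s_f2 + s_u2 + pi^2/3), the total latent variance
#' is (pi^2/3) / (1 - R2c), the fixed-effect linear-predictor variance is
#' R2m times that total, and the random-intercept variance is
#' (R2c - R2m) times it. The defaults are the fitted model's published
#' pair (0.244, 0.405), giving s_f2 = 1.349, s_u2 = 0.890, s_u = 0.944;
#' this is how the generator's random-intercept SD is obtained, since the
#' variance itself was not reported.
#'
#' @param r2_marginal,r2_conditional The pseudo-R-squared pair; must
#'   satisfy 0 <= marginal <= conditional < 1.
#' @return List with `sigma_f2`, `sigma_u2`, `sigma_u` and `total_var`.
#' @export
derive_variance_components <- function(r2_marginal = 0.244,
                                       r2_conditional = 0.405) {
  stopifnot(r2_marginal >= 0, r2_conditional < 1,
            r2_conditional >= r2_marginal)
  total <- (pi^2 / 3) / (1 - r2_conditional)
  list(
    sigma_f2 = r2_marginal * total,
    sigma_u2 = (r2_conditional - r2_marginal) * total,
    sigma_u = sqrt((r2_conditional - r2_marginal) * total),
    total_var = total
  )
}

# Published fixed-effect estimates of the day-level alcohol model
# (logit scale), used as the generator's default coefficient vector.
default_beta <- function() {
  c(
    intercept = -3.519,
    pa = 0.685, na = -0.077, craving = 0.348, rumination = 0.586,
    social_context = -0.076, weekend = 1.082, roaming_entropy = 8.126,
    tp_culture = 0.015, tp_nightlife = 0.040, tp_leisure = 0.030,
    tp_meeting_spots = -0.081, tp_peers = -0.005,
    age_group = 0.721, sex = -0.295
  )
}

# Covariate distribution parameters: sample means/SDs of the daily
# constructs, Poisson rates for daily trigger-point contacts, cohort
# composition, and the roaming-entropy distribution (mean chosen as a
# plausible low daily mobility level; its SD is derived, see
# derive_re_sd()).
default_covariate_params <- function() {
  list(
    pa = list(mean = 3.70, sd = 0.803),
    na = list(mean = 1.15, sd = 0.607),
    craving = list(mean = 1.50, sd = 0.765),
    rumination = list(mean = 1.82, sd = 0.774),
    social_context = list(mean = 0.470, sd = 0.184),
    roaming_entropy = list(mean = 0.20, sd = NA_real_), # derived
    tp_culture = list(lambda = 0.3),
    tp_nightlife = list(lambda = 0.5),
    tp_leisure = list(lambda = 0.8),
    tp_meeting_spots = list(lambda = 1.0),
    tp_peers = list(lambda = 0.5),
    p_age16 = 28 / 52,
    p_female = 26 / 52
  )
}

# Mean of each model covariate under the generator, used to center the
# linear predictor (the configured intercept is the log-odds of drinking
# at covariate means for an average participant).
covariate_means <- function(config) {
  cp <- config$covariate_params
  dates <- config$start_date + seq_len(config$n_days) - 1L
  c(
    pa = cp$pa$mean, na = cp$na$mean, craving = cp$craving$mean,
    rumination = cp$rumination$mean,
    social_context = cp$social_context$mean,
    weekend = mean(weekend_flag(dates)),
    roaming_entropy = cp$roaming_entropy$mean,
    tp_culture = cp$tp_culture$lambda,
    tp_nightlife = cp$tp_nightlife$lambda,
    tp_leisure = cp$tp_leisure$lambda,
    tp_meeting_spots = cp$tp_meeting_spots$lambda,
    tp_peers = cp$tp_peers$lambda,
    age_group = cp$p_age16,
    sex = cp$p_female
  )
}

#' Roaming-entropy SD that completes the calibration
#'
#' Given the coefficient vector, the covariate distributions and a target
#' fixed-effect linear-predictor variance, solves (assuming independent
#' covariates) sum_k beta_k^2 var(x_k) = sigma_f2 for the variance of the
#' roaming-entropy covariate, the one predictor whose spread was not
#' reported.
#'
#' @param beta Named coefficient vector (see `generator_config()$beta`).
#' @param covariate_params Covariate parameter list.
#' @param sigma_f2 Target linear-predictor variance (default: derived from
#'   the published pseudo-R-squared pair).
#' @param weekend_var Variance of the weekend indicator (default
#'   (3/7)(4/7), the 14-day Monday-start calendar).
#' @return The roaming-entropy SD.
#' @export
derive_re_sd <- function(beta, covariate_params,
                         sigma_f2 = derive_variance_components()$sigma_f2,
                         weekend_var = (3 / 7) * (4 / 7)) {
  cp <- covariate_params
  vars <- c(
    pa = cp$pa$sd^2, na = cp$na$sd^2, craving = cp$craving$sd^2,
    rumination = cp$rumination$sd^2,
    social_context = cp$social_context$sd^2,
    weekend = weekend_var,
    tp_culture = cp$tp_culture$lambda,
    tp_nightlife = cp$tp_nightlife$lambda,
    tp_leisure = cp$tp_leisure$lambda,
    tp_meeting_spots = cp$tp_meeting_spots$lambda,
    tp_peers = cp$tp_peers$lambda,
    age_group = cp$p_age16 * (1 - cp$p_age16),
    sex = cp$p_female * (1 - cp$p_female)
  )
  other <- sum(beta[names(vars)]^2 * vars)
  v_re <- (sigma_f2 - other) / beta[["roaming_entropy"]]^2
  if (v_re <= 0) {
    stop("configured covariate variances already exceed the target ",
         "linear-predictor variance; cannot derive a roaming-entropy SD")
  }
  sqrt(v_re)
}

#' Generator configuration
#'
#' Bundles every generative parameter of the synthetic study: cohort size
#' and composition, study calendar, the coefficient vector of the
#' outcome-generating logistic model, the random-intercept SD on the logit
#' scale, covariate distributions, per-prompt compliance, and the GPS
#' geometry. Defaults reproduce the published study conditions: 52
#' participants (24 aged 14, 26 female) over 14 days starting on a Monday,
#' 6 prompts/day with mean compliance 0.797, per-minute GPS (1440
#' fixes/day), published coefficient vector, and a random-intercept SD of
#' 0.944 derived from the printed pseudo-R-squared pair via
#' [derive_variance_components()].
#'
#' @param n_participants Number of participants (default 52).
#' @param n_days Study days (default 14).
#' @param start_date First study day (default 2021-03-01, a Monday, so a
#'   14-day window holds 6 weekend days).
#' @param beta Named coefficient vector including `intercept`; the
#'   intercept is interpreted as the log-odds of drinking at covariate
#'   means for a participant with a zero random intercept.
#' @param sigma_u Random-intercept SD (logit scale).
#' @param covariate_params Covariate distribution list; a missing
#'   roaming-entropy SD is filled in by [derive_re_sd()].
#' @param compliance_p Per-prompt answer probability (default 0.797).
#' @param fixes_per_day GPS fixes per day (default 1440).
#' @param item_noise_sd SD of per-item response noise around the daily
#'   latent construct value (default 0.8).
#' @param grid_origin c(lat, lon) of the synthetic city grid (default
#'   c(49.49, 8.47)).
#' @param grid_spacing Grid spacing in degrees (default 1e-3, ~110 m
#'   north-south, so distinct grid points never fall inside one 15 m
#'   contact radius).
#' @param n_poi_near POIs per category placed on grid points (contact
#'   distance 0); NULL (default) calibrates each category's count so the
#'   expected daily contact rate matches its configured rate.
#' @param n_poi_far POIs per category offset well beyond the contact
#'   radius.
#' @param tz Timezone of the study city.
#' @param seed Default seed used by [simulate_study()] (NULL = leave RNG
#'   state alone).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 52,
                             n_days = 14,
                             start_date = as.Date("2021-03-01"),
                             beta = default_beta(),
                             sigma_u = derive_variance_components()$sigma_u,
                             covariate_params = default_covariate_params(),
                             compliance_p = 0.797,
                             fixes_per_day = 1440,
                             item_noise_sd = 0.8,
                             grid_origin = c(49.49, 8.47),
                             grid_spacing = 1e-3,
                             n_poi_near = NULL,
                             n_poi_far = 8,
                             tz = "Europe/Berlin",
                             seed = NULL) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("n_participants must be a positive count")
  }
  if (n_days < 1) stop("n_days must be at least 1")
  if (compliance_p < 0 || compliance_p > 1) {
    stop("compliance_p must lie in [0, 1]")
  }
  if (sigma_u < 0) stop("sigma_u must be non-negative")
  if (fixes_per_day < 1) stop("fixes_per_day must be at least 1")
  needed <- c("intercept", MODEL_TERMS)
  if (!all(needed %in% names(beta))) {
    stop("beta must name: ", paste(setdiff(needed, names(beta)),
                                   collapse = ", "))
  }
  if (is.na(covariate_params$roaming_entropy$sd)) {
    dates <- as.Date(start_date) + seq_len(n_days) - 1L
    wv <- var(as.numeric(weekend_flag(dates))) * (n_days - 1) / n_days
    covariate_params$roaming_entropy$sd <-
      derive_re_sd(beta, covariate_params, weekend_var = wv)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_days = as.integer(n_days),
      start_date = as.Date(start_date),
      beta = beta[needed],
      sigma_u = sigma_u,
      covariate_params = covariate_params,
      compliance_p = compliance_p,
      fixes_per_day = as.integer(fixes_per_day),
      item_noise_sd = item_noise_sd,
      grid_origin = grid_origin,
      grid_spacing = grid_spacing,
      n_poi_near = n_poi_near,
      n_poi_far = n_poi_far,
      tz = tz,
      seed = seed
    ),
    class = "generator_config"
  )
}

#' Generate the participant cohort
#'
#' Draws the participant metadata table with the configured composition:
#' for the default 52-participant cohort, 24 participants aged 14 and 28
#' aged 16, sex crossed 12/12 and 14/14 within age group (26 female), and
#' 15 participants assessed before the pandemic restrictions. Each
#' participant receives a latent random intercept u ~ N(0, sigma_u^2) and
#' 10 AUDIT items whose level rises with the random intercept, so general
#' alcohol involvement correlates with generated daily drinking.
#'
#' @param config A [generator_config()].
#' @param seed Optional seed.
#' @return Data frame with `participant_id`, `age_group` (14/16), `sex`
#'   ("male"/"female"), `covid_period` (0/1), `audit_1`..`audit_10`,
#'   `audit_total`, and the latent `u`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  np <- config$n_participants
  cp <- config$covariate_params
  n14 <- round(np * (1 - cp$p_age16))
  age <- rep(c(14L, 16L), c(n14, np - n14))
  sex <- character(np)
  for (a in c(14L, 16L)) {
    idx <- which(age == a)
    nf <- round(length(idx) * cp$p_female)
    sex[idx] <- rep(c("female", "male"), c(nf, length(idx) - nf))
  }
  covid <- rep(1L, np)
  n_before <- round(np * 15 / 52)
  covid[sample.int(np, n_before)] <- 0L
  u <- rnorm(np, 0, config$sigma_u)
  z <- if (config$sigma_u > 0) u / config$sigma_u else rep(0, np)
  audit <- t(vapply(
    z,
    function(zi) rbinom(10, 4, plogis(-2.2 + 0.9 * zi)),
    integer(10)
  ))
  out <- data.frame(
    participant_id = sprintf("P%03d", seq_len(np)),
    age_group = age,
    sex = sex,
    covid_period = covid,
    stringsAsFactors = FALSE
  )
  for (j in 1:10) out[[paste0("audit_", j)]] <- audit[, j]
  out$audit_total <- rowSums(audit)
  out$u <- u
  out
}

# Participant-day latent construct values: participant-level mean plus
# day-level noise, variance split 50/50 between the two levels.
make_day_latents <- function(config, cohort) {
  np <- nrow(cohort)
  nd <- config$n_days
  n <- np * nd
  cp <- config$covariate_params
  dates <- config$start_date + seq_len(nd) - 1L
  draw <- function(m, s) {
    pm <- rep(rnorm(np, m, s / sqrt(2)), each = nd)
    pm + rnorm(n, 0, s / sqrt(2))
  }
  out <- data.frame(
    participant_id = rep(cohort$participant_id, each = nd),
    date = rep(dates, np),
    pa = draw(cp$pa$mean, cp$pa$sd),
    na = draw(cp$na$mean, cp$na$sd),
    craving = draw(cp$craving$mean, cp$craving$sd),
    rumination = draw(cp$rumination$mean, cp$rumination$sd),
    social_context = pmin(1, pmax(0, draw(cp$social_context$mean,
                                          cp$social_context$sd))),
    stringsAsFactors = FALSE
  )
  out$weekend <- as.numeric(weekend_flag(out$date))
  out
}

#' Generate binary drinking outcomes from day covariates
#'
#' Inverts the analysis model: for each participant-day,
#' y ~ Bernoulli(plogis(eta)) with
#' eta = b0 + sum_k beta_k (x_k - mu_k) + u_j, where mu_k are the
#' configured covariate means, so the intercept is the log-odds of
#' drinking at covariate means for an average participant. The linear
#' predictor and drinking probability are returned alongside the outcome.
#'
#' @param config A [generator_config()].
#' @param day_covariates Data frame with `participant_id` and all 14 model
#'   covariate columns.
#' @param u Named numeric vector of random intercepts (names =
#'   participant ids), or a cohort data frame with `u`.
#' @param seed Optional seed.
#' @return `day_covariates` with added `eta`, `p_drink` and `alcohol`.
#' @export
generate_outcomes <- function(config, day_covariates, u, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(u)) u <- setNames(u$u, u$participant_id)
  missing_cov <- setdiff(MODEL_TERMS, names(day_covariates))
  if (length(missing_cov) > 0) {
    stop("missing model covariate(s): ", paste(missing_cov, collapse = ", "))
  }
  mu <- covariate_means(config)
  beta <- config$beta
  X <- as.matrix(day_covariates[, MODEL_TERMS])
  eta <- beta[["intercept"]] +
    as.vector(X %*% beta[MODEL_TERMS]) -
    sum(beta[MODEL_TERMS] * mu[MODEL_TERMS]) +
    unname(u[as.character(day_covariates$participant_id)])
  day_covariates$eta <- eta
  day_covariates$p_drink <- plogis(eta)
  day_covariates$alcohol <- rbinom(length(eta), 1, day_covariates$p_drink)
  day_covariates
}

#' Simulate a model-ready day table
#'
#' The direct route used for parameter-recovery simulation: draws
#' participant random intercepts and day-level covariates from their
#' configured distributions (constructs split between participant and day
#' level, weekend from the calendar, roaming entropy as a clamped normal
#' on \[0, 1\], trigger-point counts as Poisson), then Bernoulli drinking
#' outcomes via [generate_outcomes()]. No EMA items or GPS fixes are
#' materialized.
#'
#' @param config A [generator_config()].
#' @param seed Optional seed.
#' @return Day table ready for [fit_alcohol_glmm()], with truth columns
#'   `eta` and `p_drink`; the cohort (with `u`) is attached as attribute
#'   `cohort`.
#' @export
simulate_model_table <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(config)
  d <- make_day_latents(config, cohort)
  n <- nrow(d)
  cp <- config$covariate_params
  d$roaming_entropy <- pmin(1, pmax(0, rnorm(
    n, cp$roaming_entropy$mean, cp$roaming_entropy$sd
  )))
  for (cat in TP_CATEGORIES) {
    d[[paste0("tp_", cat)]] <- rpois(n, cp[[paste0("tp_", cat)]]$lambda)
  }
  pid <- match(d$participant_id, cohort$participant_id)
  d$age_group <- as.numeric(cohort$age_group[pid] == 16)
  d$sex <- as.numeric(cohort$sex[pid] == "female")
  d <- generate_outcomes(config, d, cohort)
  attr(d, "cohort") <- cohort
  d
}

# Expected number of dwell blocks per day under the configured
# roaming-entropy distribution (k ~ T^RE equal-dwell anchors per day).
expected_blocks <- function(config) {
  cp <- config$covariate_params$roaming_entropy
  if (cp$sd <= 0) {
    return(max(1, round(config$fixes_per_day^cp$mean)))
  }
  re <- seq(max(0, cp$mean - 4 * cp$sd), min(1, cp$mean + 4 * cp$sd),
            length.out = 81)
  w <- exp(-0.5 * ((re - cp$mean) / cp$sd)^2)
  w <- w / sum(w)
  sum(w * pmin(config$fixes_per_day,
               pmax(1, round(config$fixes_per_day^re))))
}

# Anchor pool: a square grid of exact 4-decimal coordinates around the
# configured origin (grid spacing a multiple of 1e-3 degrees keeps points
# far apart relative to the 15 m contact radius).
anchor_pool <- function(config, n_side = 15) {
  off <- (seq_len(n_side) - (n_side + 1) / 2) * config$grid_spacing
  g <- expand.grid(dlat = off, dlon = off)
  data.frame(
    lat = round(config$grid_origin[1] + g$dlat, 4),
    lon = round(config$grid_origin[2] + g$dlon, 4)
  )
}

#' Generate one participant-day GPS trajectory
#'
#' Stay-point movement model on the synthetic grid. A "stationary" day
#' emits every fix at one anchor; a "roamer" day emits each fix in a fresh
#' grid cell (walking the grid row by row); a "commuter" day divides the
#' day into consecutive dwell blocks over `k` anchor cells with the given
#' dwell fractions. The exact roaming entropy implied by the emitted
#' cell-visit frequencies is attached as attribute `truth`.
#'
#' @param config A [generator_config()].
#' @param participant Participant id (character).
#' @param day Day number, 1-based.
#' @param profile One of "stationary", "commuter", "roamer".
#' @param anchors Data frame of anchor coordinates (`lat`, `lon`); rows
#'   are recycled in order. Defaults to grid points around the origin.
#' @param dwell Dwell fractions over anchors for the commuter profile
#'   (default: equal).
#' @param n_fixes Number of fixes (default `config$fixes_per_day`).
#' @return Data frame of fixes (`participant_id`, `timestamp`, `lat`,
#'   `lon`) with attribute `truth`: list with `re`, `cells` (the block
#'   plan), `n_fixes`.
#' @export
generate_trajectory <- function(config, participant, day,
                                profile = c("stationary", "commuter",
                                            "roamer"),
                                anchors = NULL, dwell = NULL,
                                n_fixes = config$fixes_per_day) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.character(profile) ||
        !profile[1] %in% c("stationary", "commuter", "roamer")) {
    stop("unknown trajectory profile: ", profile[1])
  }
  profile <- profile[1]
  n_fixes <- as.integer(n_fixes)
  stopifnot(n_fixes >= 1)
  pool <- anchor_pool(config)

  if (profile == "stationary") {
    if (is.null(anchors)) anchors <- pool[1, , drop = FALSE]
    plan <- data.frame(lat = anchors$lat[1], lon = anchors$lon[1],
                       n = n_fixes)
  } else if (profile == "roamer") {
    n_side <- ceiling(sqrt(n_fixes))
    off <- (seq_len(n_side) - 1) * config$grid_spacing
    g <- expand.grid(dlon = off, dlat = off)[seq_len(n_fixes), ]
    plan <- data.frame(
      lat = round(config$grid_origin[1] + g$dlat, 4),
      lon = round(config$grid_origin[2] + g$dlon, 4),
      n = 1L
    )
  } else { # commuter
    if (is.null(anchors)) anchors <- pool[1:2, , drop = FALSE]
    k <- nrow(anchors)
    if (is.null(dwell)) dwell <- rep(1 / k, k)
    stopifnot(length(dwell) == k, all(dwell > 0))
    dwell <- dwell / sum(dwell)
    counts <- floor(dwell * n_fixes)
    rem <- n_fixes - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
    keep <- counts > 0
    plan <- data.frame(lat = anchors$lat[keep], lon = anchors$lon[keep],
                       n = counts[keep])
  }

  date <- config$start_date + day - 1L
  step <- max(1L, 86400L %/% n_fixes)
  secs <- (seq_len(n_fixes) - 1L) * step
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = config$tz)
  out <- data.frame(
    participant_id = participant,
    timestamp = format(midnight + secs, "%Y-%m-%dT%H:%M:%S",
                       tz = config$tz),
    lat = rep(plan$lat, plan$n),
    lon = rep(plan$lon, plan$n),
    stringsAsFactors = FALSE
  )
  # exact entropy implied by the planned cell-visit frequencies (cells in
  # the plan are distinct by construction except repeated anchors, which
  # are collapsed here)
  cell <- paste(sprintf("%.4f", plan$lat), sprintf("%.4f", plan$lon))
  counts <- tapply(plan$n, cell, sum)
  attr(out, "truth") <- list(
    re = entropy_from_counts(as.vector(counts), n_fixes),
    plan = plan,
    n_fixes = n_fixes
  )
  out
}

#' Generate a synthetic POI map
#'
#' Places points of interest of the five trigger-point categories on the
#' synthetic grid: near POIs sit exactly on anchor-pool grid points (so
#' trajectories dwelling there are in contact, distance 0) and `n_poi_far`
#' per category are offset from grid points by ~33 m north, beyond the
#' 15 m contact radius. When `n_poi_near` is NULL (the default
#' configuration), the near-POI count of each category is calibrated so
#' that the expected daily contact count under the configured trajectory
#' model matches that category's configured contact rate.
#'
#' @param config A [generator_config()].
#' @param seed Optional seed.
#' @return Data frame `lat`, `lon`, `category`, `label`, `near` (logical:
#'   placed on a grid point).
#' @export
generate_poi_map <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  pool <- anchor_pool(config)
  blocks <- expected_blocks(config)
  rows <- list()
  for (cat in TP_CATEGORIES) {
    n_near <- config$n_poi_near
    if (is.null(n_near)) {
      lambda <- config$covariate_params[[paste0("tp_", cat)]]$lambda
      n_near <- max(1, min(
        floor(nrow(pool) / 2),
        round(nrow(pool) * lambda / blocks)
      ))
    }
    n_far <- config$n_poi_far
    if (n_near + n_far == 0) next
    idx <- sample.int(nrow(pool), n_near + n_far)
    near_idx <- idx[seq_len(n_near)]
    far_idx <- idx[-seq_len(n_near)]
    if (n_near > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        lat = pool$lat[near_idx], lon = pool$lon[near_idx],
        category = cat,
        label = paste0(cat, "_near_", seq_len(n_near)),
        near = TRUE, stringsAsFactors = FALSE
      )
    }
    if (n_far > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        lat = pool$lat[far_idx] + 3e-4, lon = pool$lon[far_idx],
        category = cat,
        label = paste0(cat, "_far_", seq_len(n_far)),
        near = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(lat = numeric(0), lon = numeric(0),
                      category = character(0), label = character(0),
                      near = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the long EMA prompt table
#'
#' Emits, for every participant-day, the six scheduled prompts; each is
#' answered independently with probability `compliance_p`. Answered
#' prompts carry item-level responses drawn around the day's latent
#' construct values (integer 1-7 after adding per-item noise and
#' clamping; craving and rumination items are stored on their raw
#' reversed anchors). The 09:00 prompt additionally carries the alone
#' item's sibling "Did you drink alcohol yesterday?", reporting the
#' previous day's generated outcome (the first morning reports a
#' pre-study day drawn from the participant's marginal drinking
#' probability).
#'
#' @param config A [generator_config()].
#' @param cohort Output of [generate_cohort()].
#' @param truth Day-level truth table with latent constructs and
#'   `alcohol`; generated internally when NULL.
#' @param seed Optional seed.
#' @return Long data frame `participant_id`, `date`, `slot`, `item_id`,
#'   `response`.
#' @export
generate_ema <- function(config, cohort, truth = NULL, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth)) {
    truth <- make_day_latents(config, cohort)
    n <- nrow(truth)
    cp <- config$covariate_params
    truth$roaming_entropy <- pmin(1, pmax(0, rnorm(
      n, cp$roaming_entropy$mean, cp$roaming_entropy$sd
    )))
    for (cat in TP_CATEGORIES) {
      truth[[paste0("tp_", cat)]] <- rpois(n, cp[[paste0("tp_",
                                                         cat)]]$lambda)
    }
    pid <- match(truth$participant_id, cohort$participant_id)
    truth$age_group <- as.numeric(cohort$age_group[pid] == 16)
    truth$sex <- as.numeric(cohort$sex[pid] == "female")
    truth <- generate_outcomes(config, truth, cohort)
  }
  u <- setNames(cohort$u, cohort$participant_id)
  clamp17 <- function(x) pmin(7, pmax(1, round(x)))
  rows <- vector("list", nrow(truth) * length(PROMPT_SLOTS))
  ri <- 0L
  for (i in seq_len(nrow(truth))) {
    td <- truth[i, ]
    day_index <- as.integer(td$date - config$start_date) + 1L
    for (slot in PROMPT_SLOTS) {
      if (runif(1) > config$compliance_p) next
      item_id <- character(0)
      response <- numeric(0)
      add <- function(ids, vals) {
        item_id <<- c(item_id, ids)
        response <<- c(response, vals)
      }
      ns <- config$item_noise_sd
      add(EMA_ITEMS$pa, clamp17(td$pa + rnorm(5, 0, ns)))
      add(EMA_ITEMS$na, clamp17(td$na + rnorm(5, 0, ns)))
      add(EMA_ITEMS$craving, clamp17(8 - (td$craving + rnorm(6, 0, ns))))
      add(EMA_ITEMS$rumination,
          clamp17(8 - (td$rumination + rnorm(4, 0, ns))))
      add(EMA_ITEMS$alone, rbinom(1, 1, td$social_context))
      if (slot == "09:00") {
        y_prev <- if (day_index >= 2) {
          prev <- truth$alcohol[truth$participant_id == td$participant_id &
                                  truth$date == td$date - 1L]
          prev[1]
        } else {
          rbinom(1, 1, plogis(config$beta[["intercept"]] +
                                u[[as.character(td$participant_id)]]))
        }
        add(EMA_ITEMS$alcohol, y_prev)
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        participant_id = td$participant_id,
        date = td$date,
        slot = slot,
        item_id = item_id,
        response = response,
        stringsAsFactors = FALSE
      )
    }
  }
  if (ri == 0L) {
    return(data.frame(participant_id = character(0),
                      date = as.Date(character(0)), slot = character(0),
                      item_id = character(0), response = numeric(0)))
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study
#'
#' End-to-end generation of all four pipeline inputs plus the latent
#' truth: cohort, POI map, per-minute GPS trajectories whose daily roaming
#' entropy follows the configured distribution (dwell-block trajectories
#' over k grid anchors, k chosen so the realized entropy matches a target
#' draw), trigger-point contacts realized through the POI geometry, latent
#' daily constructs, Bernoulli drinking outcomes, and the long EMA table
#' with per-prompt missingness.
#'
#' @param config A [generator_config()].
#' @param seed Seed (default `config$seed`).
#' @return Object of class `synthetic_study`: list with `participants`,
#'   `prompts`, `gps`, `pois`, `truth`, `config`.
#' @export
simulate_study <- function(config = generator_config(),
                           seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(config)
  pois <- generate_poi_map(config)
  pool <- anchor_pool(config)
  cp <- config$covariate_params

  truth <- make_day_latents(config, cohort)
  n <- nrow(truth)
  t_fix <- config$fixes_per_day

  # entropy-targeted trajectories: k equal-dwell anchors give realized
  # RE = log(k)/log(T); choose k from the target draw
  re_target <- pmin(1, pmax(0, rnorm(n, cp$roaming_entropy$mean,
                                     cp$roaming_entropy$sd)))
  k_anchors <- pmin(t_fix, pmax(1, round(t_fix^re_target)))
  k_anchors <- pmin(k_anchors, nrow(pool))

  near_pois <- pois[pois$near, , drop = FALSE]
  poi_key <- paste(sprintf("%.4f", near_pois$lat),
                   sprintf("%.4f", near_pois$lon))

  gps_list <- vector("list", n)
  truth$roaming_entropy <- NA_real_
  for (cat in TP_CATEGORIES) truth[[paste0("tp_", cat)]] <- 0L
  for (i in seq_len(n)) {
    k <- k_anchors[i]
    day_index <- as.integer(truth$date[i] - config$start_date) + 1L
    anchors <- pool[sample.int(nrow(pool), k), , drop = FALSE]
    traj <- generate_trajectory(
      config, truth$participant_id[i], day_index,
      profile = if (k == 1) "stationary" else "commuter",
      anchors = anchors, n_fixes = t_fix
    )
    tr <- attr(traj, "truth")
    truth$roaming_entropy[i] <- tr$re
    # contact episodes from the block plan: one episode per dwell block at
    # an anchor coinciding with a near POI of the category (grid spacing
    # keeps distinct anchors out of one another's contact radius)
    blk_key <- paste(sprintf("%.4f", tr$plan$lat),
                     sprintf("%.4f", tr$plan$lon))
    for (cat in TP_CATEGORIES) {
      ck <- poi_key[near_pois$category == cat]
      inside <- blk_key %in% ck
      truth[[paste0("tp_", cat)]][i] <-
        sum(inside & !c(FALSE, inside[-length(inside)]))
    }
    gps_list[[i]] <- traj
  }
  gps <- do.call(rbind, gps_list)
  rownames(gps) <- NULL

  pid <- match(truth$participant_id, cohort$participant_id)
  truth$age_group <- as.numeric(cohort$age_group[pid] == 16)
  truth$sex <- as.numeric(cohort$sex[pid] == "female")
  truth <- generate_outcomes(config, truth, cohort)
  truth$u <- cohort$u[pid]

  prompts <- generate_ema(config, cohort, truth)

  structure(
    list(
      participants = cohort,
      prompts = prompts,
      gps = gps,
      pois = pois,
      truth = truth,
      config = config
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(
    "Synthetic EMA/GPS study: ", nrow(x$participants), " participants, ",
    x$config$n_days, " days\n",
    "  prompts: ", nrow(unique(x$prompts[, c("participant_id", "date",
                                             "slot")])),
    " answered; GPS fixes: ", nrow(x$gps),
    "; POIs: ", nrow(x$pois), "\n",
    "  drinking days (truth): ", sum(x$truth$alcohol), "\n",
    sep = ""
  )
  invisible(x)
}
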