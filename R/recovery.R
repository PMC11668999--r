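#' Parameter-recovery simulation
#'
#' Repeatedly simulates day tables from the generative model via
#' [simulate_model_table()] and refits the random-intercept logistic model
#' to each, returning the per-replicate fixed-effect estimates and
#' Nakagawa pseudo-R-squared values together with their means. With the
#' default configuration this measures how well the published coefficient
#' vector is recovered under the study's own design (52 participants, 14
#' days).
#'
#' @param config A [generator_config()].
#' @param n_reps Number of replicate datasets (default 200).
#' @param seed Seed for the whole simulation; per-replicate seeds are
#'   drawn from it.
#' @param terms Fixed-effect terms to fit (default [MODEL_TERMS]).
#' @return List with `coef` (replicate x term matrix), `mean_coef`,
#'   `r2` (replicate x 2 matrix), `mean_r2`, `n_converged`, `n_reps`.
#' @export
recover_coefficients <- function(config = generator_config(),
                                 n_reps = 200, seed = 1,
                                 terms = MODEL_TERMS) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  co <- matrix(NA_real_, n_reps, length(terms),
               dimnames = list(NULL, terms))
  r2 <- matrix(NA_real_, n_reps, 2,
               dimnames = list(NULL, c("marginal", "conditional")))
  conv <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    d <- simulate_model_table(config, seed = rep_seeds[i])
    f <- fit_alcohol_glmm(d, terms = terms)
    b <- setNames(f$coefficients$b, f$coefficients$term)
    co[i, ] <- b[terms]
    pr <- pseudo_r2(f)
    r2[i, ] <- c(pr$r2_marginal, pr$r2_conditional)
    conv[i] <- f$converged
  }
  list(
    coef = co,
    mean_coef = colMeans(co),
    r2 = r2,
    mean_r2 = colMeans(r2),
    n_converged = sum(conv),
    n_reps = n_reps
  )
}

#' Type-I calibration of the overall model test
#'
#' Simulates data with every fixed-effect coefficient (including the
#' intercept) set to zero while keeping the random-intercept SD, fits the
#' full and null models to each replicate, and reports how often the
#' 14-df likelihood-ratio test rejects at level `alpha`. Under a
#' well-calibrated test the rejection rate matches `alpha`.
#'
#' @param config A [generator_config()]; its `beta` is zeroed internally.
#' @param n_reps Number of replicates (default 500).
#' @param seed Seed.
#' @param alpha Nominal level (default 0.05).
#' @return List with `rejection_rate`, `p_values`, `n_reps`, `df`.
#' @export
lrt_null_calibration <- function(config = generator_config(),
                                 n_reps = 500, seed = 1, alpha = 0.05) {
  beta0 <- config$beta
  beta0[] <- 0
  cfg <- generator_config(
    n_participants = config$n_participants,
    n_days = config$n_days,
    start_date = config$start_date,
    beta = beta0,
    sigma_u = config$sigma_u,
    covariate_params = config$covariate_params,
    compliance_p = config$compliance_p,
    fixes_per_day = config$fixes_per_day,
    tz = config$tz
  )
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  pvals <- rep(NA_real_, n_reps)
  df <- NA_integer_
  for (i in seq_len(n_reps)) {
    d <- simulate_model_table(cfg, seed = rep_seeds[i])
    f <- fit_alcohol_glmm(d)
    cmp <- null_model_comparison(f)
    pvals[i] <- cmp$p
    df <- cmp$df
  }
  list(
    rejection_rate = mean(pvals < alpha),
    p_values = pvals,
    n_reps = n_reps,
    df = df
  )
}
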