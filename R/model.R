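#' Fit the random-intercept logistic model of daily alcohol use
#'
#' Binomial generalized linear mixed model with logit link: the day-level
#' drinking outcome is regressed on the 14 fixed effects (daily positive
#' and negative affect, craving, rumination, social context, weekend flag,
#' roaming entropy, the five trigger-point contact counts, age group and
#' sex) with a random intercept per participant. Estimation is by maximum
#' likelihood with the Laplace approximation via [lme4::glmer()]; adaptive
#' Gauss-Hermite quadrature is available through `nAGQ`.
#'
#' @param day_table Model-ready day table (see [build_day_table()] or
#'   [simulate_model_table()]); must contain `alcohol`, `participant_id`
#'   and the columns in the model term set.
#' @param terms Character vector of fixed-effect terms (default: the full
#'   14-term specification).
#' @param nAGQ Number of quadrature points (1 = Laplace, the default).
#' @param check_derivs Recompute gradient/Hessian convergence diagnostics
#'   after optimization (slower; default FALSE).
#' @return An object of class `alcohol_glmm_fit`: a list with elements
#'   `coefficients` (term, b, se, z, p), `sigma_u2`, `deviance`, `logLik`,
#'   `n_days`, `n_participants`, `terms`, `converged`, `messages` and the
#'   underlying `merMod` object `fit`.
#' @export
fit_alcohol_glmm <- function(day_table, terms = MODEL_TERMS, nAGQ = 1,
                             check_derivs = FALSE) {
  missing_cols <- setdiff(c("alcohol", "participant_id", terms),
                          names(day_table))
  if (length(missing_cols) > 0) {
    stop("day table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dat <- day_table[complete.cases(day_table[, c("alcohol", terms)]), ,
                   drop = FALSE]
  if (length(unique(dat$participant_id)) < 2) {
    stop("need at least 2 participants with retained days")
  }
  if (length(unique(dat$alcohol)) < 2) {
    stop("outcome is constant; model cannot be fitted")
  }
  rhs <- paste(c(terms, "(1 | participant_id)"), collapse = " + ")
  form <- as.formula(paste("alcohol ~", rhs))
  msgs <- character(0)
  fit_with <- function(optimizer) {
    ctrl <- lme4::glmerControl(optimizer = optimizer,
                               calc.derivs = check_derivs)
    withCallingHandlers(
      lme4::glmer(form, data = dat, family = stats::binomial("logit"),
                  nAGQ = nAGQ, control = ctrl),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
  }
  # nloptwrap is fast; fall back to bobyqa if its deviance evaluation
  # crashes (PIRLS step-halving failures on near-degenerate subsets)
  fit <- tryCatch(fit_with("nloptwrap"), error = function(e) {
    msgs <<- c(msgs, conditionMessage(e))
    fit_with("bobyqa")
  })
  conv <- fit@optinfo$conv$opt == 0 &&
    length(fit@optinfo$conv$lme4$messages) == 0
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  coefs <- data.frame(
    term = names(b),
    b = unname(b),
    se = unname(se),
    z = unname(z),
    p = unname(2 * pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      coefficients = coefs,
      sigma_u2 = as.numeric(lme4::VarCorr(fit)$participant_id),
      deviance = -2 * as.numeric(logLik(fit)),
      logLik = as.numeric(logLik(fit)),
      n_days = nrow(dat),
      n_participants = length(unique(dat$participant_id)),
      terms = terms,
      converged = conv,
      messages = msgs,
      fit = fit
    ),
    class = "alcohol_glmm_fit"
  )
}

#' @export
print.alcohol_glmm_fit <- function(x, digits = 3, ...) {
  cat(
    "Random-intercept logistic model of daily alcohol use\n",
    x$n_days, " days, ", x$n_participants, " participants; deviance ",
    format(x$deviance, digits = 6), "\n",
    "random-intercept variance ", format(x$sigma_u2, digits = digits),
    "\n\n",
    sep = ""
  )
  co <- x$coefficients
  co[, -1] <- lapply(co[, -1], round, digits)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Null model: intercept plus random intercept only
#'
#' Refits the model with every fixed-effect term removed, on exactly the
#' rows used by `fit`, for the deviance-based overall model test.
#'
#' @param fit An `alcohol_glmm_fit`.
#' @return An `alcohol_glmm_fit` for the null model.
#' @export
fit_null_model <- function(fit) {
  stopifnot(inherits(fit, "alcohol_glmm_fit"))
  dat <- stats::model.frame(fit$fit)
  ctrl <- lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE)
  nf <- suppressWarnings(
    lme4::glmer(alcohol ~ 1 + (1 | participant_id), data = dat,
                family = stats::binomial("logit"), control = ctrl)
  )
  b <- lme4::fixef(nf)
  se <- sqrt(diag(as.matrix(stats::vcov(nf))))
  structure(
    list(
      coefficients = data.frame(
        term = names(b), b = unname(b), se = unname(se),
        z = unname(b / se), p = unname(2 * pnorm(-abs(b / se))),
        stringsAsFactors = FALSE
      ),
      sigma_u2 = as.numeric(lme4::VarCorr(nf)$participant_id),
      deviance = -2 * as.numeric(logLik(nf)),
      logLik = as.numeric(logLik(nf)),
      n_days = nrow(dat),
      n_participants = length(unique(dat$participant_id)),
      terms = character(0),
      converged = TRUE,
      messages = character(0),
      fit = nf
    ),
    class = "alcohol_glmm_fit"
  )
}

#' Likelihood-ratio comparison of full and null model
#'
#' Chi-square test of the joint contribution of the fixed effects: the
#' statistic is the deviance difference between the null model (intercept
#' and random intercept only) and the full model, with degrees of freedom
#' equal to the number of fixed-effect terms removed (14 for the full
#' specification).
#'
#' @param fit_full,fit_null `alcohol_glmm_fit` objects fitted to the same
#'   rows (see [fit_null_model()]).
#' @return List with `lr_chisq`, `df` and `p`.
#' @export
null_model_comparison <- function(fit_full, fit_null = NULL) {
  if (is.null(fit_null)) fit_null <- fit_null_model(fit_full)
  if (fit_full$n_days != fit_null$n_days) {
    stop("full and null model were fitted to different rows")
  }
  lr <- fit_null$deviance - fit_full$deviance
  lr <- max(lr, 0) # guard against optimizer noise at lr ~ 0
  df <- length(fit_full$terms) - length(fit_null$terms)
  list(lr_chisq = lr, df = df, p = pchisq(lr, df, lower.tail = FALSE))
}

#' Nakagawa-Schielzeth pseudo-R-squared
#'
#' Variance-explained measures for the logistic mixed model: with sigma_f2
#' the variance of the fixed-effect linear predictor over the estimation
#' rows, sigma_u2 the random-intercept variance and pi^2/3 the logistic
#' distribution-specific variance, the marginal R2 is
#' sigma_f2 / (sigma_f2 + sigma_u2 + pi^2/3) and the conditional R2 is
#' (sigma_f2 + sigma_u2) / (sigma_f2 + sigma_u2 + pi^2/3).
#'
#' @param fit An `alcohol_glmm_fit`.
#' @return List with `r2_marginal`, `r2_conditional`, `sigma_f2`,
#'   `sigma_u2`.
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "alcohol_glmm_fit"))
  X <- lme4::getME(fit$fit, "X")
  eta_f <- as.vector(X %*% lme4::fixef(fit$fit))
  sigma_f2 <- var(eta_f)
  denom <- sigma_f2 + fit$sigma_u2 + pi^2 / 3
  list(
    r2_marginal = sigma_f2 / denom,
    r2_conditional = (sigma_f2 + fit$sigma_u2) / denom,
    sigma_f2 = sigma_f2,
    sigma_u2 = fit$sigma_u2
  )
}

#' Boundary-corrected test of the random intercept
#'
#' Likelihood-ratio test of sigma_u2 = 0 comparing the mixed model with an
#' ordinary logistic regression on the same rows. Because the null value
#' lies on the boundary of the parameter space, the reference distribution
#' is the 50:50 mixture of a point mass at zero and chi-square(1), so the
#' p-value is half the chi-square(1) upper tail.
#'
#' @param fit An `alcohol_glmm_fit`.
#' @return List with `lr_chisq`, `p` and the fixed-only model deviance.
#' @export
random_intercept_test <- function(fit) {
  stopifnot(inherits(fit, "alcohol_glmm_fit"))
  dat <- stats::model.frame(fit$fit)
  form <- as.formula(paste(
    "alcohol ~",
    if (length(fit$terms) > 0) paste(fit$terms, collapse = " + ") else "1"
  ))
  glm0 <- stats::glm(form, data = dat, family = stats::binomial("logit"))
  lr <- max(0, -2 * as.numeric(logLik(glm0)) - fit$deviance)
  list(
    lr_chisq = lr,
    p = 0.5 * pchisq(lr, df = 1, lower.tail = FALSE),
    deviance_fixed_only = -2 * as.numeric(logLik(glm0))
  )
}

#' Prompt-threshold sensitivity series
#'
#' Refits the day-level model under each prompt-count inclusion threshold
#' k (days with at least k answered prompts are retained), tabulating the
#' coefficient estimates and retained-day counts side by side. A threshold
#' whose table cannot be fitted (too few days, constant outcome, ...) is
#' marked failed and the series continues.
#'
#' @param day_table Unfiltered day table (with `prompts_answered`).
#' @param k_values Integer thresholds, each in 1..6 (default 1:6).
#' @param terms Fixed-effect terms (default [MODEL_TERMS]).
#' @return List of class `sensitivity_series`: per k either an
#'   `alcohol_glmm_fit` (with `n_days` the retained count) or a list with
#'   an `error` message.
#' @export
sensitivity_series <- function(day_table, k_values = 1:6,
                               terms = MODEL_TERMS) {
  stopifnot(all(k_values %in% 1:6))
  fits <- lapply(k_values, function(k) {
    tab <- filter_model_days(day_table, min_prompts = k)
    tryCatch(
      fit_alcohol_glmm(tab, terms = terms),
      error = function(e) list(error = conditionMessage(e),
                               n_days = nrow(tab))
    )
  })
  names(fits) <- paste0("k", k_values)
  structure(list(k_values = k_values, fits = fits),
            class = "sensitivity_series")
}

#' Tabulate a sensitivity series
#'
#' @param series A `sensitivity_series`.
#' @return Data frame with one row per threshold: retained days,
#'   participants, and the coefficient of each model term (NA where the
#'   fit failed).
#' @export
summarize_series <- function(series) {
  stopifnot(inherits(series, "sensitivity_series"))
  rows <- lapply(seq_along(series$k_values), function(i) {
    f <- series$fits[[i]]
    out <- data.frame(min_prompts = series$k_values[i])
    if (inherits(f, "alcohol_glmm_fit")) {
      out$n_days <- f$n_days
      out$n_participants <- f$n_participants
      co <- setNames(f$coefficients$b, f$coefficients$term)
      for (t in f$terms) out[[t]] <- unname(co[t])
    } else {
      out$n_days <- f$n_days
      out$n_participants <- NA_integer_
    }
    out
  })
  do.call(rbind, lapply(rows, function(r) {
    r[setdiff(names(rows[[which.max(vapply(rows, ncol, 1L))]]), names(r))] <-
      NA
    r
  }))
}

#' Pooled-variance independent-samples t test
#'
#' Two-sided t test for a difference in means between two independent
#' groups with pooled variance, so df = n1 + n2 - 2 (50 for groups of 24
#' and 28).
#'
#' @param values Numeric vector.
#' @param group Two-level grouping vector of the same length.
#' @return List with `statistic`, `df`, `p` and per-group `summaries`
#'   (n, mean, sd).
#' @export
t_test_independent <- function(values, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  ns <- table(group)
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  tt <- t.test(values ~ group, var.equal = TRUE)
  sums <- do.call(rbind, lapply(levels(group), function(g) {
    x <- values[group == g]
    data.frame(group = g, n = length(x), mean = mean(x), sd = sd(x))
  }))
  list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    summaries = sums
  )
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `r`, `ci` (lower, upper), `df` and `p` (two-sided).
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, conf.level = conf_level)
  list(
    r = unname(ct$estimate),
    ci = as.numeric(ct$conf.int),
    df = unname(ct$parameter),
    p = ct$p.value
  )
}
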