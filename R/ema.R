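#' Score answered EMA prompts
#'
#' Turns the long prompt table (one row per item response) into one row per
#' answered prompt with construct scores. Positive and negative affect are
#' means of their 5 items on the 1-7 scale. Craving (6 items) and
#' rumination (4 items) are anchored 1 = "I totally agree" to 7 = "I
#' totally disagree", so items are reverse-coded as `8 - x` before
#' averaging; higher scores then mean more craving / more rumination. The
#' social-context item "Are you currently alone?" is mapped to 1 (alone) /
#' 0 (not alone).
#'
#' @param ema Long data frame with columns `participant_id`, `date`,
#'   `slot`, `item_id`, `response`. A prompt is considered answered iff it
#'   has at least one row.
#' @return Data frame with one row per answered prompt: `participant_id`,
#'   `date`, `slot`, `pa`, `na`, `craving`, `rumination`, `alone`.
#' @export
score_prompts <- function(ema) {
  stopifnot(all(c("participant_id", "date", "slot", "item_id", "response")
                %in% names(ema)))
  bad_slot <- setdiff(unique(ema$slot), PROMPT_SLOTS)
  if (length(bad_slot) > 0) {
    stop("unknown prompt slot: ", paste(bad_slot, collapse = ", "))
  }
  likert <- ema$item_id %in% unlist(EMA_ITEMS[c("pa", "na", "craving",
                                                "rumination")])
  bad <- likert & (ema$response < 1 | ema$response > 7 |
                     ema$response != round(ema$response))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(
      "response out of 1-7 range for item ", ema$item_id[i],
      " (value ", ema$response[i], ")"
    )
  }
  binar <- ema$item_id %in% unlist(EMA_ITEMS[c("alone", "alcohol")])
  bad <- binar & !(ema$response %in% c(0, 1))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(
      "response must be 0/1 for item ", ema$item_id[i],
      " (value ", ema$response[i], ")"
    )
  }
  alc <- ema$item_id == EMA_ITEMS$alcohol
  if (any(alc & ema$slot != "09:00")) {
    stop("alcohol item present outside the 09:00 slot")
  }

  key <- interaction(ema$participant_id, ema$date, ema$slot, drop = TRUE)
  score_one <- function(rows) {
    resp <- function(ids) {
      x <- rows$response[rows$item_id %in% ids]
      if (length(x) == 0) NA_real_ else mean(x)
    }
    data.frame(
      participant_id = rows$participant_id[1],
      date = rows$date[1],
      slot = rows$slot[1],
      pa = resp(EMA_ITEMS$pa),
      na = resp(EMA_ITEMS$na),
      craving = 8 - resp(EMA_ITEMS$craving),
      rumination = 8 - resp(EMA_ITEMS$rumination),
      alone = resp(EMA_ITEMS$alone),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(split(ema, key), score_one))
  out <- out[order(out$participant_id, out$date, out$slot), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate prompt scores to participant-days
#'
#' Construct scores are averaged over the day's answered prompts; the
#' social context is the fraction of answered prompts on which the
#' participant reported being alone (a `social = "sum"` variant returns
#' the raw count of alone prompts instead). The number of answered prompts
#' is recorded for later prompt-count filtering.
#'
#' @param prompt_scores Output of [score_prompts()].
#' @param social Either "proportion" (default) or "sum".
#' @return Data frame with one row per participant-day: construct means,
#'   `social_context` and `prompts_answered`.
#' @export
aggregate_days <- function(prompt_scores, social = c("proportion", "sum")) {
  social <- match.arg(social)
  key <- interaction(prompt_scores$participant_id, prompt_scores$date,
                     drop = TRUE)
  agg_one <- function(rows) {
    alone <- rows$alone[!is.na(rows$alone)]
    sc <- if (length(alone) == 0) {
      NA_real_
    } else if (social == "proportion") {
      mean(alone)
    } else {
      sum(alone)
    }
    data.frame(
      participant_id = rows$participant_id[1],
      date = rows$date[1],
      pa = mean(rows$pa, na.rm = TRUE),
      na = mean(rows$na, na.rm = TRUE),
      craving = mean(rows$craving, na.rm = TRUE),
      rumination = mean(rows$rumination, na.rm = TRUE),
      social_context = sc,
      prompts_answered = nrow(rows),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(split(prompt_scores, key), agg_one))
  out <- out[order(out$participant_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Day-shift the morning alcohol report
#'
#' The item "Did you drink alcohol yesterday?" is asked once a day in the
#' 09:00 prompt; its answer on date d is assigned as the drinking outcome
#' of date d - 1, so each day's outcome sits next to that day's
#' experiences. A missed 09:00 prompt leaves the previous day's outcome
#' missing (no row is emitted for it).
#'
#' @param ema Long EMA data frame (see [score_prompts()]).
#' @return Data frame `participant_id`, `date`, `alcohol` (0/1), where
#'   `date` is the day the drinking refers to.
#' @export
shift_alcohol <- function(ema) {
  rows <- ema[ema$item_id == EMA_ITEMS$alcohol & ema$slot == "09:00", ,
              drop = FALSE]
  if (nrow(rows) == 0) {
    return(data.frame(
      participant_id = character(0), date = as.Date(character(0)),
      alcohol = numeric(0)
    ))
  }
  out <- data.frame(
    participant_id = rows$participant_id,
    date = as.Date(rows$date) - 1L,
    alcohol = as.numeric(rows$response),
    stringsAsFactors = FALSE
  )
  out[order(out$participant_id, out$date), , drop = FALSE]
}

#' Weekend flag for a date
#'
#' The study's day-type classification: Friday, Saturday and Sunday count
#' as weekend; Monday through Thursday as weekdays.
#'
#' @param date `Date` vector (or something coercible).
#' @return Logical vector, TRUE for Fri/Sat/Sun.
#' @export
weekend_flag <- function(date) {
  as.integer(format(as.Date(date), "%u")) >= 5L
}

#' Per-participant compliance report
#'
#' Compliance is the number of answered prompts divided by the number of
#' scheduled prompts over the study window (6 per day, 84 for the default
#' 14-day protocol). Participants with a compliance rate below 50% are
#' flagged for exclusion from modelling.
#'
#' @param ema Long EMA data frame; a prompt counts as answered iff it has
#'   at least one response row dated within the study window.
#' @param participants Optional participant metadata; guarantees a row
#'   (answered = 0) for participants with no responses at all.
#' @param start_date First study day (default: earliest date in `ema`).
#' @param n_days Number of study days (default 14).
#' @param min_rate Inclusion threshold on the rate (default 0.5).
#' @return Data frame `participant_id`, `answered`, `possible`, `rate`,
#'   `included`.
#' @export
compliance_report <- function(ema, participants = NULL, start_date = NULL,
                              n_days = 14, min_rate = 0.5) {
  if (is.null(start_date)) start_date <- min(as.Date(ema$date))
  start_date <- as.Date(start_date)
  window <- as.Date(ema$date) >= start_date &
    as.Date(ema$date) <= start_date + (n_days - 1L)
  prompts <- unique(ema[window, c("participant_id", "date", "slot")])
  answered <- table(prompts$participant_id)
  ids <- names(answered)
  if (!is.null(participants)) {
    ids <- union(as.character(participants$participant_id), ids)
  }
  n_ans <- as.integer(answered[ids])
  n_ans[is.na(n_ans)] <- 0L
  possible <- n_days * length(PROMPT_SLOTS)
  out <- data.frame(
    participant_id = ids,
    answered = n_ans,
    possible = possible,
    rate = n_ans / possible,
    stringsAsFactors = FALSE
  )
  out$included <- out$rate >= min_rate
  out[order(out$participant_id), , drop = FALSE]
}

#' Filter participant-days for modelling
#'
#' Retains days with at least `min_prompts` answered prompts, an observed
#' (day-shifted) alcohol outcome and complete geospatial summaries.
#'
#' @param day_table Model day table (see [build_day_table()]).
#' @param min_prompts Required answered prompts per day, in 1..6.
#' @return The filtered table; the number of dropped rows per reason is
#'   attached as attribute `exclusions`.
#' @export
filter_model_days <- function(day_table, min_prompts = 4) {
  if (!is.numeric(min_prompts) || length(min_prompts) != 1 ||
        !(min_prompts %in% 1:6)) {
    stop("min_prompts must be a single integer in 1..6")
  }
  few <- day_table$prompts_answered < min_prompts
  no_outcome <- is.na(day_table$alcohol)
  no_geo <- is.na(day_table$roaming_entropy)
  keep <- !few & !no_outcome & !no_geo
  out <- day_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(
    too_few_prompts = sum(few),
    missing_outcome = sum(no_outcome & !few),
    missing_geo = sum(no_geo & !few & !no_outcome)
  )
  out
}

#' AUDIT sum score
#'
#' Sum of the 10 Alcohol Use Disorder Identification Test items, each
#' scored 0-4, giving a 0-40 hazardous-drinking score.
#'
#' @param items Numeric vector of exactly 10 item scores in 0..4.
#' @return Integer sum in 0..40.
#' @export
audit_sum <- function(items) {
  if (length(items) != 10) {
    stop("AUDIT requires exactly 10 items, got ", length(items))
  }
  if (any(is.na(items)) || any(items < 0 | items > 4) ||
        any(items != round(items))) {
    stop("AUDIT items must be integers in 0..4")
  }
  as.integer(sum(items))
}

#' Assemble the model-ready day table
#'
#' Joins daily EMA aggregates, the day-shifted alcohol outcome, the
#' weekend flag, geospatial day summaries and person-level covariates into
#' the table the multilevel model is fitted on. Age group is coded 0 for
#' 14-year-olds and 1 for 16-year-olds; sex 0 for male and 1 for female.
#'
#' @param ema Long EMA data frame.
#' @param geo Output of [geo_day_summaries()] (or NULL to leave geospatial
#'   columns missing).
#' @param participants Participant metadata with `participant_id`,
#'   `age_group` (14/16), `sex` ("male"/"female").
#' @param social Passed to [aggregate_days()].
#' @return Day table with one row per participant-day that had at least
#'   one answered prompt.
#' @export
build_day_table <- function(ema, geo, participants,
                            social = c("proportion", "sum")) {
  social <- match.arg(social)
  days <- aggregate_days(score_prompts(ema), social = social)
  days$date <- as.Date(days$date)
  alco <- shift_alcohol(ema)
  days$alcohol <- alco$alcohol[match(
    paste(days$participant_id, days$date),
    paste(alco$participant_id, alco$date)
  )]
  days$weekend <- as.numeric(weekend_flag(days$date))
  geo_cols <- c("roaming_entropy", paste0("tp_", TP_CATEGORIES))
  if (!is.null(geo)) {
    idx <- match(
      paste(days$participant_id, days$date),
      paste(geo$participant_id, as.Date(geo$date))
    )
    for (cl in geo_cols) days[[cl]] <- geo[[cl]][idx]
  } else {
    for (cl in geo_cols) days[[cl]] <- NA_real_
  }
  pid <- match(days$participant_id, participants$participant_id)
  if (anyNA(pid)) {
    stop("EMA contains participants absent from the metadata table")
  }
  days$age_group <- as.numeric(participants$age_group[pid] == 16)
  days$sex <- as.numeric(participants$sex[pid] == "female")
  days
}
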