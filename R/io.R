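#' Read a GPS fix table
#'
#' @param path CSV with columns `participant_id`, `timestamp` (ISO-8601),
#'   `lat`, `lon`.
#' @return Data frame of fixes.
#' @export
read_gps_csv <- function(path) {
  gps <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(gps))) {
    stop("GPS CSV must have columns: ", paste(need, collapse = ", "))
  }
  gps
}

#' Read a long EMA response table
#'
#' @param path CSV with columns `participant_id`, `date`, `slot`,
#'   `item_id`, `response`.
#' @return Data frame with `date` parsed to `Date`.
#' @export
read_ema_csv <- function(path) {
  ema <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "date", "slot", "item_id", "response")
  if (!all(need %in% names(ema))) {
    stop("EMA CSV must have columns: ", paste(need, collapse = ", "))
  }
  ema$date <- as.Date(ema$date)
  ema
}

#' Read a participant metadata table
#'
#' @param path CSV with columns `participant_id`, `age_group`, `sex`,
#'   `covid_period` and `audit_1`..`audit_10`.
#' @return Data frame with an added `audit_total` column.
#' @export
read_participants_csv <- function(path) {
  pp <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age_group", "sex", "covid_period",
            paste0("audit_", 1:10))
  if (!all(need %in% names(pp))) {
    stop("participant CSV must have columns: ",
         paste(setdiff(need, names(pp)), collapse = ", "))
  }
  pp$audit_total <- vapply(
    seq_len(nrow(pp)),
    function(i) audit_sum(as.numeric(pp[i, paste0("audit_", 1:10)])),
    integer(1)
  )
  pp
}

#' Read a POI map from GeoJSON
#'
#' Accepts a FeatureCollection of Point features with a `category`
#' property drawn from the closed five-element trigger-point set.
#'
#' @param path GeoJSON file.
#' @return Data frame `lat`, `lon`, `category`, `label`.
#' @export
read_poi_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("POI file is not a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Point")) {
      stop("POI feature ", i, " is not a Point geometry")
    }
    cat <- f$properties$category
    if (is.null(cat) || !cat %in% TP_CATEGORIES) {
      stop("POI feature ", i, " has unknown category '",
           if (is.null(cat)) "" else cat, "'")
    }
    data.frame(
      lat = as.numeric(f$geometry$coordinates[[2]]),
      lon = as.numeric(f$geometry$coordinates[[1]]),
      category = cat,
      label = if (is.null(f$properties$label)) "" else f$properties$label,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(lat = numeric(0), lon = numeric(0),
                      category = character(0), label = character(0))
  }
  out
}

#' Write a POI map to GeoJSON
#'
#' @param pois Data frame `lat`, `lon`, `category`, optional `label`.
#' @param path Output file.
#' @export
write_poi_geojson <- function(pois, path) {
  feats <- lapply(seq_len(nrow(pois)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "Point",
        coordinates = c(pois$lon[i], pois$lat[i])
      ),
      properties = list(
        category = pois$category[i],
        label = if ("label" %in% names(pois)) pois$label[i] else ""
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a synthetic study to the four pipeline input files
#'
#' Materializes a [simulate_study()] result as the file formats the
#' pipeline consumes — GPS CSV, long EMA CSV, participant CSV, POI
#' GeoJSON — plus the latent truth table (CSV) and the generator
#' configuration (JSON sidecar).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gps = file.path(dir, "gps.csv"),
    ema = file.path(dir, "ema.csv"),
    participants = file.path(dir, "participants.csv"),
    pois = file.path(dir, "pois.geojson"),
    truth = file.path(dir, "truth.csv"),
    config = file.path(dir, "config.json")
  )
  write.csv(study$gps, paths["gps"], row.names = FALSE)
  write.csv(study$prompts, paths["ema"], row.names = FALSE)
  pp <- study$participants
  pp$u <- NULL # latent; lives in the truth table
  write.csv(pp, paths["participants"], row.names = FALSE)
  write_poi_geojson(study$pois, paths["pois"])
  truth <- study$truth
  write.csv(truth, paths["truth"], row.names = FALSE)
  cfg <- study$config
  cfg$start_date <- as.character(cfg$start_date)
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Validate pipeline input files
#'
#' Schema and range checks for the four input files. Findings are
#' returned as a data frame (file, line, message); `strict = TRUE`
#' (default) turns any finding into an error.
#'
#' @param gps_path,ema_path,participants_path,pois_path File paths; NULL
#'   entries are skipped.
#' @param strict Stop on first summary of findings (default TRUE).
#' @return Data frame of findings (zero rows when everything is
#'   well-formed), invisibly when strict.
#' @export
validate_inputs <- function(gps_path = NULL, ema_path = NULL,
                            participants_path = NULL, pois_path = NULL,
                            strict = TRUE) {
  findings <- list()
  note <- function(file, line, msg) {
    findings[[length(findings) + 1]] <<- data.frame(
      file = file, line = line, message = msg, stringsAsFactors = FALSE
    )
  }
  if (!is.null(gps_path)) {
    gps <- read.csv(gps_path, stringsAsFactors = FALSE)
    need <- c("participant_id", "timestamp", "lat", "lon")
    if (!all(need %in% names(gps))) {
      note(gps_path, 1L, paste("missing columns:",
                               paste(setdiff(need, names(gps)),
                                     collapse = ", ")))
    } else {
      bad <- which(abs(gps$lat) > 90 | abs(gps$lon) > 180)
      for (i in head(bad, 20)) {
        note(gps_path, i + 1L,
             sprintf("coordinates out of range: lat=%s lon=%s",
                     gps$lat[i], gps$lon[i]))
      }
      ts <- suppressWarnings(parse_timestamp(gps$timestamp))
      bad <- which(is.na(ts))
      for (i in head(bad, 20)) {
        note(gps_path, i + 1L,
             paste("unparseable timestamp:", gps$timestamp[i]))
      }
    }
  }
  if (!is.null(ema_path)) {
    ema <- read.csv(ema_path, stringsAsFactors = FALSE)
    need <- c("participant_id", "date", "slot", "item_id", "response")
    if (!all(need %in% names(ema))) {
      note(ema_path, 1L, paste("missing columns:",
                               paste(setdiff(need, names(ema)),
                                     collapse = ", ")))
    } else {
      bad <- which(!ema$slot %in% PROMPT_SLOTS)
      for (i in head(bad, 20)) {
        note(ema_path, i + 1L, paste("unknown prompt slot:", ema$slot[i]))
      }
      likert <- ema$item_id %in% unlist(EMA_ITEMS[c("pa", "na", "craving",
                                                    "rumination")])
      bad <- which(likert & (ema$response < 1 | ema$response > 7))
      for (i in head(bad, 20)) {
        note(ema_path, i + 1L,
             sprintf("item %s response %s outside 1-7", ema$item_id[i],
                     ema$response[i]))
      }
    }
  }
  if (!is.null(participants_path)) {
    pp <- read.csv(participants_path, stringsAsFactors = FALSE)
    need <- c("participant_id", "age_group", "sex")
    if (!all(need %in% names(pp))) {
      note(participants_path, 1L,
           paste("missing columns:",
                 paste(setdiff(need, names(pp)), collapse = ", ")))
    } else {
      bad <- which(!pp$age_group %in% c(14, 16))
      for (i in head(bad, 20)) {
        note(participants_path, i + 1L,
             paste("age_group must be 14 or 16, got", pp$age_group[i]))
      }
      bad <- which(!pp$sex %in% c("male", "female"))
      for (i in head(bad, 20)) {
        note(participants_path, i + 1L,
             paste("sex must be male/female, got", pp$sex[i]))
      }
    }
  }
  if (!is.null(pois_path)) {
    gj <- tryCatch(jsonlite::read_json(pois_path), error = function(e) NULL)
    if (is.null(gj) || !identical(gj$type, "FeatureCollection")) {
      note(pois_path, 1L, "not a GeoJSON FeatureCollection")
    } else {
      for (i in seq_along(gj$features)) {
        f <- gj$features[[i]]
        if (is.null(f$geometry) || !identical(f$geometry$type, "Point")) {
          note(pois_path, i, paste("feature", i, "is not a Point"))
        } else if (is.null(f$properties$category) ||
                     !f$properties$category %in% TP_CATEGORIES) {
          note(pois_path, i,
               paste0("feature ", i, " has unknown category '",
                      f$properties$category, "'"))
        }
      }
    }
  }
  out <- if (length(findings) == 0) {
    data.frame(file = character(0), line = integer(0),
               message = character(0))
  } else {
    do.call(rbind, findings)
  }
  if (strict && nrow(out) > 0) {
    stop(
      "input validation failed:\n",
      paste(sprintf("  %s:%d %s", out$file, out$line, out$message),
            collapse = "\n")
    )
  }
  out
}
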