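#' Great-circle distance in metres
#'
#' Haversine distance on a sphere of radius 6,371,000 m. All arguments are
#' recycled to a common length, so the function works on scalar pairs as
#' well as whole fix vectors against a single point of interest.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @param radius_m Sphere radius in metres.
#' @return Numeric vector of distances in metres.
#' @examples
#' haversine_m(49.4873, 8.4661, 49.4873, 8.4661)      # 0
#' haversine_m(49.4873, 8.4661, 49.4874, 8.4661)      # ~11.1 m
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2, radius_m = 6371000) {
  stopifnot(
    all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE),
    all(abs(lon1) <= 180, na.rm = TRUE), all(abs(lon2) <= 180, na.rm = TRUE)
  )
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * radius_m * asin(pmin(1, sqrt(a)))
}

#' Round coordinates half-away-from-zero
#'
#' Decimal rounding of coordinates with ties going away from zero (so
#' 49.48735 -> 49.4874), as opposed to the round-half-even rule of
#' [base::round()]. A small inner rounding step removes binary
#' floating-point fuzz before the tie test.
#'
#' @param x Numeric vector (decimal degrees).
#' @param decimals Number of decimal places to keep.
#' @return Numeric vector rounded to `decimals` places.
#' @export
round_half_away <- function(x, decimals = 4) {
  scale <- 10^decimals
  scaled <- round(abs(x) * scale, 6)
  sign(x) * floor(scaled + 0.5) / scale
}

#' Discretize a trajectory into grid cells
#'
#' Maps every GPS fix to a "place": the latitude-longitude pair rounded to
#' `decimals` decimal places (4 decimals is roughly an 11 m cell). Returns
#' the visit frequency of each unique cell, the multiset over which roaming
#' entropy is defined.
#'
#' @param trajectory Data frame with numeric columns `lat` and `lon`,
#'   ordered in time.
#' @param decimals Decimal places defining the cell size (default 4).
#' @return Data frame with one row per unique cell: `cell` (identifier
#'   string), `lat`, `lon` (rounded coordinates) and `n` (visit count),
#'   ordered by first visit. The attribute `cell_seq` carries the per-fix
#'   cell sequence.
#' @export
discretize <- function(trajectory, decimals = 4) {
  if (is.null(trajectory) || nrow(trajectory) == 0) {
    stop("trajectory is empty; cannot discretize")
  }
  lat <- round_half_away(trajectory$lat, decimals)
  lon <- round_half_away(trajectory$lon, decimals)
  fmt <- paste0("%.", decimals, "f")
  cell <- paste(sprintf(fmt, lat), sprintf(fmt, lon), sep = "_")
  first <- !duplicated(cell)
  counts <- as.vector(table(factor(cell, levels = cell[first])))
  out <- data.frame(
    cell = cell[first], lat = lat[first], lon = lon[first], n = counts,
    stringsAsFactors = FALSE
  )
  attr(out, "cell_seq") <- cell
  out
}

# Normalized Shannon entropy of a visit-count vector, given the number of
# fixes T used as the normalizing constant log(T).
entropy_from_counts <- function(counts, n_fixes = sum(counts)) {
  if (n_fixes <= 1 || length(counts) <= 1) {
    return(0)
  }
  p <- counts / n_fixes
  re <- -sum(p * log(p)) / log(n_fixes)
  min(max(re, 0), 1)
}

#' Daily roaming entropy of a GPS trajectory
#'
#' Normalized Shannon entropy of the within-day visit frequencies over
#' discretized places: RE = -sum(p_i log p_i) / log(T), where p_i is the
#' fraction of the day's T fixes spent in cell i. RE is 0 for a participant
#' who never left one cell and 1 when every recorded fix fell in a distinct
#' cell. The normalizing constant log(T) is what makes the all-unique day
#' equal exactly 1; the base of the inner logarithm then cancels.
#'
#' @inheritParams discretize
#' @return Roaming entropy, a unitless value in \[0, 1\].
#' @export
roaming_entropy <- function(trajectory, decimals = 4) {
  if (is.null(trajectory) || nrow(trajectory) == 0) {
    stop("trajectory is empty; roaming entropy is undefined")
  }
  cells <- discretize(trajectory, decimals)
  entropy_from_counts(cells$n, nrow(trajectory))
}

#' Trigger-point contact episodes per category
#'
#' Counts, for each trigger-point category, the number of contact episodes
#' during a day: maximal runs of consecutive fixes within `radius_m` of at
#' least one point of interest (POI) of that category. Staying inside the
#' radius for many consecutive fixes counts as a single contact; leaving
#' for at least one fix and re-entering starts a new one. A fix inside the
#' radius of POIs of several categories contributes to each of them.
#'
#' @param trajectory Data frame with `lat`, `lon`, ordered in time.
#' @param pois Data frame with columns `lat`, `lon`, `category` (values
#'   from [TP_CATEGORIES]). May have zero rows.
#' @param radius_m Contact radius in metres (default 15).
#' @return Named integer vector of episode counts, one entry per category
#'   in [TP_CATEGORIES] (zero where no POI of the category exists).
#' @export
tp_contacts <- function(trajectory, pois, radius_m = 15) {
  stopifnot(is.data.frame(trajectory), nrow(trajectory) >= 1)
  counts <- setNames(integer(length(TP_CATEGORIES)), TP_CATEGORIES)
  if (is.null(pois) || nrow(pois) == 0) {
    return(counts)
  }
  bad <- setdiff(unique(pois$category), TP_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown POI category: ", paste(bad, collapse = ", "))
  }
  n <- nrow(trajectory)
  for (cat in TP_CATEGORIES) {
    pc <- pois[pois$category == cat, , drop = FALSE]
    if (nrow(pc) == 0) next
    inside <- rep(FALSE, n)
    for (k in seq_len(nrow(pc))) {
      inside <- inside |
        (haversine_m(trajectory$lat, trajectory$lon, pc$lat[k], pc$lon[k]) <=
           radius_m)
    }
    # an episode starts wherever 'inside' switches FALSE -> TRUE
    counts[cat] <- sum(inside & !c(FALSE, inside[-n]))
  }
  counts
}

# Parse ISO-8601-ish timestamps in a fixed timezone.
parse_timestamp <- function(x, tz = "Europe/Berlin") {
  if (inherits(x, "POSIXct")) {
    return(x)
  }
  as.POSIXct(
    x,
    tz = tz,
    tryFormats = c(
      "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
      "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"
    ),
    optional = TRUE
  )
}

#' Per-participant-day geospatial summaries
#'
#' Splits a GPS fix table into participant-days (local civil date in `tz`),
#' deduplicates timestamps within a day (first fix wins), and computes for
#' each day the roaming entropy, trigger-point contact counts, number of
#' fixes and number of unique cells.
#'
#' @param gps Data frame with columns `participant_id`, `timestamp`
#'   (ISO-8601 character or POSIXct), `lat`, `lon`.
#' @param pois POI data frame (`lat`, `lon`, `category`), or NULL for no
#'   trigger points.
#' @param radius_m Contact radius in metres (default 15).
#' @param decimals Cell size for discretization (default 4).
#' @param tz Timezone defining the day boundary (default "Europe/Berlin").
#' @return Data frame with one row per participant-day: `participant_id`,
#'   `date`, `roaming_entropy`, `tp_<category>` counts, `n_fixes`,
#'   `n_unique_cells`.
#' @export
geo_day_summaries <- function(gps, pois = NULL, radius_m = 15, decimals = 4,
                              tz = "Europe/Berlin") {
  stopifnot(all(c("participant_id", "timestamp", "lat", "lon") %in%
                  names(gps)))
  if (nrow(gps) == 0) stop("GPS table is empty")
  if (any(abs(gps$lat) > 90) || any(abs(gps$lon) > 180)) {
    stop("GPS coordinates out of range")
  }
  ts <- parse_timestamp(gps$timestamp, tz)
  if (anyNA(ts)) stop("unparseable GPS timestamps")
  ord <- order(gps$participant_id, ts)
  gps <- gps[ord, , drop = FALSE]
  ts <- ts[ord]
  date <- as.Date(format(ts, "%Y-%m-%d", tz = tz))
  key <- paste(gps$participant_id, date)
  dup <- duplicated(paste(key, format(ts, "%Y-%m-%d %H:%M:%OS3", tz = tz)))
  gps <- gps[!dup, , drop = FALSE]
  date <- date[!dup]
  key <- key[!dup]

  groups <- split(seq_len(nrow(gps)), key)
  rows <- lapply(groups, function(idx) {
    traj <- gps[idx, , drop = FALSE]
    cells <- discretize(traj, decimals)
    re <- entropy_from_counts(cells$n, nrow(traj))
    tp <- tp_contacts(traj, pois, radius_m)
    out <- data.frame(
      participant_id = traj$participant_id[1],
      date = date[idx[1]],
      roaming_entropy = re,
      n_fixes = nrow(traj),
      n_unique_cells = nrow(cells),
      stringsAsFactors = FALSE
    )
    for (cat in TP_CATEGORIES) out[[paste0("tp_", cat)]] <- unname(tp[cat])
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  cols <- c(
    "participant_id", "date", "roaming_entropy",
    paste0("tp_", TP_CATEGORIES), "n_fixes", "n_unique_cells"
  )
  out[, cols]
}
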