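# Small-scale generator configuration for fast pipeline tests. The default
# generator_config() carries the study-scale conditions; tests of pipeline
# mechanics use this reduced geometry instead.
tiny_config <- function(...) {
  args <- list(
    n_participants = 6, n_days = 7, fixes_per_day = 60,
    compliance_p = 0.9, n_poi_near = 2, n_poi_far = 2
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

# Build a trajectory data frame at explicit coordinates (one fix per row,
# minute-spaced timestamps on one day).
make_traj <- function(lat, lon, id = "P1", date = "2021-03-01") {
  n <- length(lat)
  data.frame(
    participant_id = id,
    timestamp = sprintf("%sT%02d:%02d:00", date, (seq_len(n) - 1) %/% 60,
                        (seq_len(n) - 1) %% 60),
    lat = lat,
    lon = lon,
    stringsAsFactors = FALSE
  )
}

# Brute-force roaming-entropy oracle: tabulate rounded coordinate pairs
# with an explicit loop and evaluate -sum(p log p)/log(T) directly.
re_oracle <- function(lat, lon, decimals = 4) {
  r <- function(x) sign(x) * floor(round(abs(x) * 10^decimals, 6) + 0.5)
  key <- paste(r(lat), r(lon))
  t_fix <- length(key)
  if (t_fix <= 1) return(0)
  counts <- c(table(key))
  if (length(counts) <= 1) return(0)
  h <- 0
  for (ci in counts) {
    p <- ci / t_fix
    h <- h - p * log(p)
  }
  min(1, h / log(t_fix))
}

# First k grid anchors of the synthetic city (internal pool).
anchor_pool_fixture <- function(cfg, k) {
  emaroam:::anchor_pool(cfg)[seq_len(k), , drop = FALSE]
}

# Default covariate parameters with an explicit roaming-entropy SD, for
# configurations whose coefficient vector makes the derived SD undefined
# (e.g. a zero roaming-entropy coefficient).
tweak_re_sd <- function(sd = 0.07) {
  cp <- emaroam:::default_covariate_params()
  cp$roaming_entropy$sd <- sd
  cp
}

# Episode-count oracle: explicit run-length walk over an inside/outside
# logical sequence.
episode_oracle <- function(inside) {
  n_ep <- 0L
  prev <- FALSE
  for (v in inside) {
    if (v && !prev) n_ep <- n_ep + 1L
    prev <- v
  }
  n_ep
}
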