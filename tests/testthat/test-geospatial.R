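test_that("haversine distance matches known values and is symmetric", {
  expect_equal(haversine_m(49.4873, 8.4661, 49.4873, 8.4661), 0)
  # one 4th-decimal step in latitude is ~11.1 m (the cell size)
  d <- haversine_m(49.4873, 8.4661, 49.4874, 8.4661)
  expect_equal(d, 0.0001 * pi / 180 * 6371000, tolerance = 1e-6)
  expect_lt(abs(d - 11.12), 0.01)

  set.seed(7)
  for (i in 1:20) {
    a <- c(runif(1, -80, 80), runif(1, -170, 170))
    b <- a + runif(2, -0.5, 0.5)
    expect_equal(
      haversine_m(a[1], a[2], b[1], b[2]),
      haversine_m(b[1], b[2], a[1], a[2])
    )
    # cross-check against an established geodesic library on one sphere
    expect_equal(
      haversine_m(a[1], a[2], b[1], b[2]),
      geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]), r = 6371000),
      tolerance = 1e-9
    )
  }
})

test_that("coordinate rounding is half-away-from-zero on the 4th decimal", {
  expect_equal(round_half_away(49.48735), 49.4874)
  expect_equal(round_half_away(8.46615), 8.4662)
  expect_equal(round_half_away(-49.48735), -49.4874)
  expect_equal(round_half_away(49.48731), 49.4873)
  expect_equal(round_half_away(49.48734), 49.4873)
})

test_that("discretize maps nearby fixes to one cell and counts visits", {
  tr <- make_traj(c(49.48731, 49.48734), c(8.46612, 8.46608))
  cells <- discretize(tr)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$lat, 49.4873)
  expect_equal(cells$lon, 8.4661)
  expect_equal(cells$n, 2)

  tr <- make_traj(rep(49.4873, 1440), rep(8.4661, 1440))
  cells <- discretize(tr)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$n, 1440)

  expect_error(discretize(data.frame(lat = numeric(0), lon = numeric(0))),
               "empty")
})

test_that("roaming entropy hits its exact endpoints and derived value", {
  # no movement -> 0
  expect_identical(roaming_entropy(make_traj(rep(49.5, 100),
                                             rep(8.5, 100))), 0)
  # every place unique -> exactly 1
  n <- 64
  tr <- make_traj(49.4 + (0:(n - 1)) * 1e-3, rep(8.4, n))
  expect_equal(roaming_entropy(tr), 1)
  # frequencies (3, 1) over 4 fixes
  tr <- make_traj(c(49.4, 49.4, 49.4, 49.5), c(8.4, 8.4, 8.4, 8.4))
  expect_equal(roaming_entropy(tr),
               -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(4),
               tolerance = 1e-12)
  expect_equal(roaming_entropy(tr), 0.405639, tolerance = 1e-6)
  # single fix -> defined as 0
  expect_identical(roaming_entropy(make_traj(49.4, 8.4)), 0)
})

test_that("roaming entropy equals the brute-force oracle on random days", {
  set.seed(11)
  for (i in 1:150) {
    t_fix <- sample(2:200, 1)
    n_cells <- sample(1:min(t_fix, 30), 1)
    which_cell <- sample.int(n_cells, t_fix, replace = TRUE)
    lat <- 49.4 + which_cell * 1e-3 + runif(t_fix, -4e-5, 4e-5)
    lon <- 8.4 + runif(t_fix, -4e-5, 4e-5)
    expect_equal(roaming_entropy(make_traj(lat, lon)),
                 re_oracle(lat, lon), tolerance = 1e-12)
  }
})

test_that("splitting one cell's visits never decreases roaming entropy", {
  set.seed(13)
  for (i in 1:60) {
    counts <- sample(1:30, sample(2:8, 1), replace = TRUE)
    counts <- counts[counts > 0]
    t_fix <- sum(counts)
    re0 <- emaroam:::entropy_from_counts(counts, t_fix)
    j <- which(counts >= 2)[1]
    if (is.na(j)) next
    a <- sample(seq_len(counts[j] - 1), 1)
    split_counts <- c(counts[-j], a, counts[j] - a)
    expect_gte(emaroam:::entropy_from_counts(split_counts, t_fix) + 1e-12,
               re0)
  }
})

test_that("contact episodes follow the 15 m closeness rule", {
  poi <- data.frame(lat = 49.4873, lon = 8.4661, category = "nightlife")
  # stationary day ~5 m from the POI: one single episode
  near <- make_traj(rep(49.48734, 50), rep(8.46610, 50))
  counts <- tp_contacts(near, poi)
  expect_equal(unname(counts["nightlife"]), 1)
  expect_equal(sum(counts), 1)
  # in, out for 10 fixes, back in: two episodes
  inlat <- 49.4873
  outlat <- 49.4873 + 5e-4 # ~55 m away
  tr <- make_traj(c(rep(inlat, 5), rep(outlat, 10), rep(inlat, 5)),
                  rep(8.4661, 20))
  expect_equal(unname(tp_contacts(tr, poi)["nightlife"]), 2)
  # 20 m away is out of radius
  tr20 <- make_traj(rep(49.4873 + 1.8e-4, 10), rep(8.4661, 10))
  expect_equal(sum(tp_contacts(tr20, poi)), 0)
  # empty POI map: all-zero counts, not an error
  expect_equal(sum(tp_contacts(tr, poi[0, ])), 0)
})

test_that("a fix can be in contact with several categories at once", {
  pois <- data.frame(
    lat = c(49.4873, 49.48731),
    lon = c(8.4661, 8.46611),
    category = c("peers", "leisure")
  )
  tr <- make_traj(rep(49.4873, 10), rep(8.4661, 10))
  counts <- tp_contacts(tr, pois)
  expect_equal(unname(counts["peers"]), 1)
  expect_equal(unname(counts["leisure"]), 1)
})

test_that("episode counts are robust to small radius changes and fix rate", {
  set.seed(17)
  poi <- data.frame(lat = c(49.4873, 49.4891), lon = c(8.4661, 8.4661),
                    category = c("peers", "peers"))
  # path dwells either exactly at POIs or >= 25 m away
  cells_lat <- c(49.4873, 49.4880, 49.4891, 49.4880, 49.4873)
  tr <- make_traj(rep(cells_lat, each = 6), rep(8.4661, 30))
  c14 <- tp_contacts(tr, poi, radius_m = 14)
  c16 <- tp_contacts(tr, poi, radius_m = 16)
  expect_identical(c14, c16)
  # doubling the fix rate with unchanged geometry collapses identically
  tr2 <- make_traj(rep(cells_lat, each = 12), rep(8.4661, 60))
  expect_identical(tp_contacts(tr, poi), tp_contacts(tr2, poi))
})

test_that("day summaries split by local date and drop duplicate stamps", {
  gps <- rbind(
    make_traj(rep(49.4873, 10), rep(8.4661, 10), date = "2021-03-01"),
    make_traj(49.4 + (0:9) * 1e-3, rep(8.4, 10), date = "2021-03-02")
  )
  # a duplicated timestamp at a different place: first fix wins
  dup <- gps[1, ]
  dup$lat <- 49.9
  gps <- rbind(gps, dup)
  out <- geo_day_summaries(gps, pois = NULL)
  expect_equal(nrow(out), 2)
  expect_equal(out$n_fixes, c(10, 10))
  expect_equal(out$roaming_entropy, c(0, 1))
  expect_true(all(out[, paste0("tp_", TP_CATEGORIES)] == 0))
  expect_error(geo_day_summaries(gps[0, ]), "empty")
})
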