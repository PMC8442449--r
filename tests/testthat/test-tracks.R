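write_csv_fixture <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("animal_id,timestamp,x,y", rows), path)
  path
}

test_that("CSV ingestion sorts, validates and splits by animal", {
  p <- write_csv_fixture(c("a1,2016-09-19T02:00:00,2000,0",
                           "a1,2016-09-19T00:00:00,0,0",
                           "a1,2016-09-19T01:00:00,1000,0",
                           "b2,2016-09-19T00:00:00,5,5",
                           "b2,2016-09-19T01:00:00,6,6"))
  trs <- read_tracks(p)
  expect_named(trs, c("a1", "b2"))
  expect_equal(n_fixes(trs$a1), 3)
  expect_equal(trs$a1$x, c(0, 1000, 2000))   # re-sorted ascending
  p2 <- write_csv_fixture(c("a1,2016-09-19T00:00:00,0,0",
                            "a1,2016-09-19T00:00:00,1,1"))
  expect_error(read_tracks(p2), "duplicate timestamp.*a1")
  p3 <- write_csv_fixture("a1,not-a-time,0,0")
  expect_error(read_tracks(p3), "malformed timestamp")
})

test_that("speed filter removes stationary clusters but keeps flight", {
  t0 <- as.POSIXct("2016-09-19 00:00:00", tz = "UTC")
  two <- trajectory("a", t0 + 3600 * (0:1), c(0, 10000), c(0, 0))
  expect_equal(n_fixes(speed_filter(two, 6)), 2)      # 10 km/h: retained
  # interior fix with both adjacent segments at 2 km/h is removed
  tr <- trajectory("a", t0 + 3600 * (0:2), c(0, 2000, 4000), c(0, 0, 0))
  expect_equal(speed_filter(tr, 6)$x, numeric(0))
  # 6-fix toy: fast - stopover cluster (3 fixes ~1 km apart) - fast
  xs <- c(0, 20000, 21000, 22000, 23000, 43000)
  tr <- trajectory("a", t0 + 3600 * (0:5), xs, rep(0, 6))
  # hand-computed segment speeds (km/h): 20, 1, 1, 1, 20
  # max(adjacent) per fix:               20, 20, 1, 1, 20, 20
  kept <- speed_filter(tr, 6)
  expect_equal(kept$x, c(0, 20000, 23000, 43000))
})

test_that("exclusion zones cut around the north and southwest anchors", {
  t0 <- as.POSIXct("2016-09-19 00:00:00", tz = "UTC")
  km <- 1000
  # northernmost at y=2000 km; the fix 499 km below it must go, the fix
  # clear of all three anchors stays
  tr <- trajectory("a", t0 + 3600 * (0:3),
                   c(0, 10, 20, -5) * km, c(2000, 1501, 800, 0) * km)
  out <- exclusion_zones(tr, preprocess_params())
  expect_equal(out$y, 800 * km)
  # fix >700 km from south+west anchors and >500 from north is retained
  tr <- trajectory("a", t0 + 3600 * (0:2),
                   c(0, 0, 0), c(2000, 1299, 0) * km)
  out <- exclusion_zones(tr, preprocess_params())
  expect_equal(out$y, 1299 * km)
  # 8-fix toy track validated against a brute-force distance table
  set.seed(4)
  xs <- runif(8, 0, 2.5e6); ys <- runif(8, 0, 2.5e6)
  tr <- trajectory("a", t0 + 3600 * (0:7), xs, ys)
  dN <- sqrt((xs - xs[which.max(ys)])^2 + (ys - ys[which.max(ys)])^2)
  dS <- sqrt((xs - xs[which.min(ys)])^2 + (ys - ys[which.min(ys)])^2)
  dW <- sqrt((xs - xs[which.min(xs)])^2 + (ys - ys[which.min(xs)])^2)
  keep <- dN >= 5e5 & dS >= 7e5 & dW >= 7e5
  out <- exclusion_zones(tr, preprocess_params())
  expect_equal(out$x, xs[keep])
  expect_equal(out$y, ys[keep])
})

test_that("length filter uses path length, not displacement", {
  t0 <- as.POSIXct("2016-09-19 00:00:00", tz = "UTC")
  straight <- trajectory("a", t0 + 3600 * (0:1), c(0, 1.6e6), c(0, 0))
  expect_true(length_filter(straight, 1500))
  short <- trajectory("a", t0 + 3600 * (0:1), c(0, 1.4e6), c(0, 0))
  expect_false(length_filter(short, 1500))
  # zigzag: chord 1200 km but flown path ~1550 km
  n <- 31
  xs <- seq(0, 1.2e6, length.out = n)
  ys <- rep(c(0, 1), length.out = n) * 2.45e5
  zig <- trajectory("a", t0 + 3600 * (0:(n - 1)), xs, ys)
  expect_gt(track_length_km(zig), 1500)
  expect_lt(sqrt(diff(range(xs))^2) / 1000, 1500)
  expect_true(length_filter(zig, 1500))
})

test_that("hourly interpolation is linear, idempotent and grid-aligned", {
  t0 <- as.POSIXct("2016-09-19 00:00:00", tz = "UTC")
  tr <- trajectory("a", t0 + 3600 * c(0, 2), c(0, 2000), c(0, 0))
  out <- interpolate_hourly(tr)
  expect_equal(n_fixes(out), 3)
  expect_equal(out$x[2], 1000)
  # idempotence
  again <- interpolate_hourly(out)
  expect_equal(again$x, out$x)
  expect_equal(as.numeric(again$t), as.numeric(out$t))
  # 30-min input: every second output fix coincides with an original
  tr30 <- trajectory("a", t0 + 1800 * (0:4), c(0, 400, 1000, 1800, 2800),
                     rep(0, 5))
  out <- interpolate_hourly(tr30)
  expect_equal(out$x, c(0, 1000, 2800))
})

test_that("step decomposition follows the mathematical angle convention", {
  t0 <- as.POSIXct("2016-09-19 00:00:00", tz = "UTC")
  tr <- trajectory("a", t0 + 3600 * (0:2),
                   c(0, 3000, 6000), c(0, 4000, 8000))
  s <- to_steps(tr)
  expect_equal(s$step_lengths, c(5000, 5000))
  expect_equal(s$turning_angles, 0)
  # east then north: turn of +pi/2
  tr <- trajectory("a", t0 + 3600 * (0:2), c(0, 1000, 1000), c(0, 0, 1000))
  expect_equal(to_steps(tr)$turning_angles, pi / 2)
  # reversal wraps to +pi, not -pi
  tr <- trajectory("a", t0 + 3600 * (0:2), c(0, 1000, 0), c(0, 0, 0))
  expect_equal(to_steps(tr)$turning_angles, pi)
})

test_that("preprocessing pipeline keeps migratory flights intact", {
  t0 <- as.POSIXct("2016-09-19 00:00:00", tz = "UTC")
  # 3000-km southward flight at 50 km/h with stationary clusters at the
  # breeding (north) and wintering (south) ends
  mig_n <- 60
  ys <- seq(3.2e6, 3.2e6 - 50000 * mig_n, by = -50000)
  breed <- rep(3.2e6, 5) + seq(0, 4000, by = 1000)
  winter <- rep(ys[length(ys)], 5) - seq(0, 4000, by = 1000)
  yy <- c(rev(breed), ys[-1], winter)
  tr <- trajectory("g1", t0 + 3600 * seq_along(yy) , rep(0, length(yy)), yy)
  out <- preprocess_tracks(list(tr))
  expect_length(out, 1)
  cleaned <- out$g1
  # hourly, strictly increasing, inside the original span
  expect_equal(unique(diff(as.numeric(cleaned$t))), 3600)
  expect_gt(track_length_km(cleaned), 1500)
  # no interpolated step exceeds the longest original segment
  s <- to_steps(cleaned)
  expect_lte(max(s$step_lengths),
             max(to_steps(tr)$step_lengths) + 1e-9)
})
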