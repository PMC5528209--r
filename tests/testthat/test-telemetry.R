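test_that("load_tracks reads, partitions, sorts, and deduplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,time,lon,lat",
               "b1,2020-01-01T02:00:00,18.50,-34.10",
               "b2,2020-01-01T00:00:00,18.70,-34.00",
               "b1,2020-01-01T00:00:00,18.40,-34.00",
               "b2,2020-01-01T02:00:00,18.80,-34.05",
               "b1,2020-01-01T04:00:00,18.60,-34.20",
               "b1,2020-01-01T04:00:00,18.99,-34.99"), f)
  expect_warning(load_tracks(f), "duplicate")
  trs <- suppressWarnings(load_tracks(f))
  expect_named(trs, c("b1", "b2"))
  expect_equal(nrow(trs$b1$fixes), 3)        # 4 rows - 1 duplicate
  expect_equal(nrow(trs$b2$fixes), 2)
  expect_true(all(diff(as.numeric(trs$b1$fixes$time)) > 0))
  expect_equal(trs$b1$fixes$lon[1], 18.40)   # time-sorted
  expect_equal(trs$b1$fixes$lon[3], 18.60)   # duplicate kept first
})

test_that("load_tracks flags schema errors and skips singleton ids", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,when,lon,lat", "b1,2020-01-01,1,2"), f)
  expect_error(load_tracks(f), "missing column")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,time,lon,lat",
               "solo,2020-01-01T00:00:00,18.4,-34.0",
               "b1,2020-01-01T00:00:00,18.4,-34.0",
               "b1,2020-01-01T02:00:00,18.5,-34.1"), f2)
  expect_warning(load_tracks(f2), "fewer than 2")
  trs <- suppressWarnings(load_tracks(f2))
  expect_named(trs, "b1")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,time,lon,lat", "b1,notatime,18.4,-34.0",
               "b1,2020-01-01T02:00:00,18.5,-34.1"), f3)
  expect_error(load_tracks(f3), "unparseable")
})

test_that("gap splitting is strict at the threshold and suffixes pieces", {
  fx <- data.frame(time = t0() + c(0, 7200, 14400) , lon = c(18, 18.1, 18.2),
                   lat = c(-34, -34, -34))
  expect_length(split_on_gaps(track(fx, id = "a")), 1)

  # one 8-day gap mid-track -> two pieces
  fx2 <- data.frame(time = t0() + c(0, 7200, 7200 + 8 * 86400,
                                    2 * 7200 + 8 * 86400),
                    lon = c(18, 18.1, 18.2, 18.3), lat = rep(-34, 4))
  ps <- split_on_gaps(track(fx2, id = "a"))
  expect_length(ps, 2)
  expect_equal(vapply(ps, function(p) p$split_suffix, ""), c("a", "b"))

  # a gap of exactly 7 days does not split
  fx3 <- data.frame(time = t0() + c(0, 7200, 7200 + 7 * 86400),
                    lon = c(18, 18.1, 18.2), lat = rep(-34, 3))
  expect_length(split_on_gaps(track(fx3, id = "a")), 1)
})

test_that("splitting is idempotent and pieces concatenate to the original", {
  set.seed(4)
  n <- 40
  gaps <- rep(7200, n - 1)
  gaps[c(10, 25)] <- 10 * 86400
  fx <- data.frame(time = t0() + cumsum(c(0, gaps)),
                   lon = cumsum(c(18, rnorm(n - 1, 0, 0.01))),
                   lat = cumsum(c(-34, rnorm(n - 1, 0, 0.01))))
  tr <- track(fx, id = "x")
  ps <- split_on_gaps(tr)
  expect_length(ps, 3)
  again <- unlist(lapply(ps, split_on_gaps), recursive = FALSE)
  expect_length(again, 3)
  expect_equal(lapply(again, function(p) p$fixes$time),
               lapply(ps, function(p) p$fixes$time))
  recon <- do.call(rbind, lapply(ps, function(p) p$fixes))
  expect_equal(recon$lon, fx$lon)
  expect_equal(recon$time, fx$time)
})

test_that("planar projection is centred, metric, and invertible", {
  fx <- data.frame(time = t0() + c(0, 3600), lon = c(20, 20),
                   lat = c(-30, -29.99))
  tr <- project_planar(track(fx, id = "p"))
  # centroid maps near the origin (fixes are symmetric about it)
  expect_lt(abs(mean(tr$fixes$x)), 1e-6)
  expect_lt(abs(mean(tr$fixes$y)), 1e-6)
  # 0.01 deg of latitude is about 1,111.95 m on the sphere
  d <- sqrt(diff(tr$fixes$x)^2 + diff(tr$fixes$y)^2)
  expect_equal(d, 2 * pi * 6371008.8 * 0.01 / 360, tolerance = 1e-4)

  # round trip through the recorded centre
  set.seed(9)
  lon <- 20 + cumsum(rnorm(30, 0, 0.3)); lat <- -30 + cumsum(rnorm(30, 0, 0.2))
  tr2 <- project_planar(track(data.frame(time = t0() + (0:29) * 3600,
                                         lon = lon, lat = lat), id = "q"))
  cc <- foragescales:::crs_center(tr2)
  back <- foragescales:::aeqd_inverse(tr2$fixes$x, tr2$fixes$y,
                                      cc["lon0"], cc["lat0"])
  expect_lt(max(abs(back[, "lon"] - lon)), 1e-9)
  expect_lt(max(abs(back[, "lat"] - lat)), 1e-9)

  expect_error(track(data.frame(time = t0() + c(0, 3600),
                                lon = c(200, 20), lat = c(0, 0)), id = "bad"),
               "outside")
})

test_that("total distance is invariant under rigid rotation", {
  tr <- mk_random_track(n = 50, seed = 2)
  th <- 0.7
  rot <- mk_planar_track(cos(th) * tr$fixes$x - sin(th) * tr$fixes$y,
                         sin(th) * tr$fixes$x + cos(th) * tr$fixes$y)
  d1 <- summarize_track(tr)$total_distance_km
  d2 <- summarize_track(rot)$total_distance_km
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("summary arithmetic reproduces the deployment-table km/day", {
  dep <- deployment_summary()
  rows <- dep[dep$ptt %in% c("7712202", "77092", "77135"), ]
  expect_equal(round(rows$dist_km / rows$days, 2), rows$km_per_day)
})

test_that("a spatially stationary track has zero distance", {
  tr <- mk_planar_track(rep(0, 25), rep(0, 25), dt = 3600)
  s <- summarize_track(tr)
  expect_equal(s$total_distance_km, 0)
  expect_equal(s$km_per_day, 0)
  expect_equal(s$n_relocations, 25)
})
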