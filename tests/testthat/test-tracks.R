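test_that("filter_equinox drops exactly the calendar-enumerated dates", {
  # one fix per day over a full (non-leap) year
  dates <- seq(as.Date("2014-07-01"), as.Date("2015-06-30"), by = "day")
  fixes <- make_fixes(rep(1, length(dates)), rep(55, length(dates)), dates)
  kept <- filter_equinox(fixes)
  expect_equal(nrow(kept), 365 - 39 - 42)

  bad <- unique(c(oracle_window_dates(2014, equinox_windows()),
                  oracle_window_dates(2015, equinox_windows())))
  expect_setequal(as.character(kept$date),
                  as.character(setdiff2 <- dates[!dates %in% bad]))

  # boundary behaviour around the autumn window
  f2 <- make_fixes(c(1, 1), c(55, 55),
                   as.Date(c("2014-10-01", "2014-10-20")))
  out <- filter_equinox(f2)
  expect_equal(as.character(out$date), "2014-10-20")

  expect_identical(filter_equinox(fixes, list()), fixes)
  expect_equal(nrow(filter_equinox(fixes[0, ])), 0L)
})

test_that("filter_equinox supports windows wrapping the year end", {
  dates <- as.Date(c("2014-12-15", "2015-01-10", "2015-06-01"))
  fixes <- make_fixes(rep(0, 3), rep(55, 3), dates)
  w <- list(list(start = c(12L, 1L), end = c(1L, 31L)))
  expect_equal(as.character(filter_equinox(fixes, w)$date), "2015-06-01")
})

test_that("filter_speed drops outliers, is a contraction and idempotent", {
  # two fixes 1 day apart, far beyond 500 km
  f <- make_fixes(c(0, 20), c(55, 55))
  expect_equal(nrow(filter_speed(f, 500)), 1L)

  stationary <- make_fixes(rep(3, 6), rep(55, 6))
  expect_equal(nrow(filter_speed(stationary, 500)), 6L)

  # mid-sequence outlier: forward-scan oracle retains 1,2,4,5
  f5 <- make_fixes(c(0, 0.5, 15, 1.0, 1.5), rep(55, 5))
  kept <- filter_speed(f5, 500)
  expect_equal(kept$lon, c(0, 0.5, 1.0, 1.5))

  # contraction + idempotence on random tracks
  set.seed(42)
  rnd <- make_fixes(cumsum(rnorm(30, 0, 3)), 55 + cumsum(rnorm(30, 0, 1.5)))
  once <- filter_speed(rnd, 300)
  expect_true(all(paste(once$date) %in% paste(rnd$date)))
  expect_identical(filter_speed(once, 300), once)

  single <- make_fixes(1, 55)
  expect_identical(filter_speed(single, 500), single)
})

test_that("filter_speed treats individuals independently", {
  a <- make_fixes(c(0, 0.5), c(55, 55), id = "a")
  b <- make_fixes(c(50, 50.5), c(10, 10), id = "b")
  both <- rbind(a, b)
  out <- filter_speed(both, 500)
  expect_equal(nrow(out), 4L)  # the a->b jump is not a movement
})

test_that("moult_residency gates on window months inside the polygon", {
  poly <- north_sea_polygon()
  w <- moult_window("puffin", "body", 7:9)
  dates <- seq(as.Date("2014-07-05"), by = "day", length.out = 10)
  inside <- make_fixes(rep(2, 10), rep(56, 10), dates, id = "in")
  expect_true(moult_residency(inside, w, poly)[["in"]])

  lons <- rep(2, 10); lons[4] <- -8   # one August fix outside
  mixed <- make_fixes(lons, rep(56, 10),
                      seq(as.Date("2014-08-01"), by = "day", length.out = 10),
                      id = "out")
  expect_false(moult_residency(mixed, w, poly)[["out"]])

  # no fixes in window months -> indeterminate, distinct from TRUE/FALSE
  offseason <- make_fixes(rep(2, 3), rep(56, 3),
                          as.Date(c("2014-11-01", "2014-11-02", "2014-11-03")),
                          id = "na")
  expect_true(is.na(moult_residency(offseason, w, poly)[["na"]]))

  # 10 tracks, 8 fully resident -> 8 eligible
  tracks <- do.call(rbind, lapply(1:10, function(i) {
    lon <- rep(2, 6)
    if (i > 8) lon[3] <- 12  # outside the box
    make_fixes(lon, rep(56, 6),
               seq(as.Date("2014-07-01"), by = "day", length.out = 6),
               id = sprintf("t%02d", i))
  }))
  res <- moult_residency(tracks, w, poly)
  expect_equal(sum(res, na.rm = TRUE), 8)
})

test_that("nrd_bandwidth matches the 1.06 normal-reference rule", {
  set.seed(11)
  x <- rnorm(100)
  expect_equal(nrd_bandwidth(x), stats::bw.nrd(x))
  expect_equal(nrd_bandwidth(x),
               1.06 * min(sd(x), IQR(x) / 1.34) * 100^(-0.2))
  # scale equivariance
  expect_equal(nrd_bandwidth(3 * x), 3 * nrd_bandwidth(x))
  expect_error(nrd_bandwidth(rep(2, 10)), "degenerate spread")
  expect_error(nrd_bandwidth(1), "at least 2")
})

test_that("kde_surface matches the brute-force Gaussian-sum oracle", {
  set.seed(5)
  fixes <- make_fixes(runif(50, 1, 3), runif(50, 54, 56))
  grid <- grid_spec(0, 4, 53, 57, resolution = 0.2)  # 20 x 20
  s <- kde_surface(fixes, bandwidth = 0.4, grid = grid)
  expect_equal(s$values, oracle_kde(fixes, 0.4, grid), tolerance = 1e-6)
  expect_true(all(s$values >= 0))
})

test_that("kde_surface integrates to ~1 and peaks at the fix", {
  one <- make_fixes(2, 55)
  grid <- grid_spec(-2, 6, 51, 59, resolution = 0.1)
  s <- kde_surface(one, bandwidth = 0.3, grid = grid)
  expect_equal(sum(s$values) * 0.1^2, 1, tolerance = 1e-3)
  peak <- which(s$values == max(s$values), arr.ind = TRUE)
  expect_equal(grid_lons(s)[peak[2]], 2.05, tolerance = 0.1)
  expect_equal(grid_lats(s)[peak[1]], 55.05, tolerance = 0.1)

  # two well-separated fixes, small bandwidth: equal-height modes
  two <- make_fixes(c(0.5, 5.5), c(53, 57))
  s2 <- kde_surface(two, bandwidth = 0.2, grid = grid)
  v <- s2$values
  expect_equal(sort(v[v > 0.9 * max(v)], decreasing = TRUE)[1:2],
               rep(max(v), 2), tolerance = 1e-6)
  expect_error(kde_surface(one[0, ], 0.4, grid), "empty population")
})

test_that("haversine distance is sane at known scales", {
  # one degree of latitude ~ 111.2 km on a 6371 km sphere
  expect_equal(haversine_km(0, 55, 0, 56), 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(haversine_km(2, 56, 2, 56), 0)
})
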