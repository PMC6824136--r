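test_that("lipid_correct_d13C follows the normalisation model", {
  # closed-form limit at the protein baseline: correction -> D * I
  floor_cn <- 0.775 / 0.246
  eps <- 1e-9
  expect_equal(lipid_correct_d13C(0, floor_cn + eps), 7.018 * 0.048,
               tolerance = 1e-4)
  expect_equal(round(7.018 * 0.048, 3), 0.337)

  # spreadsheet-style oracle for d13C = -18, C:N = 4
  cn <- 4
  L <- 93 / (1 + 1 / (0.246 * cn - 0.775))
  expected <- -18 + 7.018 * (0.048 + 3.90 / (1 + 287 / L))
  expect_equal(lipid_correct_d13C(-18, 4), expected)

  # never decreases, monotone in C:N
  cns <- seq(3.2, 8, by = 0.1)
  corr <- lipid_correct_d13C(rep(-18, length(cns)), cns) + 18
  expect_true(all(corr >= 0))
  expect_true(all(diff(corr) > 0))
  expect_error(lipid_correct_d13C(-18, 3.0), "protein baseline")
})

test_that("fit_variogram recovers known spherical parameters", {
  # simulate from a known spherical model via Cholesky; single realisations
  # of a variogram are noisy, so recovery is judged on the mean of a few
  # seeded replicates
  true <- variogram_model("spherical", nugget = 0.1, sill = 1.1, range = 3)
  n <- 200
  fits <- t(sapply(1:5, function(s) {
    set.seed(100 + s)
    lon <- runif(n, 0, 12); lat <- runif(n, 50, 62)
    D <- as.matrix(dist(cbind(lon, lat)))
    Cov <- true$sill - vgm_gamma(true, D)
    diag(Cov) <- true$sill
    z <- drop(t(chol(Cov + diag(1e-8, n))) %*% rnorm(n))
    samples <- data.frame(lon = lon, lat = lat, d15N = 10 + z, d13C = -17)
    fit <- fit_variogram(samples, "d15N")
    expect_false(isTRUE(attr(fit, "no_structure")))
    c(sill = fit$sill, range = fit$range)
  }))
  m <- colMeans(fits)
  expect_lt(abs(m["sill"] - true$sill), 0.3 * true$sill)
  expect_lt(abs(m["range"] - true$range), 0.3 * true$range)

  expect_error(fit_variogram(data.frame(lon = 1:5, lat = 1:5, d15N = rnorm(5),
                                        d13C = -17), "d15N"), "at least 10")
})

test_that("fit_variogram flags degenerate structure", {
  set.seed(3)
  # pure noise: fitted range collapses to the smallest lags
  samples <- data.frame(lon = runif(40, 0, 10), lat = runif(40, 50, 60),
                        d15N = rnorm(40), d13C = -17)
  fit <- fit_variogram(samples, "d15N")
  expect_true(isTRUE(attr(fit, "no_structure")))

  # identical values: pure nugget, flagged
  const <- data.frame(lon = runif(12), lat = runif(12), d15N = 5, d13C = -17)
  pf <- fit_variogram(const, "d15N")
  expect_true(isTRUE(attr(pf, "pure_nugget")))

  # co-located duplicates with differing values force a positive nugget
  dup <- data.frame(lon = rep(seq(0, 5, length.out = 10), 2),
                    lat = rep(seq(50, 55, length.out = 10), 2),
                    d15N = c(rnorm(10, 10), rnorm(10, 10)), d13C = -17)
  df <- fit_variogram(dup, "d15N")
  expect_gt(df$nugget, 0)
})

test_that("ordinary_krige matches the hand-assembled linear system", {
  set.seed(21)
  samples <- data.frame(lon = c(1, 3, 2, 0.5, 3.5),
                        lat = c(51, 52, 53, 52.5, 51.5),
                        d15N = c(9, 10, 11, 10.5, 9.5), d13C = -17)
  vgm <- variogram_model("spherical", nugget = 0.05, sill = 1, range = 2)
  grid <- grid_spec(0, 4, 50.5, 53.5, resolution = 0.3)
  k <- ordinary_krige(samples, "d15N", grid, vgm)
  orc <- oracle_krige(samples, "d15N", grid, vgm)
  expect_equal(k$prediction$values, orc$pred, tolerance = 1e-8)
  expect_equal(orc$weight_sums,
               matrix(1, nrow(orc$weight_sums), ncol(orc$weight_sums)),
               tolerance = 1e-8)
})

test_that("ordinary kriging is exact at samples when nugget is zero", {
  # sample coordinates placed exactly on cell centres of the 0.1-degree grid
  samples <- data.frame(lon = c(1.05, 2.25, 3.15, 0.75),
                        lat = c(51.25, 52.15, 51.75, 52.45),
                        d15N = c(9, 11, 10, 12), d13C = -17)
  vgm <- variogram_model("spherical", nugget = 0, sill = 1, range = 2)
  grid <- grid_spec(0.5, 3.5, 51, 53, resolution = 0.1)
  k <- ordinary_krige(samples, "d15N", grid, vgm)
  at <- grid_value_at(k$prediction, samples$lon, samples$lat)
  expect_equal(at, samples$d15N, tolerance = 1e-6)
  expect_true(all(k$sd$values >= 0))
})

test_that("degenerate kriging inputs are handled per policy", {
  one <- data.frame(lon = 1, lat = 51, d15N = 9.5, d13C = -17)
  vgm <- variogram_model("spherical", nugget = 0, sill = 1, range = 2)
  grid <- grid_spec(0, 2, 50, 52, resolution = 0.5)
  k <- ordinary_krige(one, "d15N", grid, vgm)
  expect_true(all(k$prediction$values == 9.5))

  dup <- data.frame(lon = c(1, 1, 2), lat = c(51, 51, 52),
                    d15N = c(9, 10, 11), d13C = -17)
  expect_error(ordinary_krige(dup, "d15N", grid, vgm), "singular")
  kj <- ordinary_krige(dup, "d15N", grid, vgm, on_singular = "jitter")
  expect_true(all(is.finite(kj$prediction$values)))
})

test_that("extract_values equals the cell-by-cell loop oracle", {
  iso <- toy_isoscape()
  set.seed(9)
  mask <- iso$d13C
  mask$values <- matrix(runif(length(mask$values)) > 0.6,
                        nrow(mask$values), ncol(mask$values))
  got <- extract_values(iso, mask)
  # loop oracle
  exp_c <- c(); exp_n <- c()
  for (i in seq_len(nrow(mask$values))) for (j in seq_len(ncol(mask$values))) {
    if (mask$values[i, j]) {
      exp_c <- c(exp_c, iso$d13C$values[i, j])
      exp_n <- c(exp_n, iso$d15N$values[i, j])
    }
  }
  expect_setequal(got$d13C, exp_c)
  expect_setequal(got$d15N, exp_n)
  expect_equal(length(got$d13C), length(got$d15N))

  one_cell <- mask; one_cell$values[] <- FALSE; one_cell$values[3, 4] <- TRUE
  single <- extract_values(iso, one_cell)
  expect_equal(single$d13C, iso$d13C$values[3, 4])

  empty <- mask; empty$values[] <- FALSE
  expect_error(extract_values(iso, empty), "empty extraction region")

  # nodata cells are skipped
  iso2 <- iso; iso2$d13C$values[3, 4] <- NA
  s2 <- extract_values(iso2, one_cell <- all_true_mask(iso$d13C))
  expect_equal(length(s2$d13C), length(iso$d13C$values) - 1)
})

test_that("isoscape container checks alignment and sanity bounds", {
  iso <- toy_isoscape()
  expect_s3_class(iso, "isoscape")
  g_off <- grid_surface(iso$d15N$values, 1, 54, 0.2)
  expect_error(isoscape(iso$d13C, g_off), "not aligned")
  hot <- iso$d15N; hot$values[1, 1] <- 50
  expect_warning(isoscape(iso$d13C, hot), "sanity bounds")
})
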