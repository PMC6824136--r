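make_offset <- function(dc = 0, sc = 0, dn = 0, sn = 0) {
  structure(list(delta13C_fj = dc, sd13C = sc, delta15N_fj = dn, sd15N = sn,
                 n_draws = 1L), class = "calibration_offset")
}

test_that("kde_mask thresholds against the floor", {
  g <- grid_surface(matrix(0.02, 4, 4), 0, 50)
  expect_true(all(kde_mask(g, 0.01)$values))
  g$values[2, 2] <- 0.005
  m <- kde_mask(g, 0.01)
  expect_equal(m$values, g$values > 0.01)  # loop-free oracle: direct comparison
  low <- grid_surface(matrix(0.001, 4, 4), 0, 50)
  expect_error(kde_mask(low, 0.01), "empty mask")
})

test_that("derive_offset behaves as a Monte-Carlo difference of normals", {
  # point masses: offset exact, sd zero
  iso_vals <- list(d13C = c(-17, -17, -17), d15N = c(10, 10, 10))
  fe <- data.frame(d13C = c(-13, -13), d15N = c(14, 14))
  off <- derive_offset(iso_vals, fe, n_draws = 500, seed = 1)
  expect_equal(off$delta15N_fj, 4)
  expect_equal(off$sd15N, 0)
  expect_equal(off$delta13C_fj, 4)

  # identical distributions: offset near 0 within 3 * sd / sqrt(n)
  set.seed(2)
  v <- rnorm(200, 10, 1)
  iso_vals <- list(d13C = v - 27, d15N = v)
  fe <- data.frame(d13C = v - 27, d15N = v)
  off <- derive_offset(iso_vals, fe, n_draws = 4000, seed = 3)
  tol <- 3 * sqrt(2) / sqrt(4000)
  expect_lt(abs(off$delta15N_fj), tol + 1e-9)

  # sd of the difference approaches sqrt(sd_f^2 + sd_j^2) = sqrt(2)
  expect_equal(off$sd15N, sqrt(2), tolerance = 0.1)

  # same seed -> bit-identical
  a <- derive_offset(iso_vals, fe, n_draws = 100, seed = 7)
  b <- derive_offset(iso_vals, fe, n_draws = 100, seed = 7)
  expect_identical(a, b)
})

test_that("likelihood_surface equals a scalar Gaussian density product", {
  iso <- toy_isoscape(n = 3, resolution = 1)
  cal <- make_offset(dc = 0.5, sc = 0.3, dn = 4, sn = 0.8)
  cond <- assignment_conditions(cal, measurement_sd = 0.2,
                                between_var_d13C = 0.4, between_var_d15N = 0.9)
  feather <- list(d13C = -16.2, d15N = 13.0)
  L <- likelihood_surface(feather, iso, cond)
  s2c <- 0.2^2 + 0.4 + 0.3^2
  s2n <- 0.2^2 + 0.9 + 0.8^2
  for (i in 1:3) for (j in 1:3) {
    expect_equal(L$values[i, j],
                 dnorm(-16.2, iso$d13C$values[i, j] + 0.5, sqrt(s2c)) *
                   dnorm(13.0, iso$d15N$values[i, j] + 4, sqrt(s2n)))
  }
})

test_that("likelihood_surface peaks at the matching cell and flattens with variance", {
  iso <- toy_isoscape(n = 10, resolution = 0.5, ng = c(-1, 0.5))
  cal <- make_offset(dn = 3)
  cond <- assignment_conditions(cal, measurement_sd = 0.2)
  target <- c(4, 7)
  feather <- list(d13C = iso$d13C$values[target[1], target[2]],
                  d15N = iso$d15N$values[target[1], target[2]] + 3)
  L <- likelihood_surface(feather, iso, cond)
  expect_equal(which(L$values == max(L$values), arr.ind = TRUE)[1, ],
               c(row = target[1], col = target[2]))

  wide <- assignment_conditions(cal, measurement_sd = 0.2,
                                between_var_d13C = 2, between_var_d15N = 2)
  Lw <- likelihood_surface(feather, iso, wide)
  expect_lt(max(Lw$values) / min(Lw$values), max(L$values) / min(L$values))

  far <- list(d13C = 100, d15N = 150)
  expect_warning(likelihood_surface(far, iso, cond), "outside isoscape support")
})

test_that("posterior_surface multiplies and renormalises", {
  set.seed(4)
  prior <- normalize_surface(grid_surface(matrix(runif(36), 6), 0, 50))
  lik <- grid_surface(matrix(runif(36), 6), 0, 50)
  post <- posterior_surface(prior, lik)
  oracle <- prior$values * lik$values
  oracle <- oracle / sum(oracle)
  expect_equal(post$values, oracle)
  expect_equal(sum(post$values), 1, tolerance = 1e-12)

  # uniform prior -> normalized likelihood
  up <- normalize_surface(grid_surface(matrix(1, 6, 6), 0, 50))
  expect_equal(posterior_surface(up, lik)$values, lik$values / sum(lik$values))

  # prior nonzero in one cell only -> posterior mass 1 there
  point <- grid_surface(matrix(0, 6, 6), 0, 50); point$values[2, 3] <- 1
  pp <- posterior_surface(point, lik)
  expect_equal(pp$values[2, 3], 1)

  zero <- grid_surface(matrix(0, 6, 6), 0, 50)
  expect_error(posterior_surface(zero, lik), "disjoint support")
})

test_that("likely_region equals the sort-and-accumulate oracle", {
  set.seed(6)
  for (rep in 1:5) {
    p <- runif(40)^3
    p <- p / sum(p)
    post <- grid_surface(matrix(p, 5, 8), 0, 50)
    got <- likely_region(post, 0.30)
    expect_equal(as.vector(got$values), oracle_likely_region(p, 0.30))
    mass <- sum(p[as.vector(got$values)])
    expect_gte(mass, 0.30 - 1e-12)
    expect_lte(mass, 0.30 + max(p))
  }

  # uniform posterior over N cells -> ceil(0.3 N) cells
  u <- grid_surface(matrix(1 / 40, 5, 8), 0, 50)
  expect_equal(sum(likely_region(u, 0.30)$values), ceiling(0.30 * 40))

  # all mass in one cell
  point <- grid_surface(matrix(0, 5, 8), 0, 50); point$values[3, 3] <- 1
  r <- likely_region(point, 0.30)
  expect_equal(sum(r$values), 1)
  expect_true(r$values[3, 3])
})

test_that("shrinking total variance concentrates the likely region", {
  iso <- toy_isoscape(n = 15, resolution = 0.4)
  prior <- normalize_surface(grid_surface(matrix(1, 15, 15), 0, 54, 0.4))
  feather <- list(d13C = iso$d13C$values[8, 8], d15N = iso$d15N$values[8, 8])
  sizes <- sapply(c(2, 1, 0.5, 0.2), function(ms) {
    cond <- assignment_conditions(make_offset(), measurement_sd = ms)
    post <- posterior_surface(prior, likelihood_surface(feather, iso, cond))
    sum(likely_region(post, 0.30)$values)
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("population_surface is the normalised mean of posteriors", {
  set.seed(8)
  mk <- function() {
    normalize_surface(grid_surface(matrix(runif(24), 4), 0, 50))
  }
  a <- mk(); b <- mk(); cpost <- mk()
  pop <- population_surface(list(a, b, cpost))
  oracle <- (a$values + b$values + cpost$values) / 3
  oracle <- oracle / sum(oracle)
  expect_equal(pop$values, oracle)
  expect_equal(population_surface(list(a))$values, a$values)
  expect_equal(population_surface(list(a, a))$values, a$values)
  expect_error(population_surface(list()), "empty")
})

test_that("region_overlap counts cells against the chosen reference", {
  base <- grid_surface(matrix(FALSE, 10, 10), 0, 50)
  a <- base; a$values[1:10, 1:10] <- TRUE            # 100 cells
  b <- base; b$values[1:8, 1:8] <- TRUE              # 64 cells, all shared
  expect_equal(region_overlap(a, b, reference = "b"), 100)
  expect_equal(region_overlap(a, b, reference = "a"), 64)
  expect_equal(region_overlap(b, a, reference = "b"), 64)
  expect_equal(region_overlap(a, a), 100)
  disj <- base; disj$values[1, 1] <- TRUE
  disj2 <- base; disj2$values[10, 10] <- TRUE
  expect_equal(region_overlap(disj, disj2, reference = "a"), 0)
  expect_error(region_overlap(base, a, reference = "a"), "empty reference")
})
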