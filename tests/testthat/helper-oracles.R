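# Independent brute-force oracles. These deliberately take the slow, obvious
# route (explicit double loops, pair counting, full enumeration) so they stay
# independent of the package's vectorised implementations.

# direct Gaussian-sum KDE: loop over cells, loop over fixes
oracle_kde <- function(fixes, bandwidth, grid) {
  lons <- grid_lons(grid); lats <- grid_lats(grid)
  out <- matrix(0, length(lats), length(lons))
  for (i in seq_along(lats)) {
    for (j in seq_along(lons)) {
      s <- 0
      for (k in seq_len(nrow(fixes))) {
        s <- s + exp(-((lons[j] - fixes$lon[k])^2 +
                         (lats[i] - fixes$lat[k])^2) / (2 * bandwidth^2))
      }
      out[i, j] <- s / (nrow(fixes) * 2 * pi * bandwidth^2)
    }
  }
  out
}

# spherical/exponential semivariance, written out again on purpose
oracle_gamma <- function(vgm, h) {
  if (h <= 0) return(0)
  ps <- vgm$sill - vgm$nugget
  g <- if (vgm$model == "spherical") {
    if (h >= vgm$range) ps else ps * (1.5 * h / vgm$range - 0.5 * (h / vgm$range)^3)
  } else {
    ps * (1 - exp(-h / vgm$range))
  }
  vgm$nugget + g
}

# per-cell ordinary kriging by assembling and solving each bordered system
oracle_krige <- function(samples, isotope, grid, vgm) {
  z <- samples[[isotope]]
  n <- length(z)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    h <- sqrt((samples$lon[i] - samples$lon[j])^2 +
                (samples$lat[i] - samples$lat[j])^2)
    A[i, j] <- oracle_gamma(vgm, h)
  }
  A[n + 1, seq_len(n)] <- 1
  A[seq_len(n), n + 1] <- 1
  lons <- grid_lons(grid); lats <- grid_lats(grid)
  pred <- matrix(0, length(lats), length(lons))
  wsum <- matrix(0, length(lats), length(lons))
  for (i in seq_along(lats)) for (j in seq_along(lons)) {
    b <- numeric(n + 1)
    for (k in seq_len(n)) {
      b[k] <- oracle_gamma(vgm, sqrt((samples$lon[k] - lons[j])^2 +
                                       (samples$lat[k] - lats[i])^2))
    }
    b[n + 1] <- 1
    w <- solve(A, b)
    pred[i, j] <- sum(w[seq_len(n)] * z)
    wsum[i, j] <- sum(w[seq_len(n)])
  }
  list(pred = pred, weight_sums = wsum)
}

# exact Mann-Whitney by pair counting over all labelings of the pooled values
oracle_mw_exact <- function(x, y) {
  count_u <- function(a, b) {
    u <- 0
    for (xi in a) for (yj in b) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  U_obs <- count_u(x, y)
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  mu <- nx * (n - nx) / 2
  sets <- utils::combn(n, nx)
  us <- apply(sets, 2, function(idx) count_u(pooled[idx], pooled[-idx]))
  list(U = U_obs, p = mean(abs(us - mu) >= abs(U_obs - mu) - 1e-9))
}

# smallest top-probability set by sort-and-accumulate
oracle_likely_region <- function(pvec, q) {
  ord <- order(pvec, seq_along(pvec) * -1, decreasing = TRUE)
  sel <- logical(length(pvec))
  acc <- 0
  for (i in ord) {
    if (acc >= q - 1e-12) break
    acc <- acc + pvec[i]
    sel[i] <- pvec[i] > 0
  }
  sel
}

# enumerate the calendar dates of one year falling in month/day windows
oracle_window_dates <- function(year, windows) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  hit <- rep(FALSE, length(dates))
  for (w in windows) {
    start <- as.Date(sprintf("%d-%02d-%02d", year, w$start[1], w$start[2]))
    end <- as.Date(sprintf("%d-%02d-%02d", year, w$end[1], w$end[2]))
    if (start <= end) {
      hit <- hit | (dates >= start & dates <= end)
    } else {
      hit <- hit | dates >= start | dates <= end
    }
  }
  dates[hit]
}
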