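#' Dual-isotope reference isoscape
#'
#' An isoscape bundles aligned [grid_surface()] rasters of baseline
#' delta-13C (permil VPDB) and delta-15N (permil air), optionally with
#' per-isotope prediction standard-deviation surfaces (e.g. kriging sd).
#' Values far outside marine food-web ranges (delta-13C outside [-40, 0],
#' delta-15N outside [0, 30]) trigger a warning, not an error.
#'
#' @param d13C,d15N `grid_surface` rasters of isotope means.
#' @param d13C_sd,d15N_sd optional aligned sd rasters.
#' @return an object of class `isoscape`.
#' @export
isoscape <- function(d13C, d15N, d13C_sd = NULL, d15N_sd = NULL) {
  stop_if_misaligned(d13C, d15N)
  if (!is.null(d13C_sd)) stop_if_misaligned(d13C, d13C_sd)
  if (!is.null(d15N_sd)) stop_if_misaligned(d13C, d15N_sd)
  c_rng <- range(d13C$values, na.rm = TRUE)
  n_rng <- range(d15N$values, na.rm = TRUE)
  if (c_rng[1] < -40 || c_rng[2] > 0) {
    warning("d13C values outside sanity bounds [-40, 0] permil")
  }
  if (n_rng[1] < 0 || n_rng[2] > 30) {
    warning("d15N values outside sanity bounds [0, 30] permil")
  }
  structure(list(d13C = d13C, d15N = d15N,
                 d13C_sd = d13C_sd, d15N_sd = d15N_sd),
            class = "isoscape")
}

#' @export
print.isoscape <- function(x, ...) {
  cat("<isoscape>\n  d13C: ")
  print(x$d13C)
  cat("  d15N: ")
  print(x$d15N)
  invisible(x)
}

# C:N mass ratio below which the lipid-normalisation model is undefined
.lipid_cn_floor <- 0.775 / 0.246

#' Lipid-normalise delta-13C from the C:N mass ratio
#'
#' Lipids are depleted in 13C relative to protein, so bulk delta-13C of
#' lipid-rich tissue underestimates the protein value. This applies the
#' mass-balance normalisation of Kiljunen and co-workers: with lipid
#' percentage `L = 93 / (1 + (0.246 * CN - 0.775)^-1)`, the corrected value
#' is `d13C + D * (I + 3.90 / (1 + 287 / L))` with `D = 7.018`,
#' `I = 0.048`. The correction is non-negative and increases with C:N.
#'
#' @param d13C measured delta-13C, permil (vectorised).
#' @param cn_ratio tissue mass C:N ratio; must exceed the protein baseline
#'   `0.775 / 0.246` (about 3.15).
#' @return corrected delta-13C, permil.
#' @export
lipid_correct_d13C <- function(d13C, cn_ratio) {
  if (any(cn_ratio <= .lipid_cn_floor)) {
    stop("C:N below protein baseline; correction inapplicable")
  }
  D <- 7.018
  I <- 0.048
  L <- 93 / (1 + (0.246 * cn_ratio - 0.775)^(-1))
  d13C + D * (I + 3.90 / (1 + 287 / L))
}

#' Read prey tissue samples from CSV
#'
#' Expects columns `lon, lat, d13C, d15N, cn_ratio, taxon` (`cn_ratio` and
#' `taxon` optional).
#'
#' @param path CSV file path.
#' @return a data.frame of tissue samples.
#' @export
read_tissue_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "d13C", "d15N")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("tissue table is missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

# ---- variogram --------------------------------------------------------------

#' Semivariogram models
#'
#' `variogram_model()` describes an isotropic semivariogram with nugget:
#' spherical or exponential. `vgm_gamma()` evaluates the semivariance at lag
#' `h` (degrees); `gamma(0) = 0` exactly, with the nugget appearing as the
#' limit for `h -> 0+`.
#'
#' @param model `"spherical"` or `"exponential"`.
#' @param nugget nugget variance, >= 0.
#' @param sill total sill (nugget + partial sill), > nugget.
#' @param range range parameter in degrees, > 0 (for the exponential model
#'   the practical range is `3 * range`).
#' @return a `variogram_model` list.
#' @export
variogram_model <- function(model = c("spherical", "exponential"),
                            nugget, sill, range) {
  model <- match.arg(model)
  stopifnot(nugget >= 0, sill > nugget, range > 0)
  structure(list(model = model, nugget = nugget, sill = sill, range = range),
            class = "variogram_model")
}

#' @rdname variogram_model
#' @param m a `variogram_model`.
#' @param h lag distances (degrees), vectorised.
#' @export
vgm_gamma <- function(m, h) {
  psill <- m$sill - m$nugget
  g <- switch(m$model,
    spherical = ifelse(h >= m$range, psill,
                       psill * (1.5 * h / m$range - 0.5 * (h / m$range)^3)),
    exponential = psill * (1 - exp(-h / m$range))
  )
  ifelse(h <= 0, 0, m$nugget + g)
}

#' Empirical semivariogram
#'
#' Classical (method-of-moments) semivariogram of one isotope over equal
#' -width lag bins up to a cutoff (default half the maximum pairwise
#' distance).
#'
#' @param samples data.frame with `lon`, `lat` and the isotope column.
#' @param isotope `"d13C"` or `"d15N"`.
#' @param n_bins number of lag bins; default 12.
#' @param cutoff maximum lag (degrees); default half the max distance.
#' @return data.frame with columns `dist` (bin mean lag), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(samples, isotope = c("d13C", "d15N"),
                                n_bins = 12, cutoff = NULL) {
  isotope <- match.arg(isotope)
  z <- samples[[isotope]]
  d <- as.matrix(stats::dist(cbind(samples$lon, samples$lat)))
  sq <- outer(z, z, `-`)^2 / 2
  iu <- upper.tri(d)
  dd <- d[iu]; gg <- sq[iu]
  if (is.null(cutoff)) cutoff <- max(dd) / 2
  keep <- dd <= cutoff & dd > 0
  bins <- cut(dd[keep], breaks = seq(0, cutoff, length.out = n_bins + 1),
              include.lowest = TRUE)
  out <- data.frame(
    dist = tapply(dd[keep], bins, mean),
    gamma = tapply(gg[keep], bins, mean),
    n_pairs = as.integer(table(bins))
  )
  out[!is.na(out$dist), , drop = FALSE]
}

#' Fit a semivariogram model by weighted least squares
#'
#' Fits the chosen model to the empirical semivariogram by weighted least
#' squares with Cressie weights `n_pairs / gamma_model^2`. Degenerate
#' inputs are handled explicitly: with all values identical a pure-nugget
#' model is returned with attribute `pure_nugget = TRUE`; if the fitted
#' range collapses to (or below) the first lag the model is flagged
#' `no_structure = TRUE`.
#'
#' @inheritParams empirical_variogram
#' @param model semivariogram family; default spherical.
#' @return a [variogram_model()] (possibly flagged, see Details).
#' @export
fit_variogram <- function(samples, isotope = c("d13C", "d15N"),
                          model = c("spherical", "exponential"),
                          n_bins = 12, cutoff = NULL) {
  isotope <- match.arg(isotope)
  model <- match.arg(model)
  if (nrow(samples) < 10) stop("need at least 10 samples to fit a variogram")
  if (anyDuplicated(cbind(samples$lon, samples$lat)) == 0 &&
      nrow(unique(cbind(samples$lon, samples$lat))) < 10) {
    stop("need at least 10 distinct sample locations")
  }
  z <- samples[[isotope]]
  if (stats::sd(z) == 0) {
    eps <- 1e-8
    m <- variogram_model(model, nugget = 0, sill = eps, range = 1)
    attr(m, "pure_nugget") <- TRUE
    return(m)
  }
  emp <- empirical_variogram(samples, isotope, n_bins = n_bins, cutoff = cutoff)
  # nugget estimate from co-located duplicates, if any
  dup_nugget <- 0
  key <- paste(samples$lon, samples$lat)
  if (anyDuplicated(key)) {
    sp <- split(z, key)
    sp <- sp[vapply(sp, length, 1L) > 1]
    dup_nugget <- mean(vapply(sp, stats::var, 1))
  }
  obj <- function(par) {
    m <- list(model = model, nugget = par[1], sill = par[1] + par[2],
              range = par[3])
    class(m) <- "variogram_model"
    gm <- vgm_gamma(m, emp$dist)
    sum(emp$n_pairs * (emp$gamma - gm)^2 / pmax(gm, 1e-10)^2)
  }
  start <- c(nugget = max(dup_nugget, min(emp$gamma) / 2),
             psill = max(max(emp$gamma) - min(emp$gamma), 1e-6),
             range = max(emp$dist) / 2)
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 1e-8, min(emp$dist) / 10),
                      upper = c(Inf, Inf, 4 * max(emp$dist)))
  p <- unname(fit$par)
  m <- variogram_model(model, nugget = p[1], sill = p[1] + p[2], range = p[3])
  # no-structure check: approximate F-test of the 3-parameter model against
  # a flat (pure-nugget) variogram on the weighted residual sums of squares
  flat_obj <- function(cst) sum(emp$n_pairs * (emp$gamma - cst)^2 / cst^2)
  best_flat <- stats::optimize(flat_obj, range(emp$gamma) + c(-1e-9, 1e-9))$objective
  df2 <- nrow(emp) - 3
  fstat <- if (df2 > 0 && fit$value > 0) {
    ((best_flat - fit$value) / 2) / (fit$value / df2)
  } else Inf
  if (m$range <= emp$dist[1] ||
      (df2 > 0 && fstat < stats::qf(0.95, 2, df2))) {
    attr(m, "no_structure") <- TRUE
  }
  if (dup_nugget > 0 && m$nugget == 0) m$nugget <- min(dup_nugget, m$sill / 2)
  m
}

# ---- ordinary kriging -------------------------------------------------------

#' Ordinary kriging onto a grid
#'
#' Predicts one isotope over every cell centre of `grid` by ordinary
#' kriging: per cell, weights solve the bordered semivariance system with
#' the unbiasedness constraint (weights sum to 1); the kriging variance is
#' also returned. With zero nugget the interpolator is exact at sample
#' locations. Duplicated coordinates with zero nugget make the system
#' singular; `on_singular` selects jittering coordinates by a tiny amount
#' or failing.
#'
#' @inheritParams empirical_variogram
#' @param grid `grid_surface` template for prediction.
#' @param vgm a [variogram_model()].
#' @param on_singular `"error"` (default) or `"jitter"`.
#' @return list with `prediction` and `sd`, both `grid_surface` objects.
#' @export
ordinary_krige <- function(samples, isotope = c("d13C", "d15N"),
                           grid = grid_spec(), vgm,
                           on_singular = c("error", "jitter")) {
  isotope <- match.arg(isotope)
  on_singular <- match.arg(on_singular)
  z <- samples[[isotope]]
  n <- length(z)
  tmpl <- function(v, s) grid_surface(matrix(v, nrow(grid$values), ncol(grid$values)),
                                      grid$lon_min, grid$lat_min, grid$resolution)
  if (n == 1L) {
    # ordinary-kriging mean degenerates to the single observation
    return(list(prediction = tmpl(z), sd = tmpl(sqrt(vgm$sill))))
  }
  xy <- cbind(samples$lon, samples$lat)
  if (anyDuplicated(xy) && vgm$nugget == 0) {
    if (on_singular == "error") {
      stop("duplicated sample coordinates with zero nugget: kriging system singular")
    }
    set.seed(1L)
    xy <- xy + matrix(stats::rnorm(length(xy), sd = 1e-6), ncol = 2)
  }
  D <- as.matrix(stats::dist(xy))
  A <- rbind(cbind(vgm_gamma(vgm, D), 1), c(rep(1, n), 0))
  lons <- grid_lons(grid); lats <- grid_lats(grid)
  cells <- cbind(rep(lons, each = length(lats)), rep(lats, length(lons)))
  # distances sample x cell
  d0 <- sqrt(outer(xy[, 1], cells[, 1], `-`)^2 + outer(xy[, 2], cells[, 2], `-`)^2)
  B <- rbind(vgm_gamma(vgm, d0), 1)
  W <- tryCatch(solve(A, B), error = function(e) {
    stop("singular kriging system: ", conditionMessage(e))
  })
  lambda <- W[seq_len(n), , drop = FALSE]
  mu <- W[n + 1L, ]
  pred <- as.vector(crossprod(lambda, z))
  kvar <- colSums(lambda * B[seq_len(n), , drop = FALSE]) + mu
  kvar[kvar < 0] <- 0
  # cells are ordered lon-major, lat fastest => matrix by column
  pm <- matrix(pred, nrow = length(lats), ncol = length(lons))
  sm <- matrix(sqrt(kvar), nrow = length(lats), ncol = length(lons))
  list(prediction = grid_surface(pm, grid$lon_min, grid$lat_min, grid$resolution),
       sd = grid_surface(sm, grid$lon_min, grid$lat_min, grid$resolution))
}

#' Krige a dual-isotope prey isoscape
#'
#' Fits (or takes) a variogram per isotope and kriges both fields
#' independently onto a common grid, returning an [isoscape()] with
#' prediction sd surfaces.
#'
#' @param samples tissue data.frame with `lon, lat, d13C, d15N`.
#' @param grid prediction `grid_surface`.
#' @param vgm_d13C,vgm_d15N optional [variogram_model()]s; fitted by
#'   [fit_variogram()] when `NULL`.
#' @param ... passed to [fit_variogram()].
#' @return an `isoscape`.
#' @export
krige_isoscape <- function(samples, grid = grid_spec(),
                           vgm_d13C = NULL, vgm_d15N = NULL, ...) {
  if (is.null(vgm_d13C)) vgm_d13C <- fit_variogram(samples, "d13C", ...)
  if (is.null(vgm_d15N)) vgm_d15N <- fit_variogram(samples, "d15N", ...)
  kc <- ordinary_krige(samples, "d13C", grid, vgm_d13C)
  kn <- ordinary_krige(samples, "d15N", grid, vgm_d15N)
  isoscape(kc$prediction, kn$prediction, kc$sd, kn$sd)
}

#' Extract isotope values under a mask
#'
#' Returns the paired delta-13C / delta-15N values of every unmasked cell
#' (equal weight per cell); cells where either isotope is nodata are
#' skipped. Used to summarise the isoscape inside a utilisation-density
#' mask before deriving calibration offsets.
#'
#' @param iso an [isoscape()].
#' @param mask logical `grid_surface` aligned with `iso`.
#' @return list with numeric vectors `d13C` and `d15N` (equal length).
#' @export
extract_values <- function(iso, mask) {
  stop_if_misaligned(iso$d13C, mask)
  sel <- mask$values & !is.na(iso$d13C$values) & !is.na(iso$d15N$values)
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) stop("empty extraction region")
  list(d13C = iso$d13C$values[sel], d15N = iso$d15N$values[sel])
}
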