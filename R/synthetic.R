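#' Synthetic scenario configuration
#'
#' Collects every knob of the synthetic-data generators in one list. The
#' defaults describe the stated world the generators emulate: a 0.1-degree
#' North Sea grid, smooth isotope gradients with a little smoothed spatial
#' noise, winter tracks as biased random walks from a colony at
#' (-2.57 degE, 56.19 degN) towards a wintering centroid, light-level
#' position error with 186 km radial RMS (186/sqrt(2) km per axis), and
#' feather values built as isoscape baseline + trophic offset + individual
#' noise at scales matching the study populations (delta-15N offsets around
#' 4--6 permil, individual sds 0.5--2 permil).
#'
#' @param seed integer seed; all generators derive their streams from it.
#' @param grid `grid_surface` template (default [grid_spec()]).
#' @param d13C_mean,d15N_mean isoscape values at the grid centre, permil.
#' @param d13C_grad,d15N_grad `c(per_deg_lat, per_deg_lon)` gradients.
#' @param noise_sd sd of the smoothed spatial noise field, permil.
#' @param smoothing_deg Gaussian smoothing length of the noise, degrees.
#' @param n_individuals individuals per group.
#' @param colony `c(lon, lat)` of the breeding colony.
#' @param centroid `c(lon, lat)` of the group wintering centroid.
#' @param centroid_scatter_deg sd of per-individual centroid scatter.
#' @param step_bias_km,step_sd_km daily drift towards the centroid and
#'   random-walk step sd, km/day.
#' @param geo_error_km per-axis geolocation error sd, km
#'   (default `186 / sqrt(2)` so radial RMS error is 186 km).
#' @param delta13C_fj,delta15N_fj group trophic offsets, permil.
#' @param ind_sd_d13C,ind_sd_d15N individual feather sds, permil.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            grid = grid_spec(),
                            d13C_mean = -17.5, d15N_mean = 10.5,
                            d13C_grad = c(-0.15, 0.20),
                            d15N_grad = c(-0.30, 0.10),
                            noise_sd = 0.3, smoothing_deg = 0.5,
                            n_individuals = 10L,
                            colony = c(lon = -2.57, lat = 56.19),
                            centroid = c(lon = 1.0, lat = 57.5),
                            centroid_scatter_deg = 0.3,
                            step_bias_km = 30, step_sd_km = 20,
                            geo_error_km = 186 / sqrt(2),
                            delta13C_fj = 0.5, delta15N_fj = 5.0,
                            ind_sd_d13C = 0.5, ind_sd_d15N = 1.0) {
  stopifnot(noise_sd >= 0, smoothing_deg >= 0, geo_error_km >= 0,
            ind_sd_d13C >= 0, ind_sd_d15N >= 0, n_individuals >= 1)
  structure(as.list(environment()), class = "scenario_config")
}

# separable Gaussian blur with edge renormalisation
.gauss_blur <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(seq(-r, r), sd = sigma_cells)
  conv_cols <- function(M) {
    np <- matrix(0, r, ncol(M))
    Mp <- rbind(np, M, np)
    out <- M
    for (i in seq_len(nrow(M))) {
      out[i, ] <- colSums(Mp[i:(i + 2 * r), , drop = FALSE] * k)
    }
    out
  }
  num <- conv_cols(t(conv_cols(m)))
  den <- conv_cols(t(conv_cols(matrix(1, nrow(m), ncol(m)))))
  t(num / den)
}

#' Generate a synthetic dual-isotope isoscape
#'
#' Per isotope: `value(lon, lat) = centre value + a * (lat - lat_mid) +
#' b * (lon - lon_mid) + smoothed noise`, where the noise is seeded white
#' noise blurred with a Gaussian of `smoothing_deg` and rescaled to sd
#' `noise_sd`. Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return list with `isoscape` (an [isoscape()]) and `gradients` (the
#'   generating coefficients, for recovery tests).
#' @export
gen_isoscape <- function(cfg) {
  g <- cfg$grid
  lons <- grid_lons(g); lats <- grid_lats(g)
  lon_mid <- mean(range(lons)); lat_mid <- mean(range(lats))
  latm <- matrix(lats, length(lats), length(lons))
  lonm <- matrix(lons, length(lats), length(lons), byrow = TRUE)
  set.seed(cfg$seed + 101L)
  field <- function(mean0, grad) {
    v <- mean0 + grad[1] * (latm - lat_mid) + grad[2] * (lonm - lon_mid)
    if (cfg$noise_sd > 0) {
      noise <- .gauss_blur(matrix(stats::rnorm(length(v)), nrow(v), ncol(v)),
                           cfg$smoothing_deg / g$resolution)
      v <- v + noise / stats::sd(noise) * cfg$noise_sd
    }
    v
  }
  d13C <- grid_surface(field(cfg$d13C_mean, cfg$d13C_grad),
                       g$lon_min, g$lat_min, g$resolution)
  d15N <- grid_surface(field(cfg$d15N_mean, cfg$d15N_grad),
                       g$lon_min, g$lat_min, g$resolution)
  list(isoscape = isoscape(d13C, d15N),
       gradients = list(d13C = cfg$d13C_grad, d15N = cfg$d15N_grad,
                        d13C_mean = cfg$d13C_mean, d15N_mean = cfg$d15N_mean))
}

#' Ground truth for one group of individuals
#'
#' Draws per-individual wintering/moult centroids around the group centroid
#' and records the group's trophic offsets -- the quantities downstream
#' recovery tests compare against.
#'
#' @param cfg a [scenario_config()].
#' @param species,winter labels attached to the individuals.
#' @param id_prefix prefix for individual ids.
#' @return data.frame with one row per individual: ids, labels, true
#'   centroid, group offsets and individual sds.
#' @export
gen_ground_truth <- function(cfg, species = "sp1", winter = "2014/15",
                             id_prefix = species) {
  set.seed(cfg$seed + 202L)
  n <- cfg$n_individuals
  lon <- cfg$centroid[["lon"]] + stats::rnorm(n, 0, cfg$centroid_scatter_deg)
  lat <- cfg$centroid[["lat"]] + stats::rnorm(n, 0, cfg$centroid_scatter_deg)
  g <- cfg$grid
  if (any(lon < g$lon_min | lon > g$lon_min + ncol(g$values) * g$resolution |
          lat < g$lat_min | lat > g$lat_min + nrow(g$values) * g$resolution)) {
    stop("true centroid outside grid")
  }
  data.frame(
    individual_id = sprintf("%s_%s_%02d", id_prefix, gsub("/", "", winter), 1:n),
    species = species, winter = winter,
    centroid_lon = lon, centroid_lat = lat,
    delta13C_fj = cfg$delta13C_fj, delta15N_fj = cfg$delta15N_fj,
    ind_sd_d13C = cfg$ind_sd_d13C, ind_sd_d15N = cfg$ind_sd_d15N,
    stringsAsFactors = FALSE
  )
}

.km_per_deg_lat <- 111.2

#' Generate geolocator tracks for one group
#'
#' Each individual starts at the colony on 1 July and performs a daily
#' biased random walk towards its true centroid (drift `step_bias_km`
#' capped at the remaining distance, plus isotropic noise `step_sd_km`)
#' until 31 March. Observed fixes add independent per-axis Gaussian
#' position error of `geo_error_km` (longitude scaled by `cos(lat)`).
#'
#' @param cfg a [scenario_config()].
#' @param truth output of [gen_ground_truth()].
#' @return list with `fixes` (observed, a fixes data.frame) and
#'   `true_path` (noise-free positions, same layout).
#' @export
gen_tracks <- function(cfg, truth) {
  set.seed(cfg$seed + 303L)
  year1 <- suppressWarnings(as.integer(substr(truth$winter[1], 1, 4)))
  if (is.na(year1)) year1 <- 2014L
  dates <- seq(as.Date(sprintf("%d-07-01", year1)),
               as.Date(sprintf("%d-03-31", year1 + 1L)), by = "day")
  res <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tc <- c(truth$centroid_lon[i], truth$centroid_lat[i])
    pos <- matrix(NA_real_, length(dates), 2)
    p <- c(cfg$colony[["lon"]], cfg$colony[["lat"]])
    for (d in seq_along(dates)) {
      kx <- .km_per_deg_lat * cos(p[2] * pi / 180)
      ky <- .km_per_deg_lat
      delta_km <- c((tc[1] - p[1]) * kx, (tc[2] - p[2]) * ky)
      dist <- sqrt(sum(delta_km^2))
      drift <- if (dist > 0) delta_km / dist * min(cfg$step_bias_km, dist) else c(0, 0)
      step <- drift + stats::rnorm(2, 0, cfg$step_sd_km)
      p <- p + c(step[1] / kx, step[2] / ky)
      pos[d, ] <- p
    }
    err <- matrix(stats::rnorm(2 * length(dates), 0, cfg$geo_error_km),
                  ncol = 2)
    obs_lon <- pos[, 1] + err[, 1] / (.km_per_deg_lat * cos(pos[, 2] * pi / 180))
    obs_lat <- pos[, 2] + err[, 2] / .km_per_deg_lat
    res[[i]] <- data.frame(
      individual_id = truth$individual_id[i], species = truth$species[i],
      winter = truth$winter[i], date = dates,
      lon = obs_lon, lat = pmin(pmax(obs_lat, -90), 90),
      true_lon = pos[, 1], true_lat = pos[, 2],
      stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, res)
  fixes <- as_fixes(all[, c("individual_id", "species", "winter",
                            "date", "lon", "lat")])
  true_path <- all[, c("individual_id", "species", "winter",
                       "date", "true_lon", "true_lat")]
  list(fixes = fixes, true_path = true_path)
}

#' Generate feather samples for one group
#'
#' `feather value = isoscape value at the individual's true centroid +
#' group trophic offset + Normal(0, individual sd)`, per isotope.
#'
#' @param cfg a [scenario_config()].
#' @param truth output of [gen_ground_truth()].
#' @param iso an [isoscape()].
#' @param feather_type label attached to the samples; default `"body"`.
#' @return a feather data.frame (see [read_feathers_csv()]).
#' @export
gen_feathers <- function(cfg, truth, iso, feather_type = "body") {
  set.seed(cfg$seed + 404L)
  n <- nrow(truth)
  base_c <- grid_value_at(iso$d13C, truth$centroid_lon, truth$centroid_lat)
  base_n <- grid_value_at(iso$d15N, truth$centroid_lon, truth$centroid_lat)
  if (anyNA(base_c) || anyNA(base_n)) stop("true centroid outside isoscape")
  data.frame(
    individual_id = truth$individual_id, species = truth$species,
    feather_type = feather_type, winter = truth$winter,
    d13C = base_c + truth$delta13C_fj + stats::rnorm(n, 0, truth$ind_sd_d13C[1]),
    d15N = base_n + truth$delta15N_fj + stats::rnorm(n, 0, truth$ind_sd_d15N[1]),
    stringsAsFactors = FALSE
  )
}

#' Two-winter contrast scenario with known ground truth
#'
#' Builds the full synthetic input bundle for the package's end-to-end
#' contrast: two species across two winters. The "stay" species keeps its
#' wintering centroid in both winters but switches diet (its injected
#' delta-15N offset drops from 4.63 to 1.74 permil in the poor winter); the
#' "move" species keeps a near-constant, slightly raised offset (6.30 vs
#' 6.13 permil) but shifts its centroid into the southern study area in the
#' poor winter. Offset magnitudes, sds, sample sizes and the 186 km
#' position error follow the scales of the study populations.
#'
#' @param seed integer seed.
#' @param n_individuals individuals per species per winter; default 10.
#' @param grid shared `grid_surface` template.
#' @return list with `fixes`, `feathers`, `isoscape`, `truth` (all groups),
#'   `groups` (per-group configs) and `expected` (injected qualitative
#'   outcomes: which species should show high between-winter overlap and
#'   the injected offset change).
#' @export
gen_two_winter_scenario <- function(seed = 1L, n_individuals = 10L,
                                    grid = grid_spec()) {
  base <- scenario_config(seed = seed, grid = grid,
                          n_individuals = n_individuals)
  iso <- gen_isoscape(base)$isoscape
  groups <- list(
    stay_w1 = list(species = "stay", winter = "2007/08",
                   centroid = c(lon = 1.0, lat = 57.5),
                   delta13C_fj = -0.02, delta15N_fj = 1.74),
    stay_w2 = list(species = "stay", winter = "2014/15",
                   centroid = c(lon = 1.0, lat = 57.5),
                   delta13C_fj = -0.60, delta15N_fj = 4.63),
    move_w1 = list(species = "move", winter = "2007/08",
                   centroid = c(lon = 5.0, lat = 53.5),
                   delta13C_fj = 0.65, delta15N_fj = 6.13),
    move_w2 = list(species = "move", winter = "2014/15",
                   centroid = c(lon = 0.0, lat = 56.8),
                   delta13C_fj = 1.11, delta15N_fj = 6.30)
  )
  fixes <- list(); feathers <- list(); truths <- list()
  k <- 0L
  for (nm in names(groups)) {
    gp <- groups[[nm]]
    k <- k + 1L
    cfg <- scenario_config(seed = seed + k * 1000L, grid = grid,
                           n_individuals = n_individuals,
                           centroid = gp$centroid,
                           delta13C_fj = gp$delta13C_fj,
                           delta15N_fj = gp$delta15N_fj)
    tr <- gen_ground_truth(cfg, species = gp$species, winter = gp$winter)
    tk <- gen_tracks(cfg, tr)
    fixes[[nm]] <- tk$fixes
    feathers[[nm]] <- gen_feathers(cfg, tr, iso)
    truths[[nm]] <- tr
  }
  list(
    fixes = as_fixes(do.call(rbind, c(fixes, list(make.row.names = FALSE)))),
    feathers = do.call(rbind, c(feathers, list(make.row.names = FALSE))),
    isoscape = iso,
    truth = do.call(rbind, c(truths, list(make.row.names = FALSE))),
    groups = groups,
    expected = list(
      high_overlap_species = "stay",
      low_overlap_species = "move",
      offset_change_species = "stay",
      injected_d15N_change = groups$stay_w2$delta15N_fj -
        groups$stay_w1$delta15N_fj
    )
  )
}

#' Write a scenario bundle to disk
#'
#' Writes `fixes.csv`, `feathers.csv`, `isoscape_d13C.csv` /
#' `isoscape_d15N.csv` (plain-text grid format), `truth.csv` and
#' `scenario.yaml` into a directory.
#'
#' @param bundle output of [gen_two_winter_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$fixes, file.path(dir, "fixes.csv"), row.names = FALSE)
  utils::write.csv(bundle$feathers, file.path(dir, "feathers.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write_grid_csv(bundle$isoscape$d13C, file.path(dir, "isoscape_d13C.csv"))
  write_grid_csv(bundle$isoscape$d15N, file.path(dir, "isoscape_d15N.csv"))
  yaml::write_yaml(bundle$groups, file.path(dir, "scenario.yaml"))
  invisible(dir)
}
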