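#' Construct a calibration offset directly
#'
#' Mostly useful for sensitivity analyses and simulation studies where the
#' offset is known rather than derived via [derive_offset()].
#'
#' @param delta13C_fj,delta15N_fj offset means (feather minus isoscape),
#'   permil.
#' @param sd13C,sd15N offset standard deviations, permil.
#' @param n_draws number of draws behind the estimate (metadata).
#' @return a `calibration_offset`.
#' @export
calibration_offset <- function(delta13C_fj, sd13C, delta15N_fj, sd15N,
                               n_draws = 1L) {
  stopifnot(sd13C >= 0, sd15N >= 0, n_draws >= 1)
  structure(list(delta13C_fj = delta13C_fj, sd13C = sd13C,
                 delta15N_fj = delta15N_fj, sd15N = sd15N,
                 n_draws = as.integer(n_draws)),
            class = "calibration_offset")
}

#' Simulation check of likely-region coverage
#'
#' Generates individuals exactly from the assignment model -- true origin
#' cell drawn from the prior, feather isotopes drawn from the bivariate
#' normal likelihood centred on that cell -- assigns each one, and reports
#' the fraction whose true origin falls inside the top-`mass_quantile`
#' likely region. Under a correctly specified model this coverage equals
#' the mass quantile (up to the discrete overshoot of at most one cell's
#' probability), so it is the package's calibration check for the whole
#' posterior chain.
#'
#' @param seed integer seed.
#' @param n_individuals number of simulated individuals; default 500.
#' @param mass_quantile likely-region mass; default 0.30.
#' @param grid simulation grid; default a 60 x 60 cell 0.1-degree window.
#' @return observed coverage fraction in `[0, 1]`.
#' @export
posterior_calibration_coverage <- function(seed = 1L, n_individuals = 500,
                                           mass_quantile = 0.30,
                                           grid = grid_spec(0, 6, 53, 59, 0.1)) {
  cfg <- scenario_config(seed = seed, grid = grid)
  iso <- gen_isoscape(cfg)$isoscape
  set.seed(seed + 1L)
  # smooth bimodal prior from a small set of synthetic winter fixes
  centers <- rbind(c(2, 55), c(4, 57))
  pts <- centers[sample(1:2, 60, replace = TRUE), ] +
    matrix(stats::rnorm(120, 0, 0.6), ncol = 2)
  fx <- data.frame(individual_id = "prior", species = "sim", winter = "w",
                   date = as.Date("2014-11-01") + 1:60,
                   lon = pmin(pmax(pts[, 1], grid$lon_min + 0.2), 5.8),
                   lat = pmin(pmax(pts[, 2], grid$lat_min + 0.2), 58.8))
  prior <- normalize_surface(kde_surface(as_fixes(fx), 0.5, grid))
  cal <- calibration_offset(0.5, 0.4, 4.0, 0.7, n_draws = 1000)
  cond <- assignment_conditions(cal, measurement_sd = 0.2,
                                between_var_d13C = 0.5,
                                between_var_d15N = 0.5,
                                mass_quantile = mass_quantile)
  sdc <- sqrt(0.2^2 + 0.5 + 0.4^2)
  sdn <- sqrt(0.2^2 + 0.5 + 0.7^2)
  pvec <- as.vector(prior$values)
  hits <- logical(n_individuals)
  for (i in seq_len(n_individuals)) {
    cell <- sample.int(length(pvec), 1, prob = pvec)
    feather <- list(
      d13C = iso$d13C$values[cell] + cal$delta13C_fj + stats::rnorm(1, 0, sdc),
      d15N = iso$d15N$values[cell] + cal$delta15N_fj + stats::rnorm(1, 0, sdn))
    post <- posterior_surface(prior, likelihood_surface(feather, iso, cond))
    hits[i] <- likely_region(post, mass_quantile)$values[cell]
  }
  mean(hits)
}

#' End-to-end recovery on the two-winter contrast scenario
#'
#' Runs the full pipeline on [gen_two_winter_scenario()] output and
#' summarises the two injected contrasts: the between-winter likely-region
#' overlap of the "stay" vs the "move" species, and the change in the
#' derived delta-15N calibration offset of the diet-switching species.
#' The residency polygon is padded beyond the grid by the geolocation
#' -error scale, and the assignment moult window is set to the months the
#' simulated birds occupy their wintering centroid (Nov--Feb).
#'
#' @param seed integer seed.
#' @param n_individuals individuals per species per winter; default 10.
#' @param resolution grid resolution in degrees; default 0.5 (coarse keeps
#'   runtime modest; the science is resolution-robust at these scales).
#' @param n_draws Monte-Carlo draws for offsets; default 1000.
#' @return list with `stay_overlap`, `move_overlap` (percent),
#'   `stay_offset_change`, `injected_change` (permil) and the full
#'   pipeline `results`.
#' @export
two_winter_recovery <- function(seed = 1L, n_individuals = 10,
                                resolution = 0.5, n_draws = 1000) {
  bundle <- gen_two_winter_scenario(seed = seed,
                                    n_individuals = n_individuals,
                                    grid = grid_spec(resolution = resolution))
  winter_months <- c(11L, 12L, 1L, 2L)
  res <- run_pipeline(list(
    fixes = bundle$fixes, feathers = bundle$feathers,
    isoscape = bundle$isoscape,
    region = north_sea_polygon(-12, 18, 44, 70),
    moult_windows = list(
      stay_body = moult_window("stay", "body", winter_months),
      move_body = moult_window("move", "body", winter_months)
    ),
    n_draws = n_draws, seed = seed
  ))
  winters <- c("2007/08", "2014/15")
  stay_ov <- winter_region_overlap(res, "stay", "body", winters)
  move_ov <- winter_region_overlap(res, "move", "body", winters)
  off <- function(w) {
    for (r in res) if (r$species == "stay" && r$winter == w) return(r$offset)
    stop("missing group")
  }
  list(stay_overlap = stay_ov, move_overlap = move_ov,
       stay_offset_change = off("2014/15")$delta15N_fj -
         off("2007/08")$delta15N_fj,
       injected_change = bundle$expected$injected_d15N_change,
       results = res)
}
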