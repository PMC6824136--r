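#' Full assignment pipeline
#'
#' Runs the whole chain for every species x feather type x winter group
#' present in the feather table: equinox and speed filtering of fixes,
#' study-region residency gating over the feather's moult window, a
#' kernel-density prior from the season's fixes, the density-floor mask,
#' Monte-Carlo calibration offset against the isoscape, per-individual
#' bivariate-normal likelihood and posterior surfaces, likely-region
#' extraction, and the population-combined surface. Errors carry the stage
#' at which they occurred.
#'
#' The configuration is a list (or path to a YAML file) with elements:
#' \describe{
#'   \item{fixes}{fixes data.frame or CSV path (see [read_tracks_csv()]).}
#'   \item{feathers}{feather data.frame or CSV path.}
#'   \item{isoscape}{an [isoscape()] or `list(d13C =, d15N =)` of grid CSV
#'     paths.}
#'   \item{moult_windows}{named list of [moult_window()]s; defaults to
#'     body Jul--Sep, cheek Jan--Mar for every species present.}
#'   \item{region}{study-region polygon; default [north_sea_polygon()].}
#'   \item{equinox_windows}{default [equinox_windows()]; `NULL` disables.}
#'   \item{max_kmday}{speed-filter threshold; default 500.}
#'   \item{bandwidth}{KDE bandwidth in degrees; `NULL` (default) averages
#'     the per-axis normal-reference values of the season's fixes.}
#'   \item{kde_floor}{prior-mask density floor; default 0.01.}
#'   \item{measurement_sd, mass_quantile, n_draws}{assignment constants;
#'     defaults 0.2, 0.30, 1000.}
#'   \item{between_var}{`NULL` (default: per-group feather variance) or a
#'     data.frame `species, winter, var_d13C, var_d15N`.}
#'   \item{uniform_prior}{if `TRUE`, replace the KDE prior by a uniform
#'     prior over the mask (sensitivity mode); default `FALSE`.}
#'   \item{seed}{base seed for all Monte-Carlo draws; default 1.}
#'   \item{out_dir}{optional directory for surfaces and the run log.}
#' }
#'
#' @param config list or YAML path as described above.
#' @return a named list of per-group results (class `assignment_result`):
#'   each holds `prior`, `mask`, `offset`, `conditions`, `posteriors`
#'   (per individual), `regions` (per individual), `population`,
#'   `population_region`, `eligible_ids`, `bandwidth`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .pipeline_defaults(config)
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }
  fixes <- with_stage("read_fixes",
    if (is.character(cfg$fixes)) read_tracks_csv(cfg$fixes) else as_fixes(cfg$fixes))
  feathers <- with_stage("read_feathers",
    if (is.character(cfg$feathers)) read_feathers_csv(cfg$feathers) else cfg$feathers)
  iso <- with_stage("read_isoscape",
    if (inherits(cfg$isoscape, "isoscape")) cfg$isoscape
    else isoscape(read_grid_csv(cfg$isoscape$d13C), read_grid_csv(cfg$isoscape$d15N)))

  if (!is.null(cfg$equinox_windows)) {
    fixes <- with_stage("filter_equinox", filter_equinox(fixes, cfg$equinox_windows))
  }
  fixes <- with_stage("filter_speed", filter_speed(fixes, cfg$max_kmday))

  groups <- unique(feathers[, c("species", "feather_type", "winter")])
  groups <- groups[order(groups$species, groups$feather_type, groups$winter), ,
                   drop = FALSE]
  results <- list()
  for (gi in seq_len(nrow(groups))) {
    sp <- groups$species[gi]; ft <- groups$feather_type[gi]
    wt <- groups$winter[gi]
    gname <- paste(sp, ft, gsub("/", "", wt), sep = "_")
    window <- cfg$moult_windows[[paste(sp, ft, sep = "_")]]
    if (is.null(window)) window <- moult_window(sp, ft, if (ft == "body") 7:9 else 1:3)
    fg <- fixes[fixes$species == sp & fixes$winter == wt, , drop = FALSE]
    if (nrow(fg) == 0L) stop(sprintf("stage 'tracks': no fixes for group %s", gname))

    resid <- with_stage("residency", moult_residency(fg, window, cfg$region))
    eligible <- names(resid)[!is.na(resid) & resid]
    if (length(eligible) == 0L) {
      stop(sprintf("stage 'residency': no resident individuals in group %s", gname))
    }
    season <- fg[fg$individual_id %in% eligible &
                   as.integer(format(fg$date, "%m")) %in% window$months, ,
                 drop = FALSE]
    if (nrow(season) == 0L) {
      stop(sprintf("stage 'prior': no in-window fixes for group %s", gname))
    }
    bw <- cfg$bandwidth
    if (is.null(bw)) {
      bw <- mean(c(nrd_bandwidth(season$lon), nrd_bandwidth(season$lat)))
    }
    kde <- with_stage("prior", kde_surface(season, bw, iso$d13C))
    mask <- with_stage("mask", kde_mask(kde, cfg$kde_floor))
    prior <- if (isTRUE(cfg$uniform_prior)) {
      u <- mask; u$values <- as.numeric(mask$values); normalize_surface(u)
    } else normalize_surface(kde)

    fe <- feathers[feathers$species == sp & feathers$feather_type == ft &
                     feathers$winter == wt &
                     feathers$individual_id %in% eligible, , drop = FALSE]
    if (nrow(fe) < 2L) {
      stop(sprintf("stage 'offset': fewer than 2 eligible feathers in group %s", gname))
    }
    iso_vals <- with_stage("extract", extract_values(iso, mask))
    offset <- with_stage("offset",
      derive_offset(iso_vals, fe, n_draws = cfg$n_draws, seed = cfg$seed + gi))

    bv <- .lookup_between_var(cfg$between_var, sp, wt, fe)
    cond <- assignment_conditions(offset,
                                  measurement_sd = cfg$measurement_sd,
                                  between_var_d13C = bv[1],
                                  between_var_d15N = bv[2],
                                  mass_quantile = cfg$mass_quantile)
    posteriors <- list(); regions <- list()
    for (k in seq_len(nrow(fe))) {
      L <- with_stage("likelihood", likelihood_surface(fe[k, ], iso, cond))
      post <- with_stage("posterior", posterior_surface(prior, L))
      posteriors[[fe$individual_id[k]]] <- post
      regions[[fe$individual_id[k]]] <- likely_region(post, cfg$mass_quantile)
    }
    pop <- with_stage("population", population_surface(posteriors))
    results[[gname]] <- structure(list(
      species = sp, feather_type = ft, winter = wt,
      prior = prior, mask = mask, offset = offset, conditions = cond,
      posteriors = posteriors, regions = regions,
      population = pop,
      population_region = likely_region(pop, cfg$mass_quantile),
      eligible_ids = eligible, bandwidth = bw
    ), class = "assignment_result")
  }
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(results, cfg)
  results
}

.pipeline_defaults <- function(config) {
  defaults <- list(
    moult_windows = NULL, region = north_sea_polygon(),
    equinox_windows = equinox_windows(), max_kmday = 500,
    bandwidth = NULL, kde_floor = 0.01,
    measurement_sd = 0.2, mass_quantile = 0.30, n_draws = 1000,
    between_var = NULL, uniform_prior = FALSE, seed = 1L, out_dir = NULL
  )
  utils::modifyList(defaults, config, keep.null = TRUE)
}

.lookup_between_var <- function(bv, species, winter, feathers) {
  if (is.null(bv)) {
    return(c(stats::var(feathers$d13C), stats::var(feathers$d15N)))
  }
  row <- bv[bv$species == species & bv$winter == winter, , drop = FALSE]
  if (nrow(row) == 0L) stop("no between-individual variance entry for ",
                            species, " ", winter)
  c(row$var_d13C[1], row$var_d15N[1])
}

.write_pipeline_outputs <- function(results, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = cfg$seed, n_draws = cfg$n_draws,
                  measurement_sd = cfg$measurement_sd,
                  mass_quantile = cfg$mass_quantile, groups = list())
  for (nm in names(results)) {
    r <- results[[nm]]
    write_grid_csv(r$population, file.path(cfg$out_dir, paste0(nm, "_population.csv")))
    reg <- r$population_region
    reg$values <- reg$values + 0
    write_grid_csv(reg, file.path(cfg$out_dir, paste0(nm, "_region.csv")))
    summary$groups[[nm]] <- list(
      species = r$species, feather_type = r$feather_type, winter = r$winter,
      n_individuals = length(r$posteriors), bandwidth = r$bandwidth,
      offset = unclass(r$offset),
      region_cells = sum(r$population_region$values)
    )
  }
  jsonlite::write_json(summary, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Between-winter overlap of population likely regions
#'
#' Convenience comparison across pipeline results: the percentage of the
#' reference winter's population likely region shared with the other
#' winter, for one species and feather type.
#'
#' @param results output of [run_pipeline()].
#' @param species,feather_type group selectors.
#' @param winters character vector of two winter labels; the *first* is the
#'   reference (denominator).
#' @return overlap percentage.
#' @export
winter_region_overlap <- function(results, species, feather_type, winters) {
  stopifnot(length(winters) == 2)
  pick <- function(w) {
    for (r in results) {
      if (r$species == species && r$feather_type == feather_type && r$winter == w) {
        return(r$population_region)
      }
    }
    stop("no pipeline result for ", species, " ", feather_type, " ", w)
  }
  region_overlap(pick(winters[2]), pick(winters[1]), reference = "b")
}
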