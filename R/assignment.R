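#' Feather isotope tables
#'
#' Feather measurements are a data.frame with columns `individual_id`,
#' `species`, `feather_type` (`"body"`/`"cheek"`), `winter`, `d13C`, `d15N`.
#'
#' @param path CSV file path.
#' @return a data.frame of feather samples.
#' @export
read_feathers_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "species", "feather_type", "winter", "d13C", "d15N")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("feather table is missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Threshold a density surface into a mask
#'
#' Cells with density strictly above `floor` (default 0.01) define the
#' region "visited" by the tracked population; the isoscape is summarised
#' over this mask when deriving calibration offsets, and it doubles as the
#' assignment prior support.
#'
#' @param kde a density `grid_surface`.
#' @param floor density cut; default 0.01.
#' @return a logical `grid_surface`.
#' @export
kde_mask <- function(kde, floor = 0.01) {
  m <- kde
  m$values <- kde$values > floor & !is.na(kde$values)
  if (!any(m$values)) stop("empty mask: no cells above floor")
  m
}

#' Monte-Carlo calibration offset between feathers and isoscape
#'
#' The calibration offset absorbs tissue-type and trophic-level isotopic
#' differences between consumer feathers and the isoscape's reference
#' organism. Per isotope, `n_draws` pairs are drawn independently from
#' `Normal(median_feather, sd_feather)` and `Normal(median_isoscape,
#' sd_isoscape)` (medians/sds computed from the supplied values); the
#' offset is the mean of feather-minus-isoscape differences and its sd the
#' sd of those differences. As `n_draws` grows the offset converges to the
#' difference of medians and the sd to `sqrt(sd_f^2 + sd_j^2)`.
#' Zero-variance inputs act as point masses.
#'
#' @param iso_values paired list from [extract_values()].
#' @param feathers feather data.frame (one population / feather type /
#'   winter) with `d13C`, `d15N`.
#' @param n_draws Monte-Carlo draws; default 1000.
#' @param seed optional integer seed for reproducibility.
#' @return a `calibration_offset`: list with `delta13C_fj`, `sd13C`,
#'   `delta15N_fj`, `sd15N`, `n_draws`.
#' @export
derive_offset <- function(iso_values, feathers, n_draws = 1000, seed = NULL) {
  stopifnot(nrow(feathers) >= 2, length(iso_values$d13C) >= 2, n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  one <- function(f, j) {
    xf <- stats::rnorm(n_draws, stats::median(f), stats::sd(f))
    xj <- stats::rnorm(n_draws, stats::median(j), stats::sd(j))
    d <- xf - xj
    c(mean = mean(d), sd = if (n_draws > 1) stats::sd(d) else 0)
  }
  oc <- one(feathers$d13C, iso_values$d13C)
  on <- one(feathers$d15N, iso_values$d15N)
  structure(list(delta13C_fj = unname(oc["mean"]), sd13C = unname(oc["sd"]),
                 delta15N_fj = unname(on["mean"]), sd15N = unname(on["sd"]),
                 n_draws = n_draws),
            class = "calibration_offset")
}

#' @export
print.calibration_offset <- function(x, ...) {
  cat(sprintf("<calibration_offset> D13C_f-j = %.2f (sd %.2f), D15N_f-j = %.2f (sd %.2f), %d draws\n",
              x$delta13C_fj, x$sd13C, x$delta15N_fj, x$sd15N, x$n_draws))
  invisible(x)
}

#' Assignment error model
#'
#' Bundles the variance components and thresholds of the per-cell
#' assignment: analytical measurement error (sd, permil; default 0.2 for
#' both isotopes), measured between-individual variance (permil^2, per
#' isotope, population-specific), the Monte-Carlo calibration offset with
#' its sd, and the likely-region mass quantile (default 0.30; the
#' associated odds-ratio constant 1.42 is carried as metadata only). The
#' total per-isotope likelihood variance is
#' `measurement_sd^2 + between_individual_var + calibration_sd^2`,
#' treating the isotopes as independent (diagonal covariance).
#'
#' @param calibration a `calibration_offset`.
#' @param measurement_sd analytical sd per isotope, permil.
#' @param between_var_d13C,between_var_d15N between-individual variance,
#'   permil^2.
#' @param mass_quantile likely-region cumulative probability; default 0.30.
#' @param odds_threshold informational odds-ratio constant; default 1.42.
#' @param include_isoscape_sd if `TRUE`, add the isoscape prediction
#'   variance (when sd surfaces exist) to the total; default `FALSE`.
#' @return an `assignment_conditions` list.
#' @export
assignment_conditions <- function(calibration,
                                  measurement_sd = 0.2,
                                  between_var_d13C = 0,
                                  between_var_d15N = 0,
                                  mass_quantile = 0.30,
                                  odds_threshold = 1.42,
                                  include_isoscape_sd = FALSE) {
  stopifnot(measurement_sd >= 0, between_var_d13C >= 0, between_var_d15N >= 0,
            mass_quantile > 0, mass_quantile < 1)
  structure(list(calibration = calibration,
                 measurement_sd = measurement_sd,
                 between_var_d13C = between_var_d13C,
                 between_var_d15N = between_var_d15N,
                 mass_quantile = mass_quantile,
                 odds_threshold = odds_threshold,
                 include_isoscape_sd = include_isoscape_sd),
            class = "assignment_conditions")
}

#' Measured between-individual feather variances
#'
#' Reference between-individual isotope variances (permil^2) measured for
#' the two study populations in each winter, plus the isoscape reference
#' organism, for use as `between_var_*` defaults in
#' [assignment_conditions()].
#'
#' @return data.frame with columns `population`, `winter`,
#'   `var_d13C`, `var_d15N`.
#' @export
between_individual_variances <- function() {
  data.frame(
    population = c("jellyfish", "puffin", "puffin", "razorbill", "razorbill"),
    winter = c(NA, "2007/08", "2014/15", "2007/08", "2014/15"),
    var_d13C = c(0.78, 0.60, 0.52, 0.63, 0.51),
    var_d15N = c(1.02, 2.74, 0.91, 2.10, 0.58),
    stringsAsFactors = FALSE
  )
}

# total likelihood variance per isotope
.total_var <- function(cond) {
  cal <- cond$calibration
  c(d13C = cond$measurement_sd^2 + cond$between_var_d13C + cal$sd13C^2,
    d15N = cond$measurement_sd^2 + cond$between_var_d15N + cal$sd15N^2)
}

#' Bivariate-normal likelihood surface for one feather
#'
#' For each isoscape cell `i`, the likelihood that the feather grew there:
#' the product of two independent normal densities centred on the cell's
#' isoscape value plus the calibration offset, with total variance
#' `measurement^2 + between-individual + calibration sd^2` per isotope.
#' Nodata cells get likelihood 0. A feather far outside the isoscape
#' support yields an (all but) all-zero surface and a warning.
#'
#' @param feather one feather: any list/row with `d13C` and `d15N`.
#' @param iso an [isoscape()].
#' @param cond an [assignment_conditions()].
#' @return a `grid_surface` of unnormalised likelihoods.
#' @export
likelihood_surface <- function(feather, iso, cond) {
  v <- .total_var(cond)
  if (isTRUE(cond$include_isoscape_sd)) {
    vc <- v["d13C"] + if (!is.null(iso$d13C_sd)) iso$d13C_sd$values^2 else 0
    vn <- v["d15N"] + if (!is.null(iso$d15N_sd)) iso$d15N_sd$values^2 else 0
  } else {
    vc <- v["d13C"]; vn <- v["d15N"]
  }
  cal <- cond$calibration
  L <- stats::dnorm(feather$d13C, iso$d13C$values + cal$delta13C_fj, sqrt(vc)) *
       stats::dnorm(feather$d15N, iso$d15N$values + cal$delta15N_fj, sqrt(vn))
  L[is.na(L)] <- 0
  if (max(L) < 1e-300) {
    warning("likelihood numerically zero everywhere: feather far outside isoscape support")
  }
  grid_surface(L, iso$d13C$lon_min, iso$d13C$lat_min, iso$d13C$resolution)
}

#' Posterior assignment surface
#'
#' Cellwise product of a location prior (season-matched utilisation density,
#' normalised to sum 1) and the isotope likelihood, renormalised to sum 1.
#' Zero-prior cells are hard zeros in the posterior.
#'
#' @param prior,likelihood aligned `grid_surface` objects.
#' @return a `grid_surface` summing to 1.
#' @export
posterior_surface <- function(prior, likelihood) {
  stop_if_misaligned(prior, likelihood)
  p <- prior$values * likelihood$values
  p[is.na(p)] <- 0
  tot <- sum(p)
  if (tot <= 0) stop("prior and likelihood have disjoint support")
  prior$values <- p / tot
  prior
}

#' Normalise a surface to a probability distribution
#'
#' @param s a non-negative `grid_surface`.
#' @return `s` rescaled so its cells sum to 1.
#' @export
normalize_surface <- function(s) {
  v <- s$values
  v[is.na(v)] <- 0
  tot <- sum(v)
  if (tot <= 0) stop("cannot normalise an all-zero surface")
  s$values <- v / tot
  s
}

#' Highest-posterior "likely region"
#'
#' The smallest set of highest-posterior cells whose cumulative probability
#' reaches `mass_quantile` (default 0.30, the study's top-30% rule; the
#' conventional odds-ratio constant 1.42 names the same region and is kept as
#' metadata in [assignment_conditions()]). Ties are broken by ascending
#' cell index, so the result is deterministic.
#'
#' @param posterior a `grid_surface` summing to 1.
#' @param mass_quantile cumulative probability to cover; default 0.30.
#' @return a logical `grid_surface`.
#' @export
likely_region <- function(posterior, mass_quantile = 0.30) {
  stopifnot(mass_quantile > 0, mass_quantile < 1)
  p <- as.vector(posterior$values)
  p[is.na(p)] <- 0
  ord <- order(-p, seq_along(p))   # ties: ascending cell index
  csum <- cumsum(p[ord])
  k <- which(csum >= mass_quantile - 1e-12)[1]
  if (is.na(k)) k <- length(p)
  sel <- logical(length(p))
  sel[ord[seq_len(k)]] <- p[ord[seq_len(k)]] > 0
  out <- posterior
  out$values <- matrix(sel, nrow(posterior$values), ncol(posterior$values))
  out
}

#' Population-combined assignment surface
#'
#' Cellwise sum of individual posteriors, renormalised to sum 1 (equivalent
#' to the normalised mean).
#'
#' @param posteriors non-empty list of aligned posterior `grid_surface`s.
#' @return a `grid_surface` summing to 1.
#' @export
population_surface <- function(posteriors) {
  if (length(posteriors) == 0L) stop("empty posterior list")
  for (p in posteriors[-1]) stop_if_misaligned(posteriors[[1]], p)
  acc <- Reduce(`+`, lapply(posteriors, function(p) {
    v <- p$values; v[is.na(v)] <- 0; v
  }))
  out <- posteriors[[1]]
  out$values <- acc
  normalize_surface(out)
}

#' Percentage overlap of two likely regions
#'
#' `100 * |A intersect B| / |reference region|` in cells; directional, with
#' the denominator chosen by `reference`.
#'
#' @param region_a,region_b aligned logical `grid_surface`s.
#' @param reference which region supplies the denominator: `"a"` or `"b"`.
#' @return percentage in `[0, 100]`.
#' @export
region_overlap <- function(region_a, region_b, reference = c("a", "b")) {
  reference <- match.arg(reference)
  stop_if_misaligned(region_a, region_b)
  a <- region_a$values & !is.na(region_a$values)
  b <- region_b$values & !is.na(region_b$values)
  ref <- if (reference == "a") a else b
  if (!any(ref)) stop("empty reference region")
  100 * sum(a & b) / sum(ref)
}
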