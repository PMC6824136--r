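#' Geolocator fix tables
#'
#' Geolocator positions are handled as a plain data.frame of *fixes* with
#' columns `individual_id`, `species`, `winter`, `date` (class `Date`),
#' `lon`, `lat`. One individual's time-ordered rows form a track; most
#' functions accept a table holding many individuals and operate per
#' individual. `as_fixes()` validates and coerces such a table.
#'
#' @param df a data.frame with the columns above (`date` coercible via
#'   `as.Date`).
#' @return a validated fixes data.frame, ordered by individual then date.
#' @export
as_fixes <- function(df) {
  need <- c("individual_id", "species", "winter", "date", "lon", "lat")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("fix table is missing columns: ", paste(missing, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  df$lon <- as.numeric(df$lon)
  df$lat <- as.numeric(df$lat)
  if (any(df$lon < -180 | df$lon > 180, na.rm = TRUE) ||
      any(df$lat < -90 | df$lat > 90, na.rm = TRUE)) {
    stop("fix coordinates outside [-180, 180] x [-90, 90]")
  }
  df <- df[order(df$individual_id, df$date), , drop = FALSE]
  for (id in unique(df$individual_id)) {
    d <- df$date[df$individual_id == id]
    if (anyDuplicated(d)) stop("duplicate fix dates for individual ", id)
  }
  rownames(df) <- NULL
  df
}

#' Read geolocator fixes from CSV
#'
#' Expects columns `individual_id, species, winter, date, lon, lat` with
#' ISO 8601 dates.
#'
#' @param path CSV file path.
#' @return a fixes data.frame (see [as_fixes()]).
#' @export
read_tracks_csv <- function(path) {
  as_fixes(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Default equinox exclusion windows
#'
#' Light-level latitude estimates are unreliable around the equinoxes; fixes
#' in the windows 10 Sep--18 Oct and 20 Feb--2 Apr (year-agnostic) are
#' removed by default.
#'
#' @return a list of windows, each `list(start = c(month, day),
#'   end = c(month, day))`.
#' @export
equinox_windows <- function() {
  list(list(start = c(9L, 10L), end = c(10L, 18L)),
       list(start = c(2L, 20L), end = c(4L, 2L)))
}

# month/day pair -> sortable code; windows may wrap the year end
.md_code <- function(m, d) m * 100L + d

.in_md_window <- function(dates, window) {
  md <- .md_code(as.integer(format(dates, "%m")), as.integer(format(dates, "%d")))
  s <- .md_code(window$start[1], window$start[2])
  e <- .md_code(window$end[1], window$end[2])
  if (s <= e) md >= s & md <= e else md >= s | md <= e
}

#' Remove fixes falling in equinox windows
#'
#' Drops every fix whose calendar month/day falls inside any of the given
#' year-agnostic windows (inclusive at both ends); windows spanning the year
#' end (e.g. Dec--Mar) are supported. Order is preserved.
#'
#' @param fixes a fixes data.frame.
#' @param windows list of windows as returned by [equinox_windows()].
#' @return the filtered fixes data.frame.
#' @export
filter_equinox <- function(fixes, windows = equinox_windows()) {
  if (nrow(fixes) == 0L || length(windows) == 0L) return(fixes)
  drop <- Reduce(`|`, lapply(windows, function(w) .in_md_window(fixes$date, w)))
  out <- fixes[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Great-circle distance (haversine)
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorised).
#' @param radius_km sphere radius; default 6371 km.
#' @return distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Remove fixes implying unrealistic travel speeds
#'
#' Automated stand-in for manual screening of implausible geolocator
#' positions: a forward scan per individual that keeps the first fix and
#' drops any fix whose great-circle speed from the previously *retained*
#' fix exceeds `max_kmday`. The filter is a contraction (output is a subset
#' of the input) and idempotent.
#'
#' @param fixes a fixes data.frame.
#' @param max_kmday maximum plausible speed in km/day; default 500.
#' @return the filtered fixes data.frame.
#' @export
filter_speed <- function(fixes, max_kmday = 500) {
  stopifnot(max_kmday > 0)
  if (nrow(fixes) <= 1L) return(fixes)
  keep <- logical(nrow(fixes))
  for (id in unique(fixes$individual_id)) {
    idx <- which(fixes$individual_id == id)
    last <- idx[1]
    keep[last] <- TRUE
    for (k in idx[-1]) {
      dt <- as.numeric(fixes$date[k] - fixes$date[last])
      dist <- haversine_km(fixes$lon[last], fixes$lat[last],
                           fixes$lon[k], fixes$lat[k])
      if (dist / dt <= max_kmday) {
        keep[k] <- TRUE
        last <- k
      }
    }
  }
  out <- fixes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Moult windows and study-region polygon
#'
#' `moult_window()` describes when a feather type is grown (calendar
#' months); `default_moult_windows()` returns the population-level timings
#' used for the two study species: body feathers Jul--Sep for both, cheek
#' feathers Jan--Mar (puffin) and Dec--Mar (razorbill).
#'
#' @param species species label.
#' @param feather_type `"body"` or `"cheek"`.
#' @param months integer vector of calendar months (1--12), non-empty.
#' @return a `moult_window` list.
#' @export
moult_window <- function(species, feather_type, months) {
  months <- as.integer(months)
  stopifnot(length(months) > 0, all(months >= 1L & months <= 12L),
            feather_type %in% c("body", "cheek"))
  structure(list(species = species, feather_type = feather_type,
                 months = sort(unique(months))),
            class = "moult_window")
}

#' @rdname moult_window
#' @export
default_moult_windows <- function() {
  list(
    puffin_body     = moult_window("puffin", "body", 7:9),
    puffin_cheek    = moult_window("puffin", "cheek", 1:3),
    razorbill_body  = moult_window("razorbill", "body", 7:9),
    razorbill_cheek = moult_window("razorbill", "cheek", c(12L, 1L, 2L, 3L))
  )
}

#' @description `north_sea_polygon()` is the default study-region polygon:
#' a configurable bounding box lon `[-4, 10]` degE, lat `[51, 62]` degN.
#' @param lon_min,lon_max,lat_min,lat_max bounding box, degrees.
#' @rdname moult_window
#' @export
north_sea_polygon <- function(lon_min = -4, lon_max = 10,
                              lat_min = 51, lat_max = 62) {
  cbind(lon = c(lon_min, lon_max, lon_max, lon_min, lon_min),
        lat = c(lat_min, lat_min, lat_max, lat_max, lat_min))
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param lon,lat point coordinates (vectorised).
#' @param poly two-column matrix of polygon vertices (closed or open ring).
#' @return logical vector; points on an edge count as inside.
#' @export
point_in_polygon <- function(lon, lat, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  if (px[1] == px[n] && py[1] == py[n]) { px <- px[-n]; py <- py[-n]; n <- n - 1 }
  inside <- logical(length(lon))
  for (k in seq_along(lon)) {
    x <- lon[k]; y <- lat[k]
    ins <- FALSE
    j <- n
    for (i in seq_len(n)) {
      on_edge <- FALSE
      # edge endpoints
      xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
      # boundary counts as inside
      if (abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi)) < 1e-12 &&
          min(xi, xj) - 1e-12 <= x && x <= max(xi, xj) + 1e-12 &&
          min(yi, yj) - 1e-12 <= y && y <= max(yi, yj) + 1e-12) on_edge <- TRUE
      if (on_edge) { ins <- TRUE; break }
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) ins <- !ins
      j <- i
    }
    inside[k] <- ins
  }
  inside
}

#' Did an individual stay in the study region through a moult window?
#'
#' For each individual in `fixes`, tests whether *every* fix dated in the
#' window's months lies inside the region polygon. Fixes over land are
#' retained (coastal species bias correction). Individuals with no fixes in
#' the window months get `NA` ("indeterminate").
#'
#' @param fixes a fixes data.frame.
#' @param window a [moult_window()].
#' @param region polygon matrix as from [north_sea_polygon()].
#' @return named logical vector, one element per individual
#'   (`TRUE` / `FALSE` / `NA`).
#' @export
moult_residency <- function(fixes, window, region = north_sea_polygon()) {
  if (nrow(fixes) == 0L) stop("empty fix table")
  months <- as.integer(format(fixes$date, "%m"))
  ids <- unique(fixes$individual_id)
  out <- stats::setNames(rep(NA, length(ids)), ids)
  for (id in ids) {
    sel <- fixes$individual_id == id & months %in% window$months
    if (!any(sel)) next
    out[id] <- all(point_in_polygon(fixes$lon[sel], fixes$lat[sel], region))
  }
  out
}

#' Normal-reference bandwidth (1.06 rule)
#'
#' The normal-reference rule-of-thumb bandwidth
#' `1.06 * min(sd, IQR / 1.34) * n^(-1/5)`, computed per coordinate axis and
#' typically averaged across axes and individuals of a population.
#'
#' @param values numeric vector with at least two distinct values.
#' @return a strictly positive bandwidth (same units as `values`).
#' @export
nrd_bandwidth <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  spread <- min(stats::sd(values), stats::IQR(values) / 1.34)
  if (spread <= 0) stop("degenerate spread: values have no usable variability")
  1.06 * spread * n^(-1 / 5)
}

#' Gaussian kernel density surface of pooled fixes
#'
#' Evaluates an isotropic bivariate Gaussian kernel density estimate of the
#' pooled fix locations at every cell centre of `grid` (degrees; product
#' kernel with one bandwidth shared by both axes). The surface has units of
#' density per square degree and integrates to ~1 over a grid that covers
#' the support.
#'
#' @param fixes a fixes data.frame (pooled individuals of one
#'   population/winter).
#' @param bandwidth kernel standard deviation in degrees; default 0.4.
#' @param grid a `grid_surface` (template; values ignored) or [grid_spec()]
#'   output.
#' @return a `grid_surface` density.
#' @export
kde_surface <- function(fixes, bandwidth = 0.4, grid = grid_spec()) {
  if (nrow(fixes) == 0L) stop("empty population: no fixes to estimate from")
  stopifnot(bandwidth > 0)
  lons <- grid_lons(grid)
  lats <- grid_lats(grid)
  h2 <- bandwidth^2
  # sum over fixes of outer(gauss_lat, gauss_lon) as one matrix product
  elat <- exp(-outer(lats, fixes$lat, `-`)^2 / (2 * h2))   # nrow x nfix
  elon <- exp(-outer(fixes$lon, lons, `-`)^2 / (2 * h2))   # nfix x ncol
  dens <- (elat %*% elon) / (nrow(fixes) * 2 * pi * h2)
  grid_surface(dens, grid$lon_min, grid$lat_min, grid$resolution)
}
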