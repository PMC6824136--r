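#' Regular longitude/latitude grid surface
#'
#' `grid_surface` is the basic raster container used throughout the package:
#' a regular lon/lat grid (cell centres, EPSG:4326 degrees) holding one
#' scalar field -- a kernel density, an isotope mean, a probability, or a
#' logical mask. Row 1 of `values` is the **southernmost** row; column 1 the
#' westernmost column. `lon_min`/`lat_min` give the outer (south-west) edge
#' of the south-west cell, so the centre of cell `[i, j]` is at
#' `lon_min + (j - 0.5) * resolution`, `lat_min + (i - 0.5) * resolution`.
#'
#' @param values numeric (or logical) matrix, rows south-to-north.
#' @param lon_min,lat_min south-west corner of the grid extent, degrees.
#' @param resolution cell size in degrees (same for both axes); default 0.1.
#' @param nodata value marking missing cells (stored as `NA` internally).
#' @return an object of class `grid_surface`.
#' @examples
#' g <- grid_surface(matrix(runif(12), 3, 4), lon_min = -4, lat_min = 51)
#' dim(g$values)
#' @export
grid_surface <- function(values, lon_min, lat_min, resolution = 0.1,
                         nodata = NA_real_) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0,
            is.numeric(lon_min), is.numeric(lat_min))
  if (!is.na(nodata) && is.numeric(values)) {
    values[values == nodata] <- NA_real_
  }
  structure(
    list(values = values, lon_min = lon_min, lat_min = lat_min,
         resolution = resolution),
    class = "grid_surface"
  )
}

#' Define an empty grid over an extent
#'
#' Convenience constructor for a zero-filled [grid_surface()] covering
#' `[lon_min, lon_max] x [lat_min, lat_max]` at `resolution` degrees.
#' The default extent is the North Sea study window used across the package.
#'
#' @param lon_min,lon_max,lat_min,lat_max extent in degrees.
#' @param resolution cell size in degrees.
#' @return a `grid_surface` of zeros.
#' @export
grid_spec <- function(lon_min = -4, lon_max = 10, lat_min = 51, lat_max = 62,
                      resolution = 0.1) {
  ncol <- round((lon_max - lon_min) / resolution)
  nrow <- round((lat_max - lat_min) / resolution)
  stopifnot(ncol >= 1, nrow >= 1)
  grid_surface(matrix(0, nrow, ncol), lon_min, lat_min, resolution)
}

#' @export
print.grid_surface <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<grid_surface> %d x %d cells @ %g deg, lon [%g, %g], lat [%g, %g]\n",
    nrow(v), ncol(v), x$resolution,
    x$lon_min, x$lon_min + ncol(v) * x$resolution,
    x$lat_min, x$lat_min + nrow(v) * x$resolution))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: [%g, %g], %d NA cells\n",
                min(fin), max(fin), sum(is.na(v))))
  }
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param g a `grid_surface`.
#' @return numeric vector of cell-centre longitudes (west to east) or
#'   latitudes (south to north).
#' @export
grid_lons <- function(g) g$lon_min + (seq_len(ncol(g$values)) - 0.5) * g$resolution

#' @rdname grid_lons
#' @export
grid_lats <- function(g) g$lat_min + (seq_len(nrow(g$values)) - 0.5) * g$resolution

#' Test whether two grids share extent and resolution
#'
#' @param a,b `grid_surface` objects.
#' @return logical.
#' @export
grids_aligned <- function(a, b) {
  isTRUE(all.equal(a$resolution, b$resolution)) &&
    isTRUE(all.equal(a$lon_min, b$lon_min)) &&
    isTRUE(all.equal(a$lat_min, b$lat_min)) &&
    all(dim(a$values) == dim(b$values))
}

stop_if_misaligned <- function(a, b) {
  if (!grids_aligned(a, b)) stop("grids are not aligned (extent/resolution mismatch)")
  invisible(TRUE)
}

#' Value of the cell containing a point
#'
#' Nearest-cell lookup: returns the value of the grid cell whose extent
#' contains each `(lon, lat)` point, or `NA` for points off the grid.
#'
#' @param g a `grid_surface`.
#' @param lon,lat point coordinates (vectorised).
#' @return numeric vector of cell values.
#' @export
grid_value_at <- function(g, lon, lat) {
  j <- floor((lon - g$lon_min) / g$resolution) + 1L
  i <- floor((lat - g$lat_min) / g$resolution) + 1L
  ok <- i >= 1L & i <= nrow(g$values) & j >= 1L & j <= ncol(g$values)
  out <- rep(NA_real_, length(lon))
  out[ok] <- g$values[cbind(i[ok], j[ok])]
  out
}

#' Min-max rescale a surface to [0, 1]
#'
#' Rescales so that the minimum maps to 0 and the maximum to 1, the form in
#' which utilisation surfaces from different winters are compared.
#'
#' @param s a `grid_surface` with non-constant values.
#' @return a `grid_surface` on `[0, 1]`.
#' @export
scale_surface <- function(s) {
  v <- s$values
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
    stop("degenerate scaling: surface is constant")
  }
  s$values <- (v - rng[1]) / (rng[2] - rng[1])
  s
}

#' Between-year difference of two scaled utilisation surfaces
#'
#' Cellwise `s_late - s_early` of two surfaces already rescaled to
#' `[0, 1]`. Positive values mark cells used more in the later period,
#' negative values cells used more in the earlier period.
#'
#' @param s_late,s_early aligned `grid_surface` objects scaled to `[0, 1]`.
#' @return a `grid_surface` with values in `[-1, 1]`.
#' @export
difference_surface <- function(s_late, s_early) {
  stop_if_misaligned(s_late, s_early)
  s_late$values <- s_late$values - s_early$values
  s_late
}

#' Directional percentage overlap of supra-threshold regions
#'
#' Computes `100 * |A intersect R| / |R|` where `A = {s_a > threshold}` and
#' `R = {s_ref > threshold}`. The measure is *directional*: the denominator
#' is always the reference surface's region, so
#' `overlap_percent(a, b) != overlap_percent(b, a)` in general.
#'
#' @param s_a,s_ref aligned scaled `grid_surface` objects.
#' @param threshold scaled-density cut defining the predominant-use region;
#'   default 0.4.
#' @return overlap percentage in `[0, 100]`.
#' @export
overlap_percent <- function(s_a, s_ref, threshold = 0.4) {
  stop_if_misaligned(s_a, s_ref)
  a <- s_a$values > threshold & !is.na(s_a$values)
  r <- s_ref$values > threshold & !is.na(s_ref$values)
  if (!any(r)) stop("empty reference region: no reference cells above threshold")
  100 * sum(a & r) / sum(r)
}

# ---- plain-text grid I/O ----------------------------------------------------

#' Read / write the plain-text grid format
#'
#' Surfaces are stored as a small self-describing text file: a one-line
#' header `lon_min,lat_min,resolution,ncol,nrow` followed by the values
#' row-major, one grid row per line, southernmost row first. `NA` marks
#' nodata cells.
#'
#' @param g a `grid_surface`.
#' @param path file path.
#' @return `read_grid_csv` returns a `grid_surface`; `write_grid_csv`
#'   returns `path` invisibly.
#' @export
write_grid_csv <- function(g, path) {
  header <- paste(c("lon_min", "lat_min", "resolution", "ncol", "nrow"),
                  collapse = ",")
  meta <- paste(c(g$lon_min, g$lat_min, g$resolution,
                  ncol(g$values), nrow(g$values)), collapse = ",")
  rows <- apply(g$values, 1, function(r) paste(format(r, digits = 15), collapse = ","))
  writeLines(c(header, meta, rows), path)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  lines <- readLines(path)
  meta <- as.numeric(strsplit(lines[2], ",")[[1]])
  names(meta) <- strsplit(lines[1], ",")[[1]]
  vals <- t(vapply(lines[-(1:2)],
                   function(l) scan(text = l, sep = ",", quiet = TRUE,
                                    na.strings = c("NA", "NaN")),
                   numeric(meta[["ncol"]]), USE.NAMES = FALSE))
  stopifnot(nrow(vals) == meta[["nrow"]])
  grid_surface(vals, meta[["lon_min"]], meta[["lat_min"]], meta[["resolution"]])
}
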