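# Small in-code fixtures shared across test files.

make_fixes <- function(lon, lat, dates = NULL, id = "b1",
                       species = "puffin", winter = "2014/15") {
  n <- length(lon)
  if (is.null(dates)) dates <- as.Date("2014-11-01") + seq_len(n) - 1
  as_fixes(data.frame(individual_id = id, species = species, winter = winter,
                      date = dates, lon = lon, lat = lat,
                      stringsAsFactors = FALSE))
}

# linear-gradient toy isoscape on a small grid (no noise, fully predictable)
toy_isoscape <- function(lon_min = 0, lat_min = 54, n = 20, resolution = 0.2,
                         c0 = -17, cg = c(-0.2, 0.3), n0 = 10, ng = c(-0.5, 0.2)) {
  g <- grid_surface(matrix(0, n, n), lon_min, lat_min, resolution)
  lats <- grid_lats(g); lons <- grid_lons(g)
  latm <- matrix(lats, n, n); lonm <- matrix(lons, n, n, byrow = TRUE)
  mk <- function(b, gr) grid_surface(b + gr[1] * (latm - mean(lats)) +
                                       gr[2] * (lonm - mean(lons)),
                                     lon_min, lat_min, resolution)
  isoscape(mk(c0, cg), mk(n0, ng))
}

all_true_mask <- function(g) {
  m <- g
  m$values <- matrix(TRUE, nrow(g$values), ncol(g$values))
  m
}
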