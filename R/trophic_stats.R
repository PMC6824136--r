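#' Yates-corrected chi-squared test for a 2x2 table
#'
#' Continuity-corrected chi-squared statistic
#' `n * (max(|ad - bc| - n/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))` with a p-value
#' from the chi-squared distribution on 1 df. Used here to compare counts
#' of individuals leaving vs staying in the study region between winters.
#' The correction is always applied for 2x2 tables.
#'
#' @param tab 2x2 matrix of non-negative counts (rows = groups/winters,
#'   columns = outcome), or a length-4 vector `c(a, b, c, d)` read row-wise.
#' @return list with `test`, `statistic`, `p_value`, `n`.
#' @export
yates_chisq <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  if (n <= 0) stop("empty table")
  marg <- c(a + b, cc + d, a + cc, b + d)
  if (any(marg == 0)) stop("degenerate margin: a row or column total is zero")
  stat <- n * max(abs(a * d - b * cc) - n / 2, 0)^2 / prod(marg)
  list(test = "yates_chisq", statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE), n = n)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The statistic `W` is the number of
#' `(x, y)` pairs with `x > y` counting ties as 1/2 (equivalently the rank
#' sum of `x` in the pooled mid-ranked sample minus `n_x (n_x + 1) / 2`),
#' so `W(x, y) + W(y, x) = n_x * n_y`. For pooled sizes up to `exact_max`
#' the two-sided p-value is exact, by enumeration of all labelings of the
#' pooled (mid-ranked) values; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @param exact_max largest pooled size for exact enumeration; default 12.
#' @return list with `test`, `W`, `p_value`, `method`, `n`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))   # mid-ranks for ties
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (n <= exact_max) {
    sets <- utils::combn(n, nx)
    rsum <- colSums(matrix(r[sets], nrow = nx))
    Us <- rsum - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
    z <- (abs(U - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal_approx"
  }
  list(test = "mann_whitney_u", W = U, p_value = p, method = method,
       n = c(nx = nx, ny = ny))
}

#' Predator-prey isotopic spacing within a foraging region
#'
#' Compares population-average feather isotope values with the mean prey
#' isoscape values over the likely foraging region. The delta-15N
#' difference is compared with the expected one-step trophic enrichment
#' (`trophic_step`, default 3.5 permil): a difference within
#' `trophic_step +/- window` flags the prey as a plausible direct diet
#' component.
#'
#' @param feather_means list with `d13C` and `d15N`: population-average
#'   feather values (permil).
#' @param prey_iso prey [isoscape()].
#' @param region logical `grid_surface`: likely foraging region.
#' @param trophic_step expected per-trophic-step delta-15N enrichment;
#'   default 3.5 permil.
#' @param window half-width of the "consistent with direct consumption"
#'   band; default 1.0 permil.
#' @return a `spacing_result` list with feather means, regional prey means,
#'   feather-minus-prey differences and the consistency flag.
#' @export
isotopic_spacing <- function(feather_means, prey_iso, region,
                             trophic_step = 3.5, window = 1.0) {
  vals <- extract_values(prey_iso, region)
  prey <- list(d13C = mean(vals$d13C), d15N = mean(vals$d15N))
  diffs <- list(d13C = feather_means$d13C - prey$d13C,
                d15N = feather_means$d15N - prey$d15N)
  structure(list(
    feather_mean = feather_means,
    prey_mean = prey,
    difference = diffs,
    trophic_step = trophic_step,
    consistent_with_diet = abs(diffs$d15N - trophic_step) <= window
  ), class = "spacing_result")
}

#' @export
print.spacing_result <- function(x, ...) {
  cat(sprintf("<spacing_result> d13C diff %.2f, d15N diff %.2f permil (step %.1f): %s\n",
              x$difference$d13C, x$difference$d15N, x$trophic_step,
              if (x$consistent_with_diet) "consistent with direct consumption"
              else "not consistent with direct consumption"))
  invisible(x)
}

#' Decode an ICES statistical rectangle code
#'
#' ICES rectangles are 30 minutes of latitude by 1 degree of longitude.
#' Rows `01`--`99` start at 36 degN (row 01 = 36--36.5 degN); columns are a
#' letter-digit pair running east from 44 degW (`A0`; `A` holds only
#' digits 0--3, `B0` = 40 degW, letter `I` is skipped).
#'
#' @param code rectangle code(s), e.g. `"38E9"`.
#' @return data.frame with `lon_min`, `lon_max`, `lat_min`, `lat_max`
#'   (degrees), one row per code.
#' @export
ices_rectangle_extent <- function(code) {
  code <- toupper(as.character(code))
  ok <- grepl("^[0-9]{2}[A-HJ-M][0-9]$", code)
  if (!all(ok)) {
    stop("malformed ICES rectangle code: ", paste(code[!ok], collapse = ", "))
  }
  row <- as.integer(substr(code, 1, 2))
  letter <- substr(code, 3, 3)
  digit <- as.integer(substr(code, 4, 4))
  if (any(row < 1)) stop("malformed ICES rectangle code: row 00")
  letters_seq <- c("A", "B", "C", "D", "E", "F", "G", "H", "J", "K", "L", "M")
  li <- match(letter, letters_seq)
  if (any(letter == "A" & digit > 3)) {
    stop("malformed ICES rectangle code: column A holds digits 0-3 only")
  }
  lon_min <- ifelse(letter == "A", -44 + digit, -40 + (li - 2) * 10 + digit)
  lat_min <- 36 + (row - 1) * 0.5
  data.frame(lon_min = lon_min, lon_max = lon_min + 1,
             lat_min = lat_min, lat_max = lat_min + 0.5)
}

#' Read CPUE records from CSV
#'
#' Expects columns `ices_rectangle, species, year, quarter, cpue_per_hr`.
#'
#' @param path CSV file path.
#' @return a data.frame of CPUE records.
#' @export
read_cpue_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ices_rectangle", "cpue_per_hr")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("CPUE table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(df$cpue_per_hr < 0)) stop("negative CPUE value")
  df
}

#' Grid CPUE records as log10(mean CPUE/hr + 1)
#'
#' Averages catch-per-unit-effort per ICES rectangle (records for one
#' species and period), transforms the per-rectangle mean as
#' `log10(mean + 1)` and paints each rectangle's cells with that value.
#' Rectangles with no records are nodata (`NA`), not zero.
#'
#' @param records CPUE data.frame with `ices_rectangle`, `cpue_per_hr`.
#' @param resolution output cell size in degrees; default 0.5 (the
#'   rectangle latitude height; must divide 0.5 and 1 evenly to tile
#'   rectangles exactly, e.g. 0.5, 0.25, 0.1).
#' @param grid optional `grid_surface` template; defaults to the bounding
#'   box of the supplied rectangles.
#' @return a `grid_surface` with nodata outside sampled rectangles.
#' @export
cpue_grid <- function(records, resolution = 0.5, grid = NULL) {
  if (nrow(records) == 0L) stop("no CPUE records")
  ext <- ices_rectangle_extent(records$ices_rectangle)
  means <- tapply(records$cpue_per_hr, records$ices_rectangle, mean)
  vals <- log10(means + 1)
  if (is.null(grid)) {
    grid <- grid_spec(min(ext$lon_min), max(ext$lon_max),
                      min(ext$lat_min), max(ext$lat_max), resolution)
  }
  out <- grid
  out$values[] <- NA_real_
  lons <- grid_lons(grid); lats <- grid_lats(grid)
  uext <- ices_rectangle_extent(names(vals))
  for (k in seq_along(vals)) {
    jj <- which(lons > uext$lon_min[k] & lons < uext$lon_max[k])
    ii <- which(lats > uext$lat_min[k] & lats < uext$lat_max[k])
    out$values[ii, jj] <- vals[[k]]
  }
  out
}

#' Prey size filters applied upstream of CPUE records
#'
#' Maximum body lengths (mm) defining prey "small enough to be eaten":
#' herring < 160, sprat < 80, sandeel < 120. Applied when building CPUE
#' record tables from survey data (the download/parsing itself is out of
#' scope here).
#'
#' @return named numeric vector of maximum lengths in mm.
#' @export
prey_size_limits_mm <- function() {
  c(herring = 160, sprat = 80, sandeel = 120)
}
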