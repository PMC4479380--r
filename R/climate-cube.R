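#' Monthly gridded weather series
#'
#' A `climate_cube` holds a contiguous monthly time series of gridded weather:
#' per-cell monthly precipitation totals (mm) and minimum / maximum / mean
#' temperature (deg C) on a regular rectangular grid. It is the raw predictor
#' source for all covariate derivation.
#'
#' Cells are indexed `(row, col)`; planar coordinates are kilometres with the
#' grid origin at the south-west corner, so cell `(r, c)` is centred at
#' `((c - 0.5) * s, (r - 0.5) * s)` where `s = sqrt(cell_km2)`.
#'
#' @param precip,tmin,tmax numeric arrays with dim `c(n_months, rows, cols)`.
#' @param tmean optional array of monthly mean temperature; defaults to
#'   `(tmin + tmax) / 2`.
#' @param start_year,start_month calendar stamp of the first time slice.
#' @param cell_km2 area of one grid cell in square kilometres.
#' @param mask optional logical matrix `rows x cols`, `TRUE` for cells carrying
#'   data; `FALSE` cells are treated as missing everywhere downstream.
#' @return an object of class `climate_cube`.
#' @export
climate_cube <- function(precip, tmin, tmax, tmean = NULL,
                         start_year, start_month = 1, cell_km2 = 25,
                         mask = NULL) {
  d <- dim(precip)
  if (length(d) != 3L)
    stop("weather arrays must have dim c(n_months, rows, cols)")
  for (a in list(tmin, tmax)) {
    if (!identical(dim(a), d)) stop("weather arrays must share dimensions")
  }
  if (is.null(tmean)) tmean <- (tmin + tmax) / 2
  if (!identical(dim(tmean), d)) stop("weather arrays must share dimensions")
  if (any(precip < 0, na.rm = TRUE)) stop("precip must be non-negative")
  if (any(tmin > tmean + 1e-9, na.rm = TRUE) ||
      any(tmean > tmax + 1e-9, na.rm = TRUE))
    stop("need tmin <= tmean <= tmax cellwise")
  if (is.null(mask)) mask <- matrix(TRUE, d[2L], d[3L])
  structure(
    list(precip = precip, tmin = tmin, tmax = tmax, tmean = tmean,
         start_year = as.integer(start_year),
         start_month = as.integer(start_month),
         cell_km2 = cell_km2, mask = mask),
    class = "climate_cube")
}

#' @export
print.climate_cube <- function(x, ...) {
  d <- dim(x$precip)
  last <- cube_month_at(x, d[1L])
  cat(sprintf(
    "climate_cube: %d months (%d-%02d .. %d-%02d), %d x %d grid, %.1f km2 cells\n",
    d[1L], x$start_year, x$start_month, last[1L], last[2L], d[2L], d[3L],
    x$cell_km2))
  invisible(x)
}

n_months <- function(cube) dim(cube$precip)[1L]
grid_dim <- function(cube) dim(cube$precip)[2:3]
cell_size_km <- function(cube) sqrt(cube$cell_km2)

#' Position of a calendar month on a cube's time axis
#'
#' @param cube a [climate_cube()].
#' @param year,month calendar month to locate.
#' @return 1-based index on the time axis.
#' @export
month_index <- function(cube, year, month) {
  idx <- (year - cube$start_year) * 12L + (month - cube$start_month) + 1L
  if (any(idx < 1L | idx > n_months(cube)))
    stop("month ", paste(year, month, sep = "-"), " outside cube time axis")
  idx
}

## (year, month) at time-axis position i (vectorised)
cube_month_at <- function(cube, i) {
  k <- (cube$start_year * 12L + cube$start_month - 1L) + (i - 1L)
  cbind(year = k %/% 12L, month = k %% 12L + 1L)
}

#' All calendar months covered by a cube
#' @param cube a [climate_cube()].
#' @return data.frame with columns `year`, `month`.
#' @export
cube_months <- function(cube) {
  as.data.frame(cube_month_at(cube, seq_len(n_months(cube))))
}

#' Monthly series of one cell, as a list of the four weather variables
#' @param cube a [climate_cube()].
#' @param row,col cell indices.
#' @return list of vectors `precip`, `tmin`, `tmax`, `tmean`.
#' @export
cell_series <- function(cube, row, col) {
  list(precip = cube$precip[, row, col], tmin = cube$tmin[, row, col],
       tmax = cube$tmax[, row, col], tmean = cube$tmean[, row, col])
}

#' Grid cell containing planar coordinates
#'
#' @param cube a [climate_cube()].
#' @param x,y planar coordinates in km (grid origin at the south-west corner).
#' @return integer matrix with columns `row`, `col`.
#' @export
cell_of_xy <- function(cube, x, y) {
  s <- cell_size_km(cube)
  d <- grid_dim(cube)
  row <- pmin(pmax(ceiling(y / s), 1L), d[1L])
  col <- pmin(pmax(ceiling(x / s), 1L), d[2L])
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Planar centre coordinates of grid cells
#' @param cube a [climate_cube()].
#' @param row,col cell indices (vectorised).
#' @return matrix with columns `x`, `y` in km.
#' @export
cell_center <- function(cube, row, col) {
  s <- cell_size_km(cube)
  cbind(x = (col - 0.5) * s, y = (row - 0.5) * s)
}

#' Write / read a climate cube as long-format CSV
#'
#' Plain-text interchange format: one line per cell-month with columns
#' `year, month, row, col, precip, tmin, tmax, tmean`.
#'
#' @param cube a [climate_cube()].
#' @param path file path.
#' @export
write_cube_csv <- function(cube, path) {
  d <- dim(cube$precip)
  ym <- cube_month_at(cube, seq_len(d[1L]))
  grid <- expand.grid(t = seq_len(d[1L]), row = seq_len(d[2L]),
                      col = seq_len(d[3L]))
  out <- data.frame(
    year = ym[grid$t, 1L], month = ym[grid$t, 2L],
    row = grid$row, col = grid$col,
    precip = cube$precip[as.matrix(grid)],
    tmin = cube$tmin[as.matrix(grid)],
    tmax = cube$tmax[as.matrix(grid)],
    tmean = cube$tmean[as.matrix(grid)])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cube_csv
#' @param cell_km2 cell area recorded in the rebuilt cube.
#' @export
read_cube_csv <- function(path, cell_km2 = 25) {
  df <- utils::read.csv(path)
  rows <- max(df$row); cols <- max(df$col)
  t0 <- min(df$year * 12L + df$month)
  t <- df$year * 12L + df$month - t0 + 1L
  nt <- max(t)
  mk <- function(v) {
    a <- array(NA_real_, c(nt, rows, cols))
    a[cbind(t, df$row, df$col)] <- v
    a
  }
  climate_cube(mk(df$precip), mk(df$tmin), mk(df$tmax), mk(df$tmean),
               start_year = (t0 - 1L) %/% 12L,
               start_month = (t0 - 1L) %% 12L + 1L,
               cell_km2 = cell_km2)
}
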