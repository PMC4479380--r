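## Eight bioclimatic covariates from monthly weather series, over trailing
## 12/36-month windows or a 30-year climatology.

#' Names of the eight climatic covariates
#'
#' Four precipitation variables (annual precipitation, precipitation of the
#' wettest and driest quarter, precipitation seasonality as a coefficient of
#' variation) and four temperature variables (annual mean temperature, maximum
#' temperature of the warmest month, minimum temperature of the coldest month,
#' temperature seasonality as a coefficient of variation).
#'
#' @return character vector of length 8.
#' @export
bioclim_names <- function() {
  c("ann_prec", "prec_wet_q", "prec_dry_q", "prec_cv",
    "ann_tmean", "tmax_warm_m", "tmin_cold_m", "temp_cv")
}

#' Derive the eight climatic covariates from a monthly window
#'
#' Quarters are every run of 3 consecutive months inside the window (no
#' wrap-around); `ann_prec` is annualised by `12 / length` so 12- and 36-month
#' windows share units. Seasonality is the sample (n-1) coefficient of
#' variation, computed on mm for precipitation and on kelvin for temperature;
#' a zero-mean precipitation series has seasonality 0 by convention. The
#' conventional bioclim "+1 mm" offset to the mean is not applied.
#'
#' @param precip,tmin,tmax,tmean numeric monthly series of equal length 12 or
#'   36 (mm totals and deg C).
#' @return named numeric vector of length 8 (see [bioclim_names()]).
#' @export
bioclim_vars <- function(precip, tmin, tmax, tmean = NULL) {
  L <- length(precip)
  if (!L %in% c(12L, 36L)) stop("window length must be 12 or 36 months")
  if (is.null(tmean)) tmean <- (tmin + tmax) / 2
  if (length(tmin) != L || length(tmax) != L || length(tmean) != L)
    stop("weather series must have equal length")
  q3 <- precip[1:(L - 2)] + precip[2:(L - 1)] + precip[3:L]
  pm <- mean(precip)
  tk <- tmean + 273.15
  c(ann_prec    = sum(precip) * 12 / L,
    prec_wet_q  = max(q3),
    prec_dry_q  = min(q3),
    prec_cv     = if (pm > 0) 100 * stats::sd(precip) / pm else 0,
    ann_tmean   = mean(tmean),
    tmax_warm_m = max(tmax),
    tmin_cold_m = min(tmin),
    temp_cv     = 100 * stats::sd(tk) / mean(tk))
}

#' Extract the trailing window preceding a month
#'
#' Returns the `length` consecutive months strictly preceding `end_exclusive`;
#' a window reaching before the cube's start is an error (callers must not
#' silently truncate).
#'
#' @param cube a [climate_cube()].
#' @param cell integer `c(row, col)`.
#' @param end_exclusive integer `c(year, month)`; the window ends with the
#'   month before this one.
#' @param length window length in months (12 or 36).
#' @return list of `precip`, `tmin`, `tmax`, `tmean` vectors, plus `months`
#'   (data.frame of the calendar months covered).
#' @export
extract_window <- function(cube, cell, end_exclusive, length = 12L) {
  if (!length %in% c(12L, 36L)) stop("window length must be 12 or 36 months")
  ## allow end_exclusive == month after the cube's last slice
  idx_end <- (end_exclusive[1L] - cube$start_year) * 12L +
    (end_exclusive[2L] - cube$start_month)       # index of last window month
  if (idx_end > n_months(cube))
    stop("window end outside cube time axis")
  idx0 <- idx_end - length + 1L
  if (idx0 < 1L)
    stop(sprintf("window of %d months before %d-%02d extends before cube start",
                 length, end_exclusive[1L], end_exclusive[2L]))
  sel <- idx0:idx_end
  list(precip = cube$precip[sel, cell[1L], cell[2L]],
       tmin   = cube$tmin[sel, cell[1L], cell[2L]],
       tmax   = cube$tmax[sel, cell[1L], cell[2L]],
       tmean  = cube$tmean[sel, cell[1L], cell[2L]],
       months = as.data.frame(cube_month_at(cube, sel)))
}

#' Long-term climatology covariates for one cell
#'
#' Averages each calendar month over the baseline years (the 12-value mean
#' monthly climatology) and applies [bioclim_vars()] to the result, as used
#' for a 30-year climate-mean model.
#'
#' @param cube a [climate_cube()].
#' @param cell integer `c(row, col)`.
#' @param baseline integer `c(start_year, end_year)`, inclusive; every month
#'   of every baseline year must be inside the cube.
#' @return named numeric vector of length 8.
#' @export
climatology_vars <- function(cube, cell, baseline) {
  years <- baseline[1L]:baseline[2L]
  idx <- month_index(cube, rep(years, each = 12L), rep(1:12, length(years)))
  avg <- function(a) {
    v <- matrix(a[idx, cell[1L], cell[2L]], nrow = 12L)  # months x years
    rowMeans(v)
  }
  bioclim_vars(avg(cube$precip), avg(cube$tmin), avg(cube$tmax),
               avg(cube$tmean))
}

#' Covariate surface for one window over all cells
#'
#' Applies [bioclim_vars()] cellwise for the trailing window ending
#' immediately before `end_exclusive`. Masked cells propagate as `NA`.
#'
#' @inheritParams extract_window
#' @return numeric array `rows x cols x 8`, third dimension named as
#'   [bioclim_names()].
#' @export
covariate_surface <- function(cube, end_exclusive, length = 12L) {
  d <- grid_dim(cube)
  out <- array(NA_real_, c(d[1L], d[2L], 8L),
               dimnames = list(NULL, NULL, bioclim_names()))
  for (r in seq_len(d[1L])) for (c in seq_len(d[2L])) {
    if (!cube$mask[r, c]) next
    w <- extract_window(cube, c(r, c), end_exclusive, length)
    out[r, c, ] <- bioclim_vars(w$precip, w$tmin, w$tmax, w$tmean)
  }
  out
}

## rolling max/min over k consecutive values; result[i] covers x[i-k+1..i],
## defined for i >= k (leading i < k are dropped)
roll_extreme <- function(x, k, max = TRUE) {
  e <- stats::embed(x, k)
  do.call(if (max) pmax else pmin, as.data.frame(e))
}

#' Trailing-window covariates for every cell and month at once
#'
#' Vectorised equivalent of looping [covariate_surface()] over the cube's
#' months: for each cell-month `t` with `t > length`, the eight covariates of
#' the window ending at month `t - 1`. Cellwise equality with the scalar path
#' is part of the test contract.
#'
#' @param cube a [climate_cube()].
#' @param length window length in months (12 or 36).
#' @return array `n_months x rows x cols x 8`; time rows `1..length` are `NA`
#'   (their windows precede the cube), masked cells are `NA` throughout.
#' @export
covariate_stack <- function(cube, length = 12L) {
  if (!length %in% c(12L, 36L)) stop("window length must be 12 or 36 months")
  L <- length
  d <- grid_dim(cube); nt <- n_months(cube)
  out <- array(NA_real_, c(nt, d[1L], d[2L], 8L),
               dimnames = list(NULL, NULL, NULL, bioclim_names()))
  if (nt < L + 1L) return(out)
  t_rec <- (L + 1L):nt                      # record months with a full window
  for (r in seq_len(d[1L])) for (c in seq_len(d[2L])) {
    if (!cube$mask[r, c]) next
    p <- cube$precip[, r, c]; tn <- cube$tmin[, r, c]
    tx <- cube$tmax[, r, c];  tm <- cube$tmean[, r, c]
    cs <- cumsum(p)
    lo <- t_rec - 1L - L                    # 0 for the first valid month
    wsum <- cs[t_rec - 1L] - ifelse(lo >= 1L, cs[pmax(lo, 1L)], 0)
    q3 <- p[1:(nt - 2)] + p[2:(nt - 1)] + p[3:nt]     # triple ending at t+2
    ## triples inside window ending t-1: ends in [t-L+2, t-1]
    wet <- roll_extreme(q3, L - 2L, max = TRUE)       # at triple-end >= L
    dry <- roll_extreme(q3, L - 2L, max = FALSE)
    ## wet/dry at index j corresponds to triple-end j + (L-2) - 1 + 2 = j+L-1
    ## i.e. window ending t-1 = j+L-1  =>  record month t = j + L
    sel <- t_rec - L
    pm <- wsum / L
    pss <- cumsum(p^2)
    wss <- pss[t_rec - 1L] - ifelse(lo >= 1L, pss[pmax(lo, 1L)], 0)
    pvar <- pmax((wss - wsum^2 / L) / (L - 1), 0)
    tk <- tm + 273.15
    tks  <- cumsum(tk);  tkss <- cumsum(tk^2); tms <- cumsum(tm)
    ksum <- tks[t_rec - 1L] - ifelse(lo >= 1L, tks[pmax(lo, 1L)], 0)
    kss  <- tkss[t_rec - 1L] - ifelse(lo >= 1L, tkss[pmax(lo, 1L)], 0)
    msum <- tms[t_rec - 1L] - ifelse(lo >= 1L, tms[pmax(lo, 1L)], 0)
    kvar <- pmax((kss - ksum^2 / L) / (L - 1), 0)
    txmax <- roll_extreme(tx, L, max = TRUE)   # at end >= L; window end t-1 => idx t-L
    tnmin <- roll_extreme(tn, L, max = FALSE)
    out[t_rec, r, c, "ann_prec"]    <- wsum * 12 / L
    out[t_rec, r, c, "prec_wet_q"]  <- wet[sel]
    out[t_rec, r, c, "prec_dry_q"]  <- dry[sel]
    out[t_rec, r, c, "prec_cv"]     <- ifelse(pm > 0, 100 * sqrt(pvar) / pm, 0)
    out[t_rec, r, c, "ann_tmean"]   <- msum / L
    out[t_rec, r, c, "tmax_warm_m"] <- txmax[sel]
    out[t_rec, r, c, "tmin_cold_m"] <- tnmin[sel]
    out[t_rec, r, c, "temp_cv"]     <- 100 * sqrt(kvar) / (ksum / L)
  }
  out
}
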