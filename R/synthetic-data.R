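## Synthetic island: weather history, ground-truth suitability, biased
## occurrence sampling and spotlight-style transect counts. Every downstream
## stage of the pipeline is testable against this generator's known truth.

## evaluate expr under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of the synthetic island study system
#'
#' Defaults reproduce the structure of the study system the pipeline targets:
#' a ~60-year monthly weather history on a rectangular island with a west-wet /
#' east-dry precipitation gradient and cool southern uplands, an imposed
#' three-year unfavourable excursion (2001-2003) in which coldest-month minima
#' are raised and wettest-quarter precipitation is inflated, and a count
#' suppression regime from 2004 in which transect-count expectations are held
#' low regardless of weather.
#'
#' @param grid_rows,grid_cols cell counts (each at least 10).
#' @param cell_area cell area in km^2 (25 = a 5-km grid).
#' @param years contiguous simulation years (span at least 20).
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param anomaly_window `c(start_year, end_year)` of the unfavourable
#'   excursion, or `NULL` for none.
#' @param anomaly_winter_warming deg C added to the coldest month's minimum
#'   temperature inside the excursion.
#' @param anomaly_wet_quarter_scale multiplier (>= 1) on wettest-quarter
#'   precipitation inside the excursion.
#' @param suppression_start_year first year of count suppression (`NULL` for
#'   none); from this year each transect's count expectation is held at
#'   `suppression_factor` times its pre-suppression baseline, regardless of
#'   suitability (abundance decouples from weather).
#' @param suppression_factor multiplicative suppression of expected counts.
#' @param temp_anom_sd,prec_anom_sd interannual anomaly scales: each year
#'   draws one temperature offset (deg C, additive) and one log-precipitation
#'   offset (multiplicative `exp(N(0, prec_anom_sd))`), applied island-wide.
#' @param seasonal_temp_amp seasonal temperature half-amplitude (deg C);
#'   southern-hemisphere phase (January warmest, July coldest).
#' @param diurnal_half_range `tmax - tmean` = `tmean - tmin` (deg C).
#' @param coldest_month,wet_quarter_months climatological coldest month and
#'   wettest-quarter months implied by the seasonal phases (generator
#'   constants; the excursion is applied to these months).
#' @param count_scale expected count per transect at suitability 1.
#' @param nb_size negative-binomial dispersion of transect counts (smaller =
#'   more overdispersed).
#' @param season_end_month last month of the 4-month spotlight survey season
#'   attributed to a survey year (2 = November-February).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_rows = 20L, grid_cols = 20L, cell_area = 25,
                             years = 1947:2009, seed = 1L,
                             anomaly_window = c(2001L, 2003L),
                             anomaly_winter_warming = 2,
                             anomaly_wet_quarter_scale = 1.5,
                             suppression_start_year = 2004L,
                             suppression_factor = 0.4,
                             temp_anom_sd = 0.8, prec_anom_sd = 0.25,
                             seasonal_temp_amp = 6, diurnal_half_range = 5,
                             coldest_month = 7L, wet_quarter_months = 6:8,
                             count_scale = 1.5, nb_size = 2,
                             season_end_month = 2L) {
  if (grid_rows < 10L || grid_cols < 10L)
    stop("grid must be at least 10 x 10 cells")
  if (length(years) < 20L || !all(diff(years) == 1L))
    stop("years must be a contiguous span of at least 20")
  if (!is.null(anomaly_window) &&
      (anomaly_window[1L] > anomaly_window[2L] ||
       anomaly_window[1L] < years[1L] ||
       anomaly_window[2L] > years[length(years)]))
    stop("anomaly_window must lie inside the simulated years")
  if (anomaly_wet_quarter_scale < 1)
    stop("anomaly_wet_quarter_scale must be >= 1")
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         cell_area = cell_area, years = as.integer(years),
         seed = as.integer(seed), anomaly_window = anomaly_window,
         anomaly_winter_warming = anomaly_winter_warming,
         anomaly_wet_quarter_scale = anomaly_wet_quarter_scale,
         suppression_start_year = suppression_start_year,
         suppression_factor = suppression_factor,
         temp_anom_sd = temp_anom_sd, prec_anom_sd = prec_anom_sd,
         seasonal_temp_amp = seasonal_temp_amp,
         diurnal_half_range = diurnal_half_range,
         coldest_month = as.integer(coldest_month),
         wet_quarter_months = as.integer(wet_quarter_months),
         count_scale = count_scale, nb_size = nb_size,
         season_end_month = as.integer(season_end_month)),
    class = "synthetic_config")
}

#' Generate a synthetic monthly weather history
#'
#' Weather = sinusoidal seasonal cycle + linear spatial gradients + one
#' i.i.d. Gaussian interannual anomaly per year (additive for temperature,
#' multiplicative log-normal for precipitation), the simplest structure that
#' exercises all eight bioclimatic covariates. Inside the configured anomaly
#' window, coldest-month temperature minima are raised by
#' `anomaly_winter_warming` and wettest-quarter precipitation is multiplied by
#' `anomaly_wet_quarter_scale`.
#'
#' @param config a [synthetic_config()].
#' @return a [climate_cube()].
#' @export
gen_weather <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  R <- config$grid_rows; C <- config$grid_cols
  years <- config$years; ny <- length(years); nt <- 12L * ny
  gx <- matrix((col(matrix(0, R, C)) - 1) / (C - 1), R, C)
  gy <- matrix((row(matrix(0, R, C)) - 1) / (R - 1), R, C)
  ## warm dry east, cool south-west; winter minima span about -4..+6 deg C so
  ## most of the island sits at or above the 0 deg C truth optimum (imposed
  ## winter warming is then unfavourable over the occupied range). Spatial
  ## gradients are wide relative to the interannual anomalies, as on a real
  ## mountainous island (west-east rainfall contrast ~6x), so year-to-year
  ## weather shifts suitability partially rather than island-wide
  tmean_base <- 12 + 5 * gx - 5 * gy
  p_base <- 30 + 170 * (1 - gx)^1.5           # mm/month, strongly wet west
  m <- rep(1:12, ny)
  seas_t <- config$seasonal_temp_amp * cos(2 * pi * (m - 1) / 12)
  seas_p <- 1 + 0.5 * cos(2 * pi * (m - config$coldest_month) / 12)
  anoms <- with_seed(config$seed, list(
    t = stats::rnorm(ny, 0, config$temp_anom_sd),
    p = stats::rnorm(ny, 0, config$prec_anom_sd)))
  t_anom <- rep(anoms$t, each = 12L)
  p_mult <- rep(exp(anoms$p), each = 12L)
  yr <- rep(years, each = 12L)
  precip <- array(0, c(nt, R, C)); tmean <- array(0, c(nt, R, C))
  in_window <- if (is.null(config$anomaly_window)) rep(FALSE, nt) else
    yr >= config$anomaly_window[1L] & yr <= config$anomaly_window[2L]
  ## winter warming applies to the whole winter (= wet-quarter months on
  ## this island), so the trailing-window minimum rises by the full amount;
  ## tmin only, tmean/tmax unchanged
  warm_extra <- numeric(nt)
  warm_extra[in_window & m %in% config$wet_quarter_months] <-
    config$anomaly_winter_warming
  wet_mult <- rep(1, nt)
  wet_mult[in_window & m %in% config$wet_quarter_months] <-
    config$anomaly_wet_quarter_scale
  for (t in seq_len(nt)) {
    tmean[t, , ] <- tmean_base + seas_t[t] + t_anom[t]
    precip[t, , ] <- p_base * seas_p[t] * p_mult[t] * wet_mult[t]
  }
  dr <- config$diurnal_half_range
  tmin <- tmean - dr
  tmax <- tmean + dr
  for (t in which(warm_extra > 0)) tmin[t, , ] <- tmin[t, , ] + warm_extra[t]
  climate_cube(precip, tmin, tmax, tmean,
               start_year = years[1L], cell_km2 = config$cell_area)
}

#' Default parameters of the ground-truth suitability function
#'
#' Truth is a logistic function of two of the pipeline's own covariates:
#' suitability declines with wettest-quarter precipitation and falls off
#' quadratically as the coldest-month minimum departs from an optimum near
#' 0 deg C, echoing a dry-adapted species whose breeding phenology is cued by
#' winter minima. Both excursion levers (warmer winters, wetter wet quarters)
#' therefore reduce suitability.
#'
#' @param b0 intercept on the logit scale.
#' @param b_wet penalty per 100 mm of wettest-quarter precipitation.
#' @param b_cold quadratic penalty per (deg C)^2 departure of the
#'   coldest-month minimum from `t_opt`.
#' @param t_opt optimal coldest-month minimum temperature (deg C).
#' @return named list of coefficients.
#' @export
truth_coefs <- function(b0 = 1.6, b_wet = 0.5, b_cold = 0.09, t_opt = 0) {
  list(b0 = b0, b_wet = b_wet, b_cold = b_cold, t_opt = t_opt)
}

#' Ground-truth suitability for every cell-month
#'
#' Deterministic given the weather and coefficients; values in `[0, 1]`.
#'
#' @param cube a [climate_cube()].
#' @param window trailing window length (months) the truth responds to.
#' @param coefs a [truth_coefs()] list.
#' @return object of class `truth_surface`: list with `suit` (array
#'   `n_months x rows x cols`, `NA` where the window precedes the cube),
#'   `window`, `coefs`, `start_year`, `start_month`.
#' @export
truth_surface <- function(cube, window = 12L, coefs = truth_coefs()) {
  cov <- covariate_stack(cube, window)
  eta <- coefs$b0 - coefs$b_wet * cov[, , , "prec_wet_q"] / 100 -
    coefs$b_cold * (cov[, , , "tmin_cold_m"] - coefs$t_opt)^2
  structure(list(suit = stats::plogis(eta), window = window, coefs = coefs,
                 start_year = cube$start_year, start_month = cube$start_month),
            class = "truth_surface")
}

#' Spatial sampling-effort (bias) surface
#'
#' A smooth multiplicative effort gradient increasing towards the north-east,
#' shared by the focal species and the target-group companions (all are
#' recorded by the same surveys, so their records inherit the same bias).
#'
#' @param config a [synthetic_config()].
#' @param strength log-scale range of the effort gradient.
#' @return positive matrix `rows x cols`.
#' @export
gen_bias <- function(config, strength = 1.5) {
  R <- config$grid_rows; C <- config$grid_cols
  gx <- (col(matrix(0, R, C)) - 1) / (C - 1)
  gy <- (row(matrix(0, R, C)) - 1) / (R - 1)
  exp(strength * (0.6 * gx + 0.4 * gy))
}

#' Generate occurrence records for the focal and target-group species
#'
#' Focal records are drawn over cell-months with probability proportional to
#' `truth x bias`; the two companion (target-group) species are drawn
#' proportional to `bias` alone, so companion density is independent of
#' suitability given effort. Records carry cell-centre coordinates, the
#' sampled year and month, accuracy fields within the pipeline's filters, and
#' a `source` flag (`"spotlight"` or `"other"`).
#'
#' @param truth a [truth_surface()].
#' @param bias positive effort matrix `rows x cols` (at least one positive
#'   cell).
#' @param cube the [climate_cube()] the truth was built from (for geometry).
#' @param n_focal,n_target_group record counts (target group split evenly
#'   between two companion species).
#' @param seed integer seed.
#' @param spotlight_prob probability a record is flagged `"spotlight"`, for
#'   the focal and the companion species respectively.
#' @return data.frame with columns `species, x, y, row, col, year, month,
#'   date_acc, loc_acc, source`.
#' @export
gen_occurrences <- function(truth, bias, cube, n_focal = 1500L,
                            n_target_group = 6500L, seed = 1L,
                            spotlight_prob = c(focal = 0.45, target = 0.75)) {
  if (any(bias < 0) || !any(bias > 0))
    stop("bias must be non-negative with at least one positive cell")
  suit <- truth$suit
  d <- dim(suit)
  valid_t <- which(!is.na(suit[, 1, 1]))
  nt <- length(valid_t)
  bias_rep <- aperm(array(bias, c(d[2L], d[3L], nt)), c(3L, 1L, 2L))
  w_focal <- suit[valid_t, , , drop = FALSE] * bias_rep
  if (!any(w_focal > 0)) stop("truth x bias is zero everywhere")
  draw <- function(n, w, species, sp_prob) {
    idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
    ai <- arrayInd(idx, dim(w))
    t <- valid_t[ai[, 1L]]; row <- ai[, 2L]; col <- ai[, 3L]
    ym <- cube_month_at(cube, t)
    xy <- cell_center(cube, row, col)
    data.frame(species = species, x = xy[, "x"], y = xy[, "y"],
               row = row, col = col, year = ym[, "year"],
               month = ym[, "month"], date_acc = 0L, loc_acc = 0,
               source = ifelse(stats::runif(n) < sp_prob,
                               "spotlight", "other"))
  }
  with_seed(seed, {
    n1 <- n_target_group %/% 2L
    rbind(draw(n_focal, w_focal, "focal", spotlight_prob[[1L]]),
          draw(n1, bias_rep, "companion_a", spotlight_prob[[2L]]),
          draw(n_target_group - n1, bias_rep, "companion_b",
               spotlight_prob[[2L]]))
  })
}

## months (cube time indices) of the survey season attributed to year y:
## the 4 consecutive months ending at season_end_month of y
season_indices <- function(cube, year, season_end_month) {
  end <- month_index(cube, year, season_end_month)
  (end - 3L):end
}

#' Generate spotlight-style transect counts
#'
#' Regions tile disjoint blocks of cells; each transect is a pair of adjacent
#' cells inside its region. The count for transect `t` in survey year `y` is
#' negative binomial with mean `count_scale` times the mean true suitability
#' over the transect's cells during the survey season of `y`. From
#' `suppression_start_year` onward the expectation is held low regardless of
#' suitability: `suppression_factor` times the transect's mean
#' pre-suppression expectation, so counts decouple from the weather.
#'
#' @param truth a [truth_surface()].
#' @param cube the generating [climate_cube()].
#' @param config a [synthetic_config()] (suppression, season and count
#'   parameters are taken from it).
#' @param n_regions,transects_per_region survey design.
#' @param years survey years (each season must fall inside the truth's valid
#'   months).
#' @param seed integer seed.
#' @param drop optional data.frame `(transect, year)` of transect-years to
#'   drop, to exercise complete-panel filters.
#' @return data.frame `transect, region, year, count`.
#' @export
gen_transects <- function(truth, cube, config, n_regions = 30L,
                          transects_per_region = 5L, years, seed = 1L,
                          drop = NULL) {
  d <- grid_dim(cube)
  ## region anchor cells on a coarse lattice, 3x3 blocks
  anchors <- expand.grid(r = seq(2L, d[1L] - 3L, by = 3L),
                         c = seq(2L, d[2L] - 3L, by = 3L))
  if (nrow(anchors) < n_regions)
    stop("grid too small for ", n_regions, " regions")
  suit <- truth$suit
  with_seed(seed, {
    sel <- sample.int(nrow(anchors), n_regions)
    design <- do.call(rbind, lapply(seq_len(n_regions), function(g) {
      a <- anchors[sel[g], ]
      tr <- lapply(seq_len(transects_per_region), function(k) {
        r0 <- a$r + sample.int(3L, 1L) - 1L
        c0 <- a$c + sample.int(2L, 1L) - 1L       # pair of E-W adjacent cells
        data.frame(region = g,
                   transect = sprintf("R%02dT%02d", g, k),
                   r1 = r0, c1 = c0, r2 = r0, c2 = c0 + 1L)
      })
      do.call(rbind, tr)
    }))
    ## suitability-driven expectation per transect and year
    mu_mat <- sapply(years, function(y) {
      idx <- season_indices(cube, y, config$season_end_month)
      if (any(is.na(suit[idx, 1, 1])))
        stop("survey season of ", y, " precedes valid truth months")
      mu_cell <- apply(suit[idx, , , drop = FALSE], c(2L, 3L), mean)
      config$count_scale *
        (mu_cell[cbind(design$r1, design$c1)] +
         mu_cell[cbind(design$r2, design$c2)]) / 2
    })
    ## suppression: hold the expectation at a fixed fraction of each
    ## transect's pre-suppression baseline, decoupled from the weather
    if (!is.null(config$suppression_start_year)) {
      supp <- years >= config$suppression_start_year
      base <- if (any(!supp)) rowMeans(mu_mat[, !supp, drop = FALSE])
              else rowMeans(mu_mat)
      mu_mat[, supp] <- config$suppression_factor * base
    }
    out <- do.call(rbind, lapply(seq_along(years), function(i) {
      data.frame(transect = design$transect, region = design$region,
                 year = years[i],
                 count = stats::rnbinom(nrow(design), mu = mu_mat[, i],
                                        size = config$nb_size))
    }))
    if (!is.null(drop)) {
      key <- paste(out$transect, out$year)
      out <- out[!key %in% paste(drop$transect, drop$year), ]
    }
    rownames(out) <- NULL
    out
  })
}
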