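## Monthly projection of a fitted model, compositing, binarisation at the
## equal sensitivity/specificity threshold, and suitable-area time series.

#' Project a model onto one month's covariate surface
#'
#' @param model a fitted `maxent_model`.
#' @param covariates array `rows x cols x p` with the model's covariates on
#'   the third dimension (named); a missing covariate name is an error.
#'   Masked (`NA`) cells propagate.
#' @return matrix `rows x cols` of logistic suitability.
#' @export
project_month <- function(model, covariates) {
  vars <- covariate_names(model)
  have <- dimnames(covariates)[[3L]]
  if (!all(vars %in% have))
    stop("covariate surface lacks: ",
         paste(setdiff(vars, have), collapse = ", "))
  d <- dim(covariates)
  tab <- matrix(covariates[, , vars, drop = FALSE], d[1L] * d[2L],
                length(vars))
  colnames(tab) <- vars
  ok <- stats::complete.cases(tab)
  out <- rep(NA_real_, nrow(tab))
  if (any(ok))
    out[ok] <- logistic_output(
      model, build_features(tab[ok, , drop = FALSE],
                            spec = model$feature_spec))
  matrix(out, d[1L], d[2L])
}

#' Project a model onto every month of a cube
#'
#' Assembles, for each requested month, the covariate surface whose window
#' version matches each fitted covariate's `_12m` / `_36m` suffix, and
#' applies the logistic output cellwise.
#'
#' @param model a fitted `maxent_model` (covariates named
#'   `<variable>_<12|36>m`).
#' @param cube a [climate_cube()].
#' @param years calendar years to project (default: every year whose windows
#'   fit inside the cube).
#' @param stacks optional precomputed [covariate_stack()]s, named `"12"`,
#'   `"36"`.
#' @return object of class `suitability_series`: list with `suit` (array
#'   `n x rows x cols`), `months` (data.frame `year, month`).
#' @export
project_series <- function(model, cube, years = NULL, stacks = NULL) {
  vars <- covariate_names(model)
  wl <- suppressWarnings(as.integer(sub("^.*_(12|36)m$", "\\1", vars)))
  base <- sub("_(12|36)m$", "", vars)
  if (any(is.na(wl)))
    stop("model covariates must carry a _12m/_36m window suffix")
  need <- sort(unique(wl))
  if (is.null(stacks)) stacks <- list()
  for (L in need)
    if (!as.character(L) %in% names(stacks))
      stacks[[as.character(L)]] <- covariate_stack(cube, L)
  maxL <- max(need)
  all_m <- cube_months(cube)
  t_all <- seq_len(n_months(cube))
  ok <- t_all > maxL
  if (!is.null(years)) ok <- ok & all_m$year %in% years
  t_sel <- t_all[ok]
  d <- grid_dim(cube)
  ncell <- d[1L] * d[2L]
  suit <- array(NA_real_, c(length(t_sel), d[1L], d[2L]))
  for (i in seq_along(t_sel)) {
    t <- t_sel[i]
    tab <- matrix(NA_real_, ncell, length(vars))
    colnames(tab) <- vars
    for (k in seq_along(vars))
      tab[, k] <- stacks[[as.character(wl[k])]][t, , , base[k]]
    okc <- stats::complete.cases(tab)
    v <- rep(NA_real_, ncell)
    if (any(okc))
      v[okc] <- logistic_output(
        model, build_features(tab[okc, , drop = FALSE],
                              spec = model$feature_spec))
    suit[i, , ] <- matrix(v, d[1L], d[2L])
  }
  structure(list(suit = suit, months = all_m[ok, , drop = FALSE]),
            class = "suitability_series")
}

#' Cellwise mean of monthly suitability surfaces
#'
#' @param surfaces array `n x rows x cols` (or a `suitability_series`).
#' @return matrix `rows x cols`; masked months are ignored cellwise, cells
#'   with no data are `NA`.
#' @export
composite_mean <- function(surfaces) {
  if (inherits(surfaces, "suitability_series")) surfaces <- surfaces$suit
  if (is.null(dim(surfaces)) || dim(surfaces)[1L] == 0L)
    stop("no surfaces to composite")
  out <- apply(surfaces, c(2L, 3L), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  out
}

#' Equal training sensitivity/specificity threshold
#'
#' Over candidate thresholds equal to the unique observed scores, returns the
#' candidate minimising `|sensitivity - specificity|`, where sensitivity is
#' the fraction of presences scoring at or above the threshold and
#' specificity the fraction of background scoring below it; ties return the
#' lowest such threshold.
#'
#' @param pres_scores,bg_scores numeric scores (both non-empty).
#' @return the selected threshold.
#' @export
equal_ss_threshold <- function(pres_scores, bg_scores) {
  if (!length(pres_scores) || !length(bg_scores))
    stop("both score vectors must be non-empty")
  cand <- sort(unique(c(pres_scores, bg_scores)))
  sp <- sort(pres_scores); sb <- sort(bg_scores)
  m <- length(sp); n <- length(sb)
  sens <- (m - findInterval(cand, sp, left.open = TRUE)) / m
  spec <- findInterval(cand, sb, left.open = TRUE) / n
  cand[which.min(abs(sens - spec))]
}

#' Binarise a suitability surface
#'
#' @param surface numeric matrix/array of logistic suitability.
#' @param t threshold in `[0, 1]`; a cell is suitable iff suitability `>= t`.
#' @return 0/1 surface of the same shape (`NA` preserved).
#' @export
binary_surface <- function(surface, t) {
  if (t < 0 || t > 1) stop("threshold must be in [0, 1]")
  if (inherits(surface, "suitability_series")) surface <- surface$suit
  (surface >= t) + 0
}

#' Suitable-area time series from binary surfaces
#'
#' Monthly area is the count of suitable cells times the cell area; annual
#' rows summarise each year's monthly areas (mean, min, max). The annual
#' value carried into downstream abundance analysis is the mean by default.
#' Years without all 12 months are flagged incomplete.
#'
#' @param binary array `n x rows x cols` of 0/1 surfaces.
#' @param months data.frame `year, month` aligned with the array's first
#'   dimension (a `suitability_series`' `months`).
#' @param cell_km2 area of one cell, km^2.
#' @return list of class `area_series`: `monthly` (`year, month, area_km2`)
#'   and `annual` (`year, mean, min, max, n_months, complete`).
#' @export
area_series <- function(binary, months, cell_km2) {
  if (dim(binary)[1L] != nrow(months))
    stop("months must align with the surface array")
  monthly <- data.frame(
    year = months$year, month = months$month,
    area_km2 = apply(binary, 1L, sum, na.rm = TRUE) * cell_km2)
  annual <- do.call(rbind, lapply(split(monthly, monthly$year), function(df)
    data.frame(year = df$year[1L], mean = mean(df$area_km2),
               min = min(df$area_km2), max = max(df$area_km2),
               n_months = nrow(df), complete = nrow(df) == 12L)))
  rownames(annual) <- NULL
  if (any(!annual$complete))
    warning("partial years in area series: ",
            paste(annual$year[!annual$complete], collapse = ", "))
  structure(list(monthly = monthly, annual = annual, cell_km2 = cell_km2),
            class = "area_series")
}

#' Per-cell fraction of months classed suitable
#'
#' The composite of the binary surfaces: a habitat-stability map.
#'
#' @param binary array `n x rows x cols` of 0/1 surfaces.
#' @return matrix of fractions in `[0, 1]`.
#' @export
suitable_fraction <- function(binary) composite_mean(binary)
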