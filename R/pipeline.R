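## Orchestration of the full analysis from a single declarative config:
## simulate (or ingest) -> prepare occurrences -> covariates -> target-group
## background -> maxent fit with window selection -> monthly projection and
## core-habitat area -> abundance analysis. Also the spotlight-excluded
## "independent model" variant.

#' Declarative configuration of a full pipeline run
#'
#' Defaults mirror the study design the package implements: a ~60-year
#' synthetic weather history, presences prepared with the 1-month / 10-km
#' accuracy filters and 5-km monthly dedup, a target-group background,
#' 12- vs 36-month window selection by permutation importance, monthly
#' projection with equal sensitivity/specificity binarisation, and the
#' abundance analysis over a fixed 20-year transect panel.
#'
#' @param synth a [synthetic_config()] describing the study system.
#' @param seed master seed; stage seeds are derived from it.
#' @param n_focal,n_target_group occurrence sample sizes.
#' @param background_n target-group background size.
#' @param window_lengths trailing windows to compute (subset of 12, 36).
#' @param window_select fit the double-window model and keep one version per
#'   variable by permutation importance (requires both windows).
#' @param beta_multiplier,fit_tol,fit_max_iter [fit_maxent()] settings.
#' @param k_folds cross-validation folds.
#' @param project_years years to project monthly suitability for.
#' @param annual_stat annual area statistic carried into abundance analysis.
#' @param abundance_years span of the abundance index panel.
#' @param regional_early,regional_late 3-year windows of the regional change.
#' @param n_regions,transects_per_region synthetic survey design.
#' @param changepoint_method,changepoint_n_perm [changepoint_mean()] settings.
#' @param climate_model also fit a long-term climatology model (30-year
#'   baseline) for comparison.
#' @param climate_baseline inclusive years of the climatology baseline.
#' @return list of class `run_config`.
#' @export
run_config <- function(synth = synthetic_config(),
                       seed = 1L,
                       n_focal = 1500L, n_target_group = 6500L,
                       background_n = 10000L,
                       window_lengths = c(12L, 36L),
                       window_select = length(window_lengths) > 1L,
                       beta_multiplier = 1, fit_tol = 1e-7,
                       fit_max_iter = 1000L,
                       k_folds = 10L,
                       project_years = 1950:2009,
                       annual_stat = "mean",
                       abundance_years = 1990:2009,
                       regional_early = 1997:1999,
                       regional_late = 2007:2009,
                       n_regions = 30L, transects_per_region = 5L,
                       changepoint_method = "distribution_free",
                       changepoint_n_perm = 999L,
                       climate_model = FALSE,
                       climate_baseline = c(1976L, 2005L)) {
  structure(as.list(environment()), class = "run_config")
}

## stage seeds derived from the master seed (kept well below 2^31)
stage_seed <- function(config, stage) {
  offs <- c(occurrences = 1L, transects = 2L, background = 3L, cv = 4L,
            importance = 5L, changepoint = 6L)
  (config$seed %% 20000000L) * 100L + offs[[stage]]
}

#' Run the full weather-model pipeline
#'
#' Executes every stage on synthetic data generated from the config (or on
#' supplied inputs) and returns all artifacts: the prepared occurrence sets,
#' background, window-selection table, correlation screen, final model and
#' cross-validation report, monthly suitability and core-habitat area series,
#' and the abundance analysis (changepoints, segmented regressions, regional
#' change table).
#'
#' @param config a [run_config()].
#' @param cube,occurrences,counts optional externally supplied inputs; when
#'   `NULL` they are generated from `config$synth`.
#' @param exclude_spotlight drop `source == "spotlight"` records from both
#'   the focal and the target-group sets before modelling (the independent
#'   model variant).
#' @return a list of class `model_bundle`.
#' @export
run_full_model <- function(config = run_config(), cube = NULL,
                           occurrences = NULL, counts = NULL,
                           exclude_spotlight = FALSE) {
  stopifnot(inherits(config, "run_config"))
  synth <- config$synth
  if (is.null(cube)) cube <- gen_weather(synth)
  truth <- truth_surface(cube)
  if (is.null(occurrences)) {
    occurrences <- gen_occurrences(
      truth, gen_bias(synth), cube, n_focal = config$n_focal,
      n_target_group = config$n_target_group,
      seed = stage_seed(config, "occurrences"))
  }
  if (is.null(counts)) {
    counts <- gen_transects(
      truth, cube, synth, n_regions = config$n_regions,
      transects_per_region = config$transects_per_region,
      years = config$abundance_years,
      seed = stage_seed(config, "transects"))
  }
  if (exclude_spotlight) {
    occurrences <- occurrences[occurrences$source != "spotlight", ,
                               drop = FALSE]
    if (!nrow(occurrences)) stop("no non-spotlight records remain")
  }

  ## --- occurrence preparation -------------------------------------------
  prepared <- dedupe_records(filter_records(occurrences))
  stacks <- stats::setNames(
    lapply(config$window_lengths, function(L) covariate_stack(cube, L)),
    as.character(config$window_lengths))
  stamped <- stamp_covariates(prepared, cube,
                              window_lengths = config$window_lengths,
                              stacks = stacks)
  pres <- stamped[stamped$species == "focal", , drop = FALSE]

  ## --- target-group background ------------------------------------------
  background <- build_target_group_background(
    stamped, cube, n = config$background_n,
    seed = stage_seed(config, "background"),
    window_lengths = config$window_lengths, stacks = stacks)

  cov_cols <- as.vector(outer(bioclim_names(),
                              config$window_lengths,
                              function(v, L) sprintf("%s_%dm", v, L)))
  ## --- model fitting ----------------------------------------------------
  if (config$window_select && length(config$window_lengths) > 1L) {
    selection <- select_window_per_variable(
      pres[, cov_cols], background[, cov_cols],
      seed = stage_seed(config, "importance"),
      beta_multiplier = config$beta_multiplier, tol = config$fit_tol,
      max_iter = config$fit_max_iter)
    selected <- selection$selected
  } else {
    selection <- NULL
    selected <- sprintf("%s_%dm", bioclim_names(),
                        config$window_lengths[1L])
  }
  screen <- correlation_screen(rbind(pres[, selected],
                                     background[, selected]))
  bgf <- build_features(background[, selected])
  prf <- build_features(pres[, selected], spec = attr(bgf, "feature_spec"))
  model <- fit_maxent(prf, bgf, beta_multiplier = config$beta_multiplier,
                      tol = config$fit_tol,
                      max_iter = config$fit_max_iter)
  importance <- permutation_importance(
    model, pres[, selected], background[, selected],
    seed = stage_seed(config, "importance"))
  cv <- cross_validate(pres[, selected], background[, selected],
                       k = config$k_folds, seed = stage_seed(config, "cv"),
                       beta_multiplier = config$beta_multiplier,
                       tol = config$fit_tol,
                       max_iter = config$fit_max_iter)

  ## --- projection and core-habitat area ---------------------------------
  suit <- project_series(model, cube, years = config$project_years,
                         stacks = stacks)
  composite <- composite_mean(suit)
  thr <- equal_ss_threshold(logistic_output(model, prf),
                            logistic_output(model, bgf))
  binary <- binary_surface(suit, thr)
  areas <- area_series(binary, suit$months, cube$cell_km2)

  ## --- abundance analysis -----------------------------------------------
  ai <- abundance_index(counts, config$abundance_years)
  annual <- annual_area_df(areas, config$annual_stat)
  annual <- annual[annual$year %in% config$abundance_years, , drop = FALSE]
  cp_ai <- changepoint_mean(ai$ai, method = config$changepoint_method,
                            n_perm = config$changepoint_n_perm,
                            seed = stage_seed(config, "changepoint"),
                            years = ai$year)
  cp_ratio <- ratio_changepoint(annual, ai,
                                method = config$changepoint_method,
                                n_perm = config$changepoint_n_perm,
                                seed = stage_seed(config, "changepoint"))
  segments <- segmented_regression(annual, ai, cp_ratio$year)
  regional <- regional_change(counts, config$regional_early,
                              config$regional_late)

  bundle <- list(
    config = config, cube = cube, truth = truth,
    occurrences = occurrences, counts = counts,
    presences = pres, background = background,
    selection = selection, selected = selected, screen = screen,
    model = model, importance = importance, cv = cv,
    suitability = suit, composite = composite, threshold = thr,
    areas = areas, abundance = ai,
    changepoint_ai = cp_ai, changepoint_ratio = cp_ratio,
    segments = segments, regional = regional)

  ## --- optional long-term climatology model -----------------------------
  if (config$climate_model) {
    pres_clim <- stamp_climatology(pres[, setdiff(names(pres), cov_cols)],
                                   cube, config$climate_baseline)
    bg_clim <- stamp_climatology(
      background[, setdiff(names(background), cov_cols)],
      cube, config$climate_baseline)
    bundle$climate <- list(
      cv = cross_validate(pres_clim[, bioclim_names()],
                          bg_clim[, bioclim_names()],
                          k = config$k_folds,
                          seed = stage_seed(config, "cv"),
                          beta_multiplier = config$beta_multiplier,
                          tol = config$fit_tol,
                          max_iter = config$fit_max_iter))
  }
  class(bundle) <- "model_bundle"
  bundle
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("model_bundle\n")
  cat(sprintf("  presences: %d, background: %d, covariates: %s\n",
              nrow(x$presences), nrow(x$background),
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  CV AUC %.3f +/- %.3f, threshold %.3f\n",
              x$cv$mean_auc, x$cv$sd_auc, x$threshold))
  cat(sprintf("  AI changepoint year %s, ratio changepoint year %s\n",
              x$changepoint_ai$year, x$changepoint_ratio$year))
  invisible(x)
}

#' Run the spotlight-excluded independent model
#'
#' Repeats the pipeline with all `source == "spotlight"` records removed from
#' both the focal occurrence set and the target-group background source, so
#' the suitable-area series is independent of the spotlight counts that form
#' the abundance index. When the full model's bundle is supplied, a
#' side-by-side comparison (AUC, importances, composite-map correlation) is
#' attached.
#'
#' @param config a [run_config()].
#' @param full optional `model_bundle` from [run_full_model()] to compare
#'   against (also reuses its generated inputs).
#' @return a `model_bundle` with an extra `comparison` element when `full`
#'   is given.
#' @export
run_independent_model <- function(config = run_config(), full = NULL) {
  bundle <- run_full_model(
    config,
    cube = if (!is.null(full)) full$cube,
    occurrences = if (!is.null(full)) full$occurrences,
    counts = if (!is.null(full)) full$counts,
    exclude_spotlight = TRUE)
  if (!is.null(full)) {
    ok <- !is.na(bundle$composite) & !is.na(full$composite)
    imp_full <- stats::setNames(full$importance,
                                sub("_(12|36)m$", "", names(full$importance)))
    imp_ind <- stats::setNames(bundle$importance,
                               sub("_(12|36)m$", "", names(bundle$importance)))
    vars <- union(names(imp_full), names(imp_ind))
    bundle$comparison <- list(
      auc = data.frame(model = c("full", "independent"),
                       mean_auc = c(full$cv$mean_auc, bundle$cv$mean_auc),
                       sd_auc = c(full$cv$sd_auc, bundle$cv$sd_auc)),
      importance = data.frame(variable = vars,
                              full = imp_full[vars],
                              independent = imp_ind[vars],
                              row.names = NULL),
      composite_correlation = stats::cor(full$composite[ok],
                                         bundle$composite[ok],
                                         method = "spearman"))
  }
  bundle
}

#' Write a bundle's main artifacts to a directory
#'
#' Plain-text artifacts: prepared presences, background sample, monthly and
#' annual area series, abundance index, regional change table, and a JSON
#' summary (selection, importances, threshold, CV, changepoints, regression
#' statistics, config).
#'
#' @param bundle a `model_bundle`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(
    df, file.path(outdir, name), row.names = FALSE)
  w(bundle$presences, "presences.csv")
  w(bundle$background, "background.csv")
  w(bundle$areas$monthly, "area_monthly.csv")
  w(bundle$areas$annual, "area_annual.csv")
  w(as.data.frame(bundle$abundance), "abundance_index.csv")
  w(bundle$regional, "regional_change.csv")
  summary <- list(
    selected = bundle$selected,
    importance = as.list(bundle$importance),
    threshold = bundle$threshold,
    cv = bundle$cv[c("mean_auc", "sd_auc")],
    changepoint_ai = bundle$changepoint_ai[
      c("index", "year", "pre_mean", "pre_se", "post_mean", "post_se",
        "p_value")],
    changepoint_ratio = bundle$changepoint_ratio[
      c("index", "year", "pre_mean", "post_mean", "p_value")],
    segments = bundle$segments[c("pre", "post")],
    config = bundle$config[setdiff(names(bundle$config), "synth")],
    synth = unclass(bundle$config$synth))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(outdir)
}
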