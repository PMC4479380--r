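## Abundance index from transect counts, regional 10-year changes,
## at-most-one-change changepoint detection, and pre/post segmented
## regression of suitable area on log abundance.

#' Abundance index over a fixed transect panel
#'
#' The panel is the set of transects with a count in every year of `years`
#' (transects with incomplete data are excluded and logged); the index for a
#' year is the total count over the panel.
#'
#' @param counts data.frame `transect, year, count` (extra columns ignored).
#' @param years the years the index must cover.
#' @return data.frame of class `abundance_series` with columns `year, ai`;
#'   attributes `panel` (transect ids) and `excluded`.
#' @export
abundance_index <- function(counts, years) {
  sub <- counts[counts$year %in% years, , drop = FALSE]
  tab <- table(factor(sub$transect), factor(sub$year, levels = years))
  complete <- rownames(tab)[rowSums(tab >= 1L) == length(years)]
  if (!length(complete)) stop("no transect was surveyed in every year")
  excluded <- setdiff(unique(as.character(sub$transect)), complete)
  panel <- sub[sub$transect %in% complete, , drop = FALSE]
  ai <- stats::aggregate(count ~ year, data = panel, FUN = sum)
  out <- data.frame(year = years,
                    ai = ai$count[match(years, ai$year)])
  structure(out, class = c("abundance_series", "data.frame"),
            panel = complete, excluded = excluded)
}

bin_change <- function(delta) {
  a <- abs(delta)
  ifelse(a < 3, "small", ifelse(a <= 6, "medium", "large"))
}

#' Regional 10-year change in the abundance index
#'
#' For each transect surveyed in all six years, the difference between its
#' late and early 3-year mean annual sightings; transect differences are then
#' summed per region. Regions with no detections at all across the six years,
#' or with a net change of exactly zero, are excluded with a reason. The
#' magnitude bins follow the mapping small `< 3`, medium `3-6`, large `> 6`
#' sightings.
#'
#' @param counts data.frame `transect, region, year, count`.
#' @param early,late integer year vectors (e.g. `1997:1999` and `2007:2009`).
#' @return data.frame `region, delta, bin, direction, excluded, reason`.
#' @export
regional_change <- function(counts, early, late) {
  span <- c(early, late)
  sub <- counts[counts$year %in% span, , drop = FALSE]
  tab <- table(sub$transect, sub$year)
  complete <- rownames(tab)[rowSums(tab >= 1L) == length(span)]
  sub <- sub[sub$transect %in% complete, , drop = FALSE]
  per_tr <- do.call(rbind, lapply(split(sub, sub$transect, drop = TRUE),
    function(df) data.frame(
      region = df$region[1L], transect = df$transect[1L],
      total = sum(df$count),
      delta = mean(df$count[df$year %in% late]) -
              mean(df$count[df$year %in% early]))))
  out <- do.call(rbind, lapply(split(per_tr, per_tr$region), function(df) {
    delta <- sum(df$delta)
    none <- sum(df$total) == 0
    excluded <- none || delta == 0
    data.frame(region = df$region[1L], delta = delta,
               bin = bin_change(delta),
               direction = if (delta > 0) "increase" else
                 if (delta < 0) "decrease" else "none",
               excluded = excluded,
               reason = if (none) "no detections" else
                 if (delta == 0) "no change in AI" else "")
  }))
  rownames(out) <- NULL
  out
}

## split statistic for every candidate changepoint position 1..n-1
split_statistic <- function(x, method) {
  n <- length(x)
  k <- seq_len(n - 1L)
  if (method == "distribution_free") {
    r <- rank(x)
    s <- cumsum(r)[k] - k * mean(r)
    abs(s) / sqrt(k * (n - k))
  } else {
    cs <- cumsum(x); css <- cumsum(x^2)
    tot_ss <- css[n] - cs[n]^2 / n
    sse1 <- css[k] - cs[k]^2 / k
    sse2 <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k)
    tot_ss - (sse1 + sse2)
  }
}

#' Single (at-most-one) changepoint in the mean of a series
#'
#' Finds the split maximising a mean-change criterion: by default a
#' distribution-free rank CUSUM (`|sum of centred ranks up to k|` normalised
#' by `sqrt(k (n - k))`), alternatively the Gaussian between-segment
#' sum-of-squares reduction. Significance is assessed by permutation of the
#' series. The changepoint index is the last position of the pre segment.
#'
#' @param series numeric series, length at least 4.
#' @param method `"distribution_free"` (rank CUSUM) or `"gaussian"`.
#' @param n_perm permutations for the significance test (0 skips the test).
#' @param alpha significance level.
#' @param seed seed for the permutations.
#' @param years optional calendar year labels aligned with the series.
#' @return list of class `changepoint_result`: `index`, `year`, `pre_mean`,
#'   `pre_se`, `post_mean`, `post_se`, `statistic`, `p_value`, `significant`.
#' @export
changepoint_mean <- function(series, method = c("distribution_free",
                                                "gaussian"),
                             n_perm = 999L, alpha = 0.05, seed = 1L,
                             years = NULL) {
  method <- match.arg(method)
  n <- length(series)
  if (n < 4L) stop("changepoint detection needs a series of length >= 4")
  stat <- split_statistic(series, method)
  idx <- which.max(stat)                    # ties: earliest split
  obs <- stat[idx]
  p <- NA_real_
  if (n_perm > 0L) {
    p <- with_seed(seed, {
      exceed <- sum(vapply(seq_len(n_perm), function(b)
        max(split_statistic(sample(series), method)) >= obs - 1e-12,
        logical(1L)))
      (1 + exceed) / (n_perm + 1)
    })
  }
  pre <- series[seq_len(idx)]; post <- series[(idx + 1L):n]
  se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  structure(
    list(index = idx, year = if (!is.null(years)) years[idx] else NA,
         pre_mean = mean(pre), pre_se = se(pre),
         post_mean = mean(post), post_se = se(post),
         statistic = obs, p_value = p,
         significant = if (is.na(p)) NA else p <= alpha,
         method = method, n = n),
    class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf(
    "changepoint after position %d%s: mean %.3f +/- %.3f -> %.3f +/- %.3f\n",
    x$index, if (!is.na(x$year)) sprintf(" (year %s)", x$year) else "",
    x$pre_mean, x$pre_se, x$post_mean, x$post_se))
  if (!is.na(x$p_value))
    cat(sprintf("  %s statistic %.3f, permutation p = %.4f (%ssignificant)\n",
                x$method, x$statistic, x$p_value,
                if (isTRUE(x$significant)) "" else "not "))
  invisible(x)
}

## normalise an annual-area input: area_series object or data.frame(year, area)
annual_area_df <- function(area, stat = "mean") {
  if (inherits(area, "area_series"))
    return(data.frame(year = area$annual$year, area = area$annual[[stat]]))
  df <- as.data.frame(area)
  names(df)[1:2] <- c("year", "area")
  df
}

#' Changepoint in the suitable-area to abundance ratio
#'
#' Applies [changepoint_mean()] to the per-year ratio of suitable area to the
#' abundance index over the common years; a shift marks the year after which
#' abundance decouples from habitat. Zero-AI years are excluded with a
#' warning (the ratio is undefined).
#'
#' @param area an `area_series` or data.frame `year, area`.
#' @param ai an `abundance_series` or data.frame `year, ai`.
#' @param annual_stat which annual area statistic to use (`"mean"`, `"min"`,
#'   `"max"`).
#' @param ... passed to [changepoint_mean()].
#' @return a `changepoint_result` with an extra `ratio` data.frame.
#' @export
ratio_changepoint <- function(area, ai, annual_stat = "mean", ...) {
  adf <- annual_area_df(area, annual_stat)
  ai <- as.data.frame(ai)
  common <- intersect(adf$year, ai$year)
  df <- data.frame(year = common,
                   area = adf$area[match(common, adf$year)],
                   ai = ai$ai[match(common, ai$year)])
  if (any(df$ai == 0)) {
    warning("excluding ", sum(df$ai == 0), " zero-AI years from the ratio")
    df <- df[df$ai > 0, , drop = FALSE]
  }
  if (nrow(df) < 4L) stop("fewer than 4 usable common years")
  df$ratio <- df$area / df$ai
  res <- changepoint_mean(df$ratio, years = df$year, ...)
  res$ratio <- df
  res
}

ols_segment <- function(df, label) {
  if (nrow(df) < 3L)
    stop(sprintf("%s segment has %d years; need at least 3", label, nrow(df)))
  fit <- stats::lm(area ~ log_ai, data = df)
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  if (is.null(fstat)) {          # constant predictor: no slope estimable
    warning(label, " segment has a constant log(AI); no slope estimable")
    fstat <- c(NA_real_, NA_real_, NA_real_)
  }
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       f = unname(fstat[1L]), df1 = unname(fstat[2L]),
       df2 = unname(fstat[3L]),
       p_value = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                  lower.tail = FALSE)),
       n = nrow(df))
}

#' Pre/post segmented regression of area on log abundance
#'
#' Ordinary least squares of annual suitable area on the natural log of the
#' abundance index, fitted separately on years up to and including the
#' changepoint year and on the years after it. Zero-AI years are excluded
#' with a warning (log undefined).
#'
#' @param area an `area_series` or data.frame `year, area`.
#' @param ai an `abundance_series` or data.frame `year, ai`.
#' @param changepoint_year last year of the pre segment.
#' @param annual_stat annual area statistic to use.
#' @return list with elements `pre` and `post`, each containing `slope`,
#'   `intercept`, `r_squared`, `f`, `df1`, `df2`, `p_value`, `n`.
#' @export
segmented_regression <- function(area, ai, changepoint_year,
                                 annual_stat = "mean") {
  adf <- annual_area_df(area, annual_stat)
  ai <- as.data.frame(ai)
  common <- intersect(adf$year, ai$year)
  df <- data.frame(year = common,
                   area = adf$area[match(common, adf$year)],
                   ai = ai$ai[match(common, ai$year)])
  if (any(df$ai <= 0)) {
    warning("excluding ", sum(df$ai <= 0), " zero-AI years from regression")
    df <- df[df$ai > 0, , drop = FALSE]
  }
  df$log_ai <- log(df$ai)
  list(pre = ols_segment(df[df$year <= changepoint_year, , drop = FALSE],
                         "pre"),
       post = ols_segment(df[df$year > changepoint_year, , drop = FALSE],
                          "post"),
       data = df)
}
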