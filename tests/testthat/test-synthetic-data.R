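test_that("generators are deterministic under a fixed seed", {
  sy <- synthetic_config(years = 1985:2009, seed = 11)
  c1 <- gen_weather(sy); c2 <- gen_weather(sy)
  expect_identical(c1, c2)
  tr <- truth_surface(c1)
  bias <- gen_bias(sy)
  o1 <- gen_occurrences(tr, bias, c1, n_focal = 200, n_target_group = 100,
                        seed = 3)
  o2 <- gen_occurrences(tr, bias, c1, n_focal = 200, n_target_group = 100,
                        seed = 3)
  expect_identical(o1, o2)
  t1 <- gen_transects(tr, c1, sy, years = 1990:2009, seed = 5)
  t2 <- gen_transects(tr, c1, sy, years = 1990:2009, seed = 5)
  expect_identical(t1, t2)
})

test_that("weather respects physical and configuration invariants", {
  sy <- synthetic_config(years = 1985:2009, seed = 2)
  cube <- gen_weather(sy)
  expect_true(all(cube$precip >= 0))
  expect_true(all(cube$tmin <= cube$tmean & cube$tmean <= cube$tmax))
  ## seasonal structure: July is the coldest month, winter the wet season
  s <- cell_series(cube, 5, 5)
  monthly_t <- tapply(s$tmean, rep(1:12, length.out = length(s$tmean)), mean)
  expect_equal(unname(which.min(monthly_t)), 7)
  monthly_p <- tapply(s$precip, rep(1:12, length.out = length(s$precip)), mean)
  expect_gt(mean(monthly_p[6:8]), mean(monthly_p[c(1, 2, 12)]))
  expect_error(synthetic_config(grid_rows = 5), "at least 10")
  expect_error(synthetic_config(years = 2000:2005), "at least 20")
})

test_that("null anomaly leaves the excursion window statistically flat", {
  sy <- synthetic_config(years = 1980:2009, seed = 9,
                         anomaly_window = c(1995, 1997),
                         anomaly_winter_warming = 0,
                         anomaly_wet_quarter_scale = 1)
  cube <- gen_weather(sy)
  s <- cell_series(cube, 3, 3)
  yr <- cube_months(cube)$year
  july_tmin <- s$tmin[cube_months(cube)$month == 7]
  jy <- unique(yr)
  inw <- jy >= 1995 & jy <= 1997
  ## interannual anomalies are N(0, 0.8): window/non-window means differ by
  ## sampling error only
  expect_lt(abs(mean(july_tmin[inw]) - mean(july_tmin[!inw])),
            3 * sy$temp_anom_sd / sqrt(3))
})

test_that("winter warming raises coldest-month minima by the set amount", {
  ## compare window vs non-window July tmin over replicate seeds
  diffs <- sapply(1:25, function(seed) {
    sy <- synthetic_config(years = 1990:2009, seed = seed,
                           anomaly_window = c(2000, 2002),
                           anomaly_winter_warming = 2,
                           anomaly_wet_quarter_scale = 1)
    cube <- gen_weather(sy)
    mo <- cube_months(cube)
    july <- mo$month == 7
    inw <- mo$year >= 2000 & mo$year <= 2002
    mean(cube$tmin[july & inw, 4, 4]) - mean(cube$tmin[july & !inw, 4, 4])
  })
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 2), 4 * mc_se + 1e-9)
})

test_that("occurrence sampling follows truth x bias", {
  sy <- synthetic_config(years = 1985:2009, seed = 4)
  cube <- gen_weather(sy)
  tr <- truth_surface(cube)

  ## degenerate bias: all records land in the only positive-effort cell
  bias0 <- matrix(0, sy$grid_rows, sy$grid_cols); bias0[7, 9] <- 1
  occ <- gen_occurrences(tr, bias0, cube, n_focal = 50, n_target_group = 20,
                         seed = 1)
  expect_true(all(occ$row == 7 & occ$col == 9))
  expect_error(gen_occurrences(tr, bias0 * 0, cube), "at least one positive")

  ## two-region truth contrast: flat 0.8 vs 0.2 suitability, uniform bias,
  ## focal records split ~4:1 (exact binomial check)
  tr2 <- tr
  tr2$suit[] <- NA
  valid <- 13:dim(tr$suit)[1]
  tr2$suit[valid, , ] <- 0.2
  tr2$suit[valid, , 1:10] <- 0.8   # region A = west half of a 20-col grid
  occ2 <- gen_occurrences(tr2, matrix(1, sy$grid_rows, sy$grid_cols), cube,
                          n_focal = 2000, n_target_group = 10, seed = 2)
  focal <- occ2[occ2$species == "focal", ]
  n_a <- sum(focal$col <= 10)
  expect_gt(binom.test(n_a, 2000, p = 0.8)$p.value, 0.001)
})

test_that("focal density tracks truth x bias; companions track bias alone", {
  sy <- synthetic_config(years = 1985:2009, seed = 6)
  cube <- gen_weather(sy)
  tr <- truth_surface(cube)
  bias <- gen_bias(sy)
  occ <- gen_occurrences(tr, bias, cube, n_focal = 10000,
                         n_target_group = 10000, seed = 8)
  valid <- which(!is.na(tr$suit[, 1, 1]))
  ## expected cell weights marginalised over months
  w_focal <- apply(tr$suit[valid, , ], c(2, 3), sum) * bias
  w_comp <- bias
  focal <- occ[occ$species == "focal", ]
  comp <- occ[occ$species != "focal", ]
  obs_f <- table(factor(paste(focal$row, focal$col),
                        levels = paste(row(bias), col(bias))))
  obs_c <- table(factor(paste(comp$row, comp$col),
                        levels = paste(row(bias), col(bias))))
  ## lump low-expectation cells so the chi-square approximation is valid
  p_f <- as.vector(w_focal) / sum(w_focal)
  low <- p_f * nrow(focal) < 5
  obs_lumped <- c(as.vector(obs_f)[!low], sum(obs_f[low]))
  p_lumped <- c(p_f[!low], sum(p_f[low]))
  expect_gt(chisq.test(obs_lumped, p = p_lumped)$p.value, 0.001)
  ## companion cell frequencies are independent of truth given bias: the
  ## effort-standardised companion rate should not correlate with truth
  mean_truth <- apply(tr$suit[valid, , ], c(2, 3), mean)
  rate_c <- as.vector(obs_c) / as.vector(w_comp)
  expect_lt(abs(cor(rate_c, as.vector(mean_truth), method = "spearman")), 0.1)
})

test_that("transect counts are suppressed by the configured factor", {
  ratios <- sapply(1:30, function(seed) {
    sy <- synthetic_config(years = 1985:2009, seed = seed,
                           anomaly_window = NULL,
                           suppression_start_year = 2005)
    cube <- gen_weather(sy)
    tr <- truth_surface(cube)
    counts <- gen_transects(tr, cube, sy, years = 1990:2009, seed = seed)
    mean(counts$count[counts$year >= 2005]) /
      mean(counts$count[counts$year < 2005])
  })
  mc_se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.4), 5 * mc_se + 0.05)
})

test_that("zero count scale gives all-zero counts; drops are honoured", {
  sy <- synthetic_config(years = 1985:2009, seed = 3, count_scale = 0)
  cube <- gen_weather(sy)
  tr <- truth_surface(cube)
  counts <- gen_transects(tr, cube, sy, years = 1995:2000, seed = 1)
  expect_true(all(counts$count == 0))
  dropped <- gen_transects(tr, cube, sy, years = 1995:2000, seed = 1,
                           drop = data.frame(transect = counts$transect[1],
                                             year = 1996))
  expect_equal(nrow(counts) - nrow(dropped), 1L)
})

test_that("stationary truth yields no spurious changepoint signal", {
  ## under a constant-suitability, no-suppression regime the AI series is
  ## i.i.d.; the changepoint test should reject at ~alpha
  hits <- sapply(1:60, function(seed) {
    set.seed(seed)
    ai <- rnbinom(20, mu = 40, size = 10)   # stationary panel totals
    changepoint_mean(ai, n_perm = 199, seed = seed)$significant
  })
  expect_gte(mean(!hits), 0.9)
})
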