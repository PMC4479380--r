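toy_counts <- function() {
  ## 5 transects x 4 years; transect t3 misses 2002
  df <- expand.grid(transect = paste0("t", 1:5), year = 2001:2004,
                    KEEP.OUT.ATTRS = FALSE)
  df$region <- as.integer(sub("t", "", df$transect)) %/% 3 + 1
  set.seed(1)
  df$count <- rpois(nrow(df), 4)
  df[!(df$transect == "t3" & df$year == 2002), ]
}

test_that("abundance index uses only the complete transect panel", {
  counts <- toy_counts()
  ai <- abundance_index(counts, 2001:2004)
  expect_setequal(attr(ai, "panel"), c("t1", "t2", "t4", "t5"))
  expect_equal(attr(ai, "excluded"), "t3")
  ## hand sums over the panel
  for (y in 2001:2004) {
    want <- sum(counts$count[counts$year == y & counts$transect != "t3"])
    expect_equal(ai$ai[ai$year == y], want)
  }
  ## invariant to transect ordering; idempotent panel selection
  shuf <- counts[sample.int(nrow(counts)), ]
  expect_equal(abundance_index(shuf, 2001:2004)$ai, ai$ai)
  expect_error(abundance_index(counts[counts$year > 2001, ], 2001:2004),
               "every year")
  zero <- counts; zero$count <- 0
  expect_true(all(abundance_index(zero, 2001:2004)$ai == 0))
})

test_that("regional change bins and exclusions follow the rules", {
  mk <- function(region, transect, early, late) {
    rbind(data.frame(transect = transect, region = region, year = 1997:1999,
                     count = early),
          data.frame(transect = transect, region = region, year = 2007:2009,
                     count = late))
  }
  counts <- rbind(
    mk("A", "a1", c(3, 4, 5), c(1, 1, 1)),     # delta -3 -> medium decrease
    mk("B", "b1", c(0, 0, 0), c(0, 0, 0)),     # no detections -> excluded
    mk("C", "c1", c(2, 2, 2), c(2, 2, 2)),     # delta 0 -> excluded
    mk("D", "d1", c(0, 0, 0), c(7, 7, 7)),     # delta +7 -> large increase
    mk("E", "e1", c(1, 1, 1), c(3, 2, 1)))     # delta +1 -> small increase
  rc <- regional_change(counts, 1997:1999, 2007:2009)
  a <- rc[rc$region == "A", ]
  expect_equal(a$delta, -3); expect_equal(a$bin, "medium")
  expect_equal(a$direction, "decrease"); expect_false(a$excluded)
  expect_true(rc$excluded[rc$region == "B"])
  expect_match(rc$reason[rc$region == "B"], "no detections")
  expect_true(rc$excluded[rc$region == "C"])
  expect_match(rc$reason[rc$region == "C"], "no change")
  expect_equal(rc$bin[rc$region == "D"], "large")
  expect_equal(rc$bin[rc$region == "E"], "small")
})

test_that("changepoint recovers a clean mean shift with correct summaries", {
  x <- c(5, 5, 5, 5, 1, 1, 1, 1)
  for (method in c("distribution_free", "gaussian")) {
    res <- changepoint_mean(x, method = method, n_perm = 0)
    expect_equal(res$index, 4L)
    expect_equal(res$pre_mean, 5); expect_equal(res$post_mean, 1)
    ## brute force over all 7 splits agrees
    br <- changepoint_brute(x, method)
    expect_equal(res$index, br$index)
    expect_equal(res$statistic, br$value)
  }
  expect_error(changepoint_mean(c(1, 2, 3)), "length >= 4")
})

test_that("changepoint split maximises the criterion on random series", {
  set.seed(18)
  for (i in 1:40) {
    n <- sample(6:50, 1)
    x <- rnorm(n) + (runif(1) < 0.5) * (seq_len(n) > n %/% 2) * runif(1, 0, 3)
    for (method in c("distribution_free", "gaussian")) {
      res <- changepoint_mean(x, method = method, n_perm = 0)
      br <- changepoint_brute(x, method)
      expect_equal(res$index, br$index)
      expect_equal(res$statistic, br$value, tolerance = 1e-10)
    }
  }
})

test_that("constant series shows no significant changepoint", {
  res <- changepoint_mean(rep(3, 12), n_perm = 199, seed = 2)
  expect_false(res$significant)
})

test_that("a 3-sd mean shift is located within one position", {
  hits <- sapply(1:100, function(seed) {
    set.seed(seed)
    x <- c(rnorm(10), rnorm(10, 3))
    abs(changepoint_mean(x, n_perm = 0)$index - 10) <= 1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("ratio changepoint flags decoupling, not proportional change", {
  set.seed(7)
  area <- data.frame(year = 1990:2009, area = 900 + 200 * sin(1:20))
  ## AI proportional to area: constant ratio, no significant shift
  ai_prop <- data.frame(year = 1990:2009, ai = round(area$area / 15))
  res <- ratio_changepoint(area, ai_prop, n_perm = 499, seed = 1)
  expect_false(res$significant)
  ## AI decoupled (held low) from 2004: ratio jumps, changepoint at 2003
  ai_dec <- ai_prop
  ai_dec$ai[ai_dec$year >= 2004] <- round(ai_dec$ai[ai_dec$year >= 2004] * 0.3)
  res2 <- ratio_changepoint(area, ai_dec, n_perm = 499, seed = 1)
  expect_true(res2$significant)
  expect_lte(abs(res2$year - 2003), 1)
  ## composition: the ratio series reproduces the plain changepoint result
  ratio <- res2$ratio$ratio
  direct <- changepoint_mean(ratio, n_perm = 0)
  expect_equal(res2$index, direct$index)
  ## zero-AI years are excluded with a warning
  ai_zero <- ai_prop; ai_zero$ai[3] <- 0
  expect_warning(ratio_changepoint(area, ai_zero, n_perm = 0), "zero-AI")
})

test_that("segmented regression matches closed-form OLS", {
  ## perfect line: r^2 = 1
  ai <- data.frame(year = 1991:2000, ai = c(10, 20, 15, 30, 40, 35, 25, 50,
                                            45, 60))
  area <- data.frame(year = 1991:2000, area = 100 + 80 * log(ai$ai))
  seg <- suppressWarnings(segmented_regression(area, ai,
                                               changepoint_year = 1995))
  expect_equal(seg$pre$r_squared, 1, tolerance = 1e-12)
  expect_equal(seg$pre$slope, 80, tolerance = 1e-9)
  ## hand-computed OLS on a noisy 5-point segment
  set.seed(5)
  area2 <- data.frame(year = 1991:2000,
                      area = 100 + 80 * log(ai$ai) + rnorm(10, 0, 40))
  seg2 <- segmented_regression(area2, ai, changepoint_year = 1995)
  x <- log(ai$ai[1:5]); y <- area2$area[1:5]
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  ssr <- sum((a + b * x - mean(y))^2); sse <- sum((y - a - b * x)^2)
  expect_equal(seg2$pre$slope, b, tolerance = 1e-9)
  expect_equal(seg2$pre$r_squared, ssr / (ssr + sse), tolerance = 1e-9)
  expect_equal(seg2$pre$f, (ssr / 1) / (sse / 3), tolerance = 1e-9)
  expect_equal(seg2$pre$p_value, pf((ssr) / (sse / 3), 1, 3,
                                    lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(seg2$pre$df2, 3)
  ## a too-short segment errors with its name
  expect_error(segmented_regression(area2, ai, changepoint_year = 1992),
               "pre segment")
})

test_that("null regression p-values are uniform", {
  set.seed(23)
  pvals <- sapply(1:400, function(i) {
    ai <- data.frame(year = 1:15, ai = rpois(15, 30) + 1)
    area <- data.frame(year = 1:15, area = rnorm(15, 1000, 100))
    ols <- suppressWarnings(segmented_regression(area, ai,
                                                 changepoint_year = 15 - 3))
    ols$pre$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.1)
})
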