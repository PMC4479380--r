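test_that("feature construction scales, counts and clamps correctly", {
  bg <- data.frame(a = c(0, 10), b = c(1, 3))
  f <- build_features(bg)
  spec <- attr(f, "feature_spec")
  ## 2 linear + 2 quadratic + 1 product
  expect_equal(ncol(f), 5L)
  expect_equal(unname(f[, "a"]), c(0, 1))
  expect_true(all(f >= 0 & f <= 1))
  ## presence outside the background range clamps to the bound
  pr <- build_features(data.frame(a = c(-5, 20), b = c(2, 2)), spec = spec)
  expect_equal(unname(pr[, "a"]), c(0, 1))
  ## constant covariates are dropped with a warning
  expect_warning(
    fc <- build_features(data.frame(a = c(0, 1, 2), k = c(7, 7, 7))),
    "constant")
  expect_false(any(grepl("k", colnames(fc))))
})

test_that("moment-matching fixture recovers the closed-form coefficient", {
  bg <- matrix(c(1, 1, 0, 0), ncol = 1, dimnames = list(NULL, "f"))
  pr <- matrix(c(1, 1, 1, 0), ncol = 1, dimnames = list(NULL, "f"))
  m <- fit_maxent(pr, bg, beta_multiplier = 0, tol = 1e-12)
  ## moment constraint 2 e^l / (2 e^l + 2) = 3/4  =>  l = ln 3
  expect_equal(unname(m$lambda), log(3), tolerance = 1e-6)
  expect_equal(m$q_background, c(0.375, 0.375, 0.125, 0.125),
               tolerance = 1e-6)
  expect_equal(sum(m$q_background), 1, tolerance = 1e-9)
  ## entropy-calibrated logistic output at the two feature levels
  expect_equal(m$entropy, 1.2555, tolerance = 1e-4)
  lo <- logistic_output(m, matrix(c(1, 0), ncol = 1))
  expect_equal(lo, c(0.568, 0.305), tolerance = 1e-3)
})

test_that("a dominating penalty shrinks all coefficients to zero", {
  set.seed(5)
  bgc <- data.frame(x = rnorm(50), y = rnorm(50))
  bgf <- build_features(bgc)
  prf <- build_features(data.frame(x = rnorm(20, 2), y = rnorm(20, -1)),
                        spec = attr(bgf, "feature_spec"))
  m <- fit_maxent(prf, bgf, beta_multiplier = 1e6)
  expect_true(all(m$lambda == 0))
  expect_equal(m$q_background, rep(1 / 50, 50), tolerance = 1e-12)
  ## uniform raw distribution: logistic output is 0.5 everywhere
  expect_equal(logistic_output(m, bgf), rep(0.5, 50), tolerance = 1e-9)
})

test_that("objective trace is monotone and moment conditions hold at beta=0", {
  set.seed(8)
  bgc <- data.frame(x = rnorm(200), y = runif(200))
  bgf <- build_features(bgc)
  prc <- data.frame(x = rnorm(40, 1), y = runif(40)^2)
  prf <- build_features(prc, spec = attr(bgf, "feature_spec"))
  m <- fit_maxent(prf, bgf, beta_multiplier = 0, tol = 1e-10,
                  max_iter = 5000)
  expect_true(all(diff(m$trace) >= -1e-10))
  expect_equal(sum(m$q_background), 1, tolerance = 1e-9)
  ## max-ent moment conditions: feature expectations match presence means
  eq <- as.vector(t(bgf) %*% m$q_background)
  expect_equal(eq, unname(colMeans(prf)), tolerance = 1e-4)
})

test_that("fit agrees with a generic convex-solver oracle", {
  set.seed(21)
  for (i in 1:5) {
    bgc <- matrix(rnorm(100 * 3), 100, 3,
                  dimnames = list(NULL, c("u", "v", "w")))
    prc <- matrix(rnorm(20 * 3, mean = 0.5), 20, 3,
                  dimnames = list(NULL, c("u", "v", "w")))
    bgf <- build_features(bgc)
    prf <- build_features(prc, spec = attr(bgf, "feature_spec"))
    m <- fit_maxent(prf, bgf, beta_multiplier = 1, tol = 1e-10,
                    max_iter = 5000)
    oracle <- maxent_oracle_objective(prf, bgf, m$beta)
    expect_equal(m$trace[length(m$trace)], oracle$objective,
                 tolerance = 1e-5)
  }
})

test_that("non-convergence raises an error carrying the objective trace", {
  set.seed(3)
  bgf <- build_features(data.frame(x = rnorm(50), y = rnorm(50)))
  prf <- build_features(data.frame(x = rnorm(10, 3), y = rnorm(10)),
                        spec = attr(bgf, "feature_spec"))
  err <- tryCatch(fit_maxent(prf, bgf, tol = 0, max_iter = 2),
                  maxent_nonconvergence = function(e) e)
  expect_s3_class(err, "maxent_nonconvergence")
  expect_true(length(err$trace) >= 2)
})

test_that("AUC is the tie-aware Mann-Whitney probability", {
  expect_equal(auc(c(0.9, 0.8), c(0.1, 0.2, 0.3)), 1)
  expect_equal(auc(rep(0.5, 4), rep(0.5, 6)), 0.5)
  ## 4 pairs: (.9>.5), (.9>.1), (.2<.5), (.2>.1) -> 3/4
  expect_equal(auc(c(0.9, 0.2), c(0.5, 0.1)), 0.75)
  ## invariance under strictly monotone transforms
  set.seed(2)
  p <- runif(30); b <- runif(50)
  expect_equal(auc(p, b), auc(qlogis(p), qlogis(b)))
  expect_equal(auc(p, b), auc(p^3, b^3))
})

test_that("permutation importance isolates informative covariates", {
  set.seed(14)
  n_bg <- 400
  bgc <- data.frame(sig = rnorm(n_bg), noise = rnorm(n_bg))
  prc <- data.frame(sig = rnorm(120, 1.5), noise = rnorm(120))
  bgf <- build_features(bgc)
  prf <- build_features(prc, spec = attr(bgf, "feature_spec"))
  m <- fit_maxent(prf, bgf)
  wins <- sapply(1:100, function(seed) {
    imp <- permutation_importance(m, prc, bgc, seed = seed)
    imp[["sig"]] > imp[["noise"]]
  })
  expect_gte(mean(wins), 0.95)
  ## identity permutation (test hook): no drop anywhere -> equal shares
  expect_warning(
    imp0 <- permutation_importance(m, prc, bgc, permute = seq_len),
    "equal shares")
  expect_equal(unname(imp0), c(50, 50))
  ## single-covariate model: the whole importance mass
  bg1 <- build_features(bgc["sig"])
  m1 <- fit_maxent(build_features(prc["sig"],
                                  spec = attr(bg1, "feature_spec")), bg1)
  expect_equal(unname(permutation_importance(m1, prc["sig"], bgc["sig"])),
               100)
})

test_that("window selection keeps the version driving the truth", {
  ## truth depends on the 36-month variable; its 12-month sibling is a
  ## noisier proxy (correlated but diluted)
  picks <- sapply(1:10, function(seed) {
    set.seed(seed)
    n_bg <- 500; n_pr <- 150
    z <- rnorm(n_bg + n_pr)
    tbl <- data.frame(prec_36m = z, prec_12m = z + rnorm(n_bg + n_pr, 0, 1.5))
    pr_w <- plogis(3 * tbl$prec_36m)
    pr_idx <- sample.int(n_bg + n_pr, n_pr, TRUE, prob = pr_w)
    sel <- select_window_per_variable(tbl[pr_idx, ], tbl[1:n_bg, ],
                                      seed = seed)
    sel$choices$chosen[sel$choices$variable == "prec"]
  })
  expect_gte(mean(picks == "prec_36m"), 0.9)
  ## exact ties keep the 12-month version (parsimony tie-break): the
  ## identity permutation hook forces a zero-drop tie across versions
  tbl <- data.frame(prec_12m = c(1:20) / 20, prec_36m = c(1:20) / 20)
  pr <- tbl[rep(15:20, 3), ]
  sel <- suppressWarnings(select_window_per_variable(pr, tbl, seed = 1,
                                                     permute = seq_len))
  expect_equal(sel$choices$chosen, "prec_12m")
  expect_equal(nrow(sel$choices), 1L)
})

test_that("correlation screening flags only near-collinear pairs", {
  set.seed(33)
  x <- rnorm(10000)
  tab <- data.frame(x = x, x2 = 2 * x, z = rnorm(10000))
  sc <- correlation_screen(tab)
  expect_true(any(sc$flagged$var1 == "x" & sc$flagged$var2 == "x2"))
  expect_false(any(sc$flagged$var1 == "x" & sc$flagged$var2 == "z"))
  expect_lt(abs(sc$correlations["x", "z"]), 0.05)
  expect_equal(nrow(correlation_screen(tab, threshold = 1.01)$flagged), 0L)
})

test_that("cross-validation bookkeeping and degenerate folds behave", {
  set.seed(44)
  bgc <- data.frame(x = rnorm(100))
  prc <- data.frame(x = rep(c(1.1, 1.3), 5))   # 10 presences
  cv <- cross_validate(prc, bgc, k = 2, seed = 1)
  expect_equal(length(cv$fold_auc), 2L)
  expect_error(cross_validate(prc, bgc, k = 11), "exceeds")
  ## identical presences in every fold: deterministic fit, zero sd
  pr_same <- data.frame(x = rep(1.2, 12))
  cv_same <- cross_validate(pr_same, bgc, k = 3, seed = 1)
  expect_equal(cv_same$sd_auc, 0, tolerance = 1e-12)
})

test_that("known logistic truth is recovered with useful discrimination", {
  fx <- make_logistic_fixture(n_pres = 300, n_bg = 3000, seed = 10)
  bgf <- build_features(fx$bg)
  prf <- build_features(fx$pres, spec = attr(bgf, "feature_spec"))
  m <- fit_maxent(prf, bgf)
  fitted <- logistic_output(m, bgf)
  expect_gte(cor(fitted, fx$truth_bg, method = "spearman"), 0.9)
  cv <- cross_validate(fx$pres, fx$bg, k = 5, seed = 2)
  expect_gt(cv$mean_auc, 0.75)
})
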