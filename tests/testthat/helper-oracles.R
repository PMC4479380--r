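## Independent oracles and small fixture builders. These deliberately use
## naive loops / generic optimisers so they share no code path with the
## package implementations they check.

## brute-force bioclim derivation: explicit loops and textbook formulas
bioclim_brute <- function(p, tn, tx, tm = (tn + tx) / 2) {
  L <- length(p)
  qs <- sapply(1:(L - 2), function(i) p[i] + p[i + 1] + p[i + 2])
  mean_p <- sum(p) / L
  sd_p <- sqrt(sum((p - mean_p)^2) / (L - 1))
  tk <- tm + 273.15
  mean_k <- sum(tk) / L
  sd_k <- sqrt(sum((tk - mean_k)^2) / (L - 1))
  c(ann_prec = sum(p) * 12 / L,
    prec_wet_q = max(qs), prec_dry_q = min(qs),
    prec_cv = if (mean_p > 0) 100 * sd_p / mean_p else 0,
    ann_tmean = sum(tm) / L,
    tmax_warm_m = max(tx), tmin_cold_m = min(tn),
    temp_cv = 100 * sd_k / mean_k)
}

## generic convex-solver oracle for the maxent objective: L-BFGS-B on the
## split-variable (lambda = a - b, a, b >= 0) form of the L1 problem
maxent_oracle_objective <- function(pres, bg, beta) {
  J <- ncol(bg)
  pbar <- colMeans(pres)
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  neg <- function(ab) {
    lam <- ab[1:J] - ab[J + 1:J]
    -(sum(pbar * lam) - lse(as.vector(bg %*% lam))) + sum(beta * ab)
  }
  gr <- function(ab) {
    lam <- ab[1:J] - ab[J + 1:J]
    eta <- as.vector(bg %*% lam)
    q <- exp(eta - lse(eta))
    g <- as.vector(t(bg) %*% q) - pbar    # gradient of -loglik wrt lambda
    c(g + beta, -g + beta)
  }
  fit <- stats::optim(rep(0, 2 * J), neg, gr, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 5000,
                                                factr = 10))
  lam <- fit$par[1:J] - fit$par[J + 1:J]
  list(objective = sum(pbar * lam) -
         lse(as.vector(bg %*% lam)) - sum(beta * abs(lam)),
       lambda = lam)
}

## exhaustive-split changepoint oracle: direct formulas per candidate split
changepoint_brute <- function(x, method = "distribution_free") {
  n <- length(x)
  crit <- sapply(1:(n - 1), function(k) {
    if (method == "distribution_free") {
      r <- rank(x)
      abs(sum(r[1:k]) - k * mean(r)) / sqrt(k * (n - k))
    } else {
      pre <- x[1:k]; post <- x[(k + 1):n]
      sum((x - mean(x))^2) -
        (sum((pre - mean(pre))^2) + sum((post - mean(post))^2))
    }
  })
  list(index = which.max(crit), value = max(crit), all = crit)
}

## exhaustive equal-sensitivity/specificity threshold oracle
equal_ss_brute <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  gap <- sapply(cand, function(t) abs(mean(pres >= t) - mean(bg < t)))
  cand[which.min(gap)]
}

## presence-background fixture from a known 2-covariate logistic truth:
## background ~ uniform, presences drawn from it weighted by the truth
make_logistic_fixture <- function(n_pres, n_bg, seed,
                                  b = c(-3, 6, -4)) {
  set.seed(seed)
  pool_n <- max(20000, 4 * n_pres)
  pool <- data.frame(x1 = runif(pool_n, -1, 1), x2 = runif(pool_n, -1, 1))
  truth <- plogis(b[1] + b[2] * pool$x1 + b[3] * pool$x2)
  pres_idx <- sample.int(pool_n, n_pres, replace = TRUE, prob = truth)
  bg_idx <- sample.int(pool_n, n_bg, replace = TRUE)
  list(pres = pool[pres_idx, ], bg = pool[bg_idx, ],
       truth_bg = truth[bg_idx])
}

## tiny cube with fully scripted weather, for hand-checkable covariates
scripted_cube <- function(rows = 1, cols = 1, years = 1989:1990,
                          precip_fun = function(m, r, c) 50 + 10 * sin(m),
                          tmean_fun = function(m, r, c) 10 + 5 * cos(m)) {
  nt <- 12 * length(years)
  p <- array(0, c(nt, rows, cols)); tm <- array(0, c(nt, rows, cols))
  for (t in 1:nt) for (r in 1:rows) for (c in 1:cols) {
    p[t, r, c] <- precip_fun(t, r, c)
    tm[t, r, c] <- tmean_fun(t, r, c)
  }
  climate_cube(p, tm - 4, tm + 4, tm, start_year = years[1], cell_km2 = 25)
}

## quick record table builder
make_records <- function(..., defaults = list(species = "focal", x = 10,
                                              y = 10, year = 2000, month = 6,
                                              date_acc = 0, loc_acc = 0,
                                              source = "other")) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(utils::modifyList(defaults, as.list(r)))
  }))
}

## default small-scale scenario config used across pipeline tests: the full
## study structure (20x20 island, 30 regions x 5 transects) over a 22-year
## history, with reduced sample sizes for runtime
scenario_config <- function(seed, grid = 20L, ...) {
  sy <- synthetic_config(grid_rows = grid, grid_cols = grid,
                         years = 1988:2009, seed = seed)
  run_config(synth = sy, seed = seed, n_focal = 400L,
             n_target_group = 1200L, background_n = 1500L,
             window_lengths = 12L, window_select = FALSE,
             project_years = 1990:2009, k_folds = 5L,
             changepoint_n_perm = 499L, ...)
}
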