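## Maximum-entropy presence-background model: feature construction, L1
## penalised fitting by cyclic coordinate descent, logistic output, and
## evaluation utilities (AUC, permutation importance, window selection,
## correlation screening, k-fold cross-validation).

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Build the scaled feature matrix
#'
#' Features are linear, quadratic and pairwise-product transforms of the
#' covariates (hinge and threshold classes are deliberately not used). Each
#' feature is min-max scaled to `[0, 1]` using constants fixed on the
#' background sample; presence (or projection) features computed with an
#' existing spec are clamped to `[0, 1]`. Features of a constant covariate
#' carry no information and are dropped with a warning.
#'
#' @param cov data.frame or matrix of covariates (columns named).
#' @param spec an existing feature spec (from a background call) to apply; if
#'   `NULL`, a new spec is derived treating `cov` as the background.
#' @param classes feature classes to build when deriving a new spec.
#' @return numeric feature matrix with attribute `"feature_spec"`.
#' @export
build_features <- function(cov, spec = NULL,
                           classes = c("linear", "quadratic", "product")) {
  cov <- as.matrix(cov)
  vars <- colnames(cov)
  if (is.null(spec)) {
    rows <- list()
    if ("linear" %in% classes)
      for (v in vars) rows[[length(rows) + 1L]] <-
        data.frame(name = v, class = "linear", v1 = v, v2 = NA)
    if ("quadratic" %in% classes)
      for (v in vars) rows[[length(rows) + 1L]] <-
        data.frame(name = paste0(v, "^2"), class = "quadratic", v1 = v, v2 = NA)
    if ("product" %in% classes && length(vars) > 1L)
      for (i in seq_len(length(vars) - 1L)) for (j in (i + 1L):length(vars))
        rows[[length(rows) + 1L]] <-
          data.frame(name = paste0(vars[i], ":", vars[j]), class = "product",
                     v1 = vars[i], v2 = vars[j])
    spec <- do.call(rbind, rows)
    ## a constant covariate carries no information: drop every feature that
    ## involves it (its products are mere rescalings of other features)
    const_var <- vars[apply(cov, 2L, function(v) max(v) - min(v) <= 0)]
    raw <- raw_features(cov, spec)
    spec$lo <- apply(raw, 2L, min)
    spec$hi <- apply(raw, 2L, max)
    flat <- spec$hi - spec$lo <= 0 | spec$v1 %in% const_var |
      (!is.na(spec$v2) & spec$v2 %in% const_var)
    if (any(flat)) {
      warning("dropping constant features: ",
              paste(spec$name[flat], collapse = ", "))
      spec <- spec[!flat, , drop = FALSE]
      raw <- raw[, !flat, drop = FALSE]
    }
  } else {
    raw <- raw_features(cov, spec)
  }
  scaled <- sweep(sweep(raw, 2L, spec$lo), 2L, spec$hi - spec$lo, "/")
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  colnames(scaled) <- spec$name
  attr(scaled, "feature_spec") <- spec
  scaled
}

raw_features <- function(cov, spec) {
  miss <- setdiff(unique(c(spec$v1, stats::na.omit(spec$v2))), colnames(cov))
  if (length(miss))
    stop("covariates missing from input: ", paste(miss, collapse = ", "))
  out <- matrix(0, nrow(cov), nrow(spec))
  for (k in seq_len(nrow(spec))) {
    out[, k] <- switch(spec$class[k],
      linear = cov[, spec$v1[k]],
      quadratic = cov[, spec$v1[k]]^2,
      product = cov[, spec$v1[k]] * cov[, spec$v2[k]],
      stop("unknown feature class ", spec$class[k]))
  }
  out
}

## penalised mean presence log-likelihood (the quantity being maximised)
maxent_objective <- function(lambda, eta, pbar, beta) {
  sum(pbar * lambda) - logsumexp(eta) - sum(beta * abs(lambda))
}

#' Fit the maximum-entropy model
#'
#' Maximises the L1-penalised mean presence log-likelihood
#' `(1/m) sum_i log q(x_i) - sum_j beta_j |lambda_j|`, where
#' `q(x) = exp(lambda . f(x)) / sum_background exp(lambda . f)` is the raw
#' maximum-entropy distribution over the background, by cyclic coordinate
#' descent with a one-dimensional Newton step, soft-thresholding for the L1
#' penalty and step-halving to guarantee a monotone objective trace. The
#' per-feature penalty is `beta_j = beta_multiplier * s_j / sqrt(m)` with
#' `s_j` the background standard deviation of feature `j`.
#'
#' @param pres_features presence feature matrix (`m >= 2` rows).
#' @param bg_features background feature matrix (`N >= 10` rows), sharing
#'   columns (and usually a `"feature_spec"` attribute) with the presences.
#' @param beta_multiplier scales all penalties; 0 gives the unpenalised
#'   maximum-entropy fit whose feature expectations match presence means.
#' @param tol convergence tolerance on the objective change per full sweep.
#' @param max_iter maximum number of sweeps; non-convergence is an error of
#'   class `"maxent_nonconvergence"` carrying the objective trace.
#' @return object of class `maxent_model`: coefficients `lambda`, penalties
#'   `beta`, training log-normaliser `log_z`, entropy `entropy` of the raw
#'   distribution, objective `trace`, and the feature spec for projection.
#' @export
fit_maxent <- function(pres_features, bg_features, beta_multiplier = 1,
                       tol = 1e-8, max_iter = 1000L) {
  m <- nrow(pres_features); N <- nrow(bg_features)
  if (m < 2L) stop("need at least 2 presence rows")
  if (N < 2L) stop("need at least 2 background rows")
  J <- ncol(bg_features)
  pbar <- colMeans(pres_features)
  s <- apply(bg_features, 2L, stats::sd)
  beta <- beta_multiplier * s / sqrt(m)
  lambda <- numeric(J)
  eta <- numeric(N)
  obj <- maxent_objective(lambda, eta, pbar, beta)
  trace <- obj
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    obj_prev <- obj
    for (j in seq_len(J)) {
      f <- bg_features[, j]
      lz <- logsumexp(eta)
      q <- exp(eta - lz)
      eq <- sum(q * f)
      g <- eq - pbar[j]                       # d(-objective)/d lambda_j
      h <- max(sum(q * f * f) - eq^2, 1e-12)
      z <- h * lambda[j] - g
      lam_new <- sign(z) * max(abs(z) - beta[j], 0) / h
      step <- lam_new - lambda[j]
      if (abs(step) < 1e-14) next
      for (ls in 1:40) {
        cand <- lambda[j] + step
        eta_try <- eta + step * f
        lam_try <- lambda; lam_try[j] <- cand
        obj_try <- maxent_objective(lam_try, eta_try, pbar, beta)
        if (obj_try >= obj - 1e-12) {
          lambda[j] <- cand; eta <- eta_try; obj <- obj_try
          break
        }
        step <- step / 2
      }
    }
    trace <- c(trace, obj)
    if (obj - obj_prev < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(
      class = c("maxent_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "maxent did not converge in %d sweeps (last objective %.8f)",
        max_iter, obj),
        call = sys.call(-1L), trace = trace))
    stop(cond)
  }
  lz <- logsumexp(eta)
  q <- exp(eta - lz)
  qp <- q[q > 0]
  structure(
    list(lambda = stats::setNames(lambda, colnames(bg_features)),
         beta = beta, pbar = pbar, log_z = lz,
         entropy = -sum(qp * log(qp)),
         q_background = q, trace = trace, converged = converged,
         m = m, n_background = N,
         feature_spec = attr(bg_features, "feature_spec")),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d features (%d active), %d presences / %d background\n",
    length(x$lambda), sum(x$lambda != 0), x$m, x$n_background))
  cat(sprintf("  entropy H = %.4f, final objective %.6f (%d sweeps)\n",
              x$entropy, x$trace[length(x$trace)], length(x$trace) - 1L))
  invisible(x)
}

## linear predictor for a feature matrix
feature_link <- function(model, features) {
  as.vector(features %*% model$lambda)
}

#' Logistic suitability of feature rows
#'
#' The raw value `q(x) = exp(lambda . f(x) - log Z)` is mapped to `(0, 1)` by
#' the entropy-calibrated logistic transform
#' `e^H q / (1 + e^H q)` with `H` the entropy of the raw distribution over the
#' training background; a uniform raw distribution maps every cell to 0.5.
#'
#' @param model a fitted [fit_maxent()] model.
#' @param features feature matrix (built with the model's feature spec).
#' @return numeric vector of suitabilities in `(0, 1)`.
#' @export
logistic_output <- function(model, features) {
  lq <- feature_link(model, features) - model$log_z
  v <- exp(model$entropy + lq)
  v / (1 + v)
}

#' Predict suitability from covariates
#'
#' @param object a `maxent_model`.
#' @param newdata data.frame/matrix of covariate columns.
#' @param type `"logistic"` (default), `"raw"` (the normalised maximum-entropy
#'   density value) or `"link"` (`lambda . f(x)`).
#' @param ... unused.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw", "link"), ...) {
  type <- match.arg(type)
  feats <- build_features(newdata, spec = object$feature_spec)
  switch(type,
         logistic = logistic_output(object, feats),
         raw = exp(feature_link(object, feats) - object$log_z),
         link = feature_link(object, feats))
}

#' Area under the ROC curve for presence vs background scores
#'
#' The Mann-Whitney probability that a random presence outscores a random
#' background point, with ties counted one half; invariant to strictly
#' monotone transforms of the scores.
#'
#' @param pres_scores,bg_scores numeric score vectors (both non-empty).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pres_scores, bg_scores) {
  m <- length(pres_scores); n <- length(bg_scores)
  if (m == 0L || n == 0L) stop("both score vectors must be non-empty")
  r <- rank(c(pres_scores, bg_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Permutation importance of each covariate
#'
#' For each covariate, its values are permuted jointly across the pooled
#' presence + background rows, all features involving it are rebuilt with the
#' model's scaling constants, and the training AUC is recomputed; the
#' importance is `max(0, AUC_original - AUC_permuted)` (averaged over
#' `n_perm` permutations), normalised so the vector sums to 100.
#'
#' @param model a fitted `maxent_model`.
#' @param pres_cov,bg_cov covariate tables of the training presences and
#'   background.
#' @param seed integer seed for the permutations.
#' @param n_perm permutations per covariate (1 matches common practice;
#'   increase for stability).
#' @param permute permutation generator `function(n)`; the default draws a
#'   random permutation. Supplying `seq_len` (the identity) yields zero drops
#'   and is useful as a test hook.
#' @return named numeric vector of importances summing to 100.
#' @export
permutation_importance <- function(model, pres_cov, bg_cov, seed = 1L,
                                   n_perm = 1L, permute = sample.int) {
  pres_cov <- as.data.frame(pres_cov); bg_cov <- as.data.frame(bg_cov)
  vars <- covariate_names(model)
  pooled <- rbind(pres_cov[, vars, drop = FALSE],
                  bg_cov[, vars, drop = FALSE])
  m <- nrow(pres_cov)
  feats <- build_features(pooled, spec = model$feature_spec)
  link <- feature_link(model, feats)
  auc0 <- auc(link[seq_len(m)], link[-seq_len(m)])
  with_seed(seed, {
    drops <- vapply(vars, function(v) {
      mean(vapply(seq_len(n_perm), function(k) {
        perm <- pooled
        perm[[v]] <- perm[[v]][permute(nrow(perm))]
        fl <- feature_link(model, build_features(perm,
                                                 spec = model$feature_spec))
        auc0 - auc(fl[seq_len(m)], fl[-seq_len(m)])
      }, numeric(1L)))
    }, numeric(1L))
    imp <- pmax(drops, 0)
    if (sum(imp) <= 0) {
      warning("all permutation drops are zero; returning equal shares")
      imp <- rep(1, length(imp))
    }
    stats::setNames(100 * imp / sum(imp), vars)
  })
}

#' Covariate names a model was fitted on
#' @param model a `maxent_model`.
#' @return character vector.
#' @export
covariate_names <- function(model) {
  unique(c(model$feature_spec$v1, stats::na.omit(model$feature_spec$v2)))
}

#' Choose the 12- or 36-month version of each variable
#'
#' Fits one model on both trailing-window versions of every variable
#' (columns `<var>_12m` / `<var>_36m`), computes permutation importance, and
#' keeps the window version with the higher importance for each variable.
#' Ties keep the 12-month version (the shorter memory is the more
#' parsimonious choice).
#'
#' @param pres_cov,bg_cov covariate tables containing both window versions.
#' @param seed seed for the permutation importances.
#' @param beta_multiplier,tol,max_iter passed to [fit_maxent()].
#' @param n_perm permutations per covariate.
#' @return list: `choices` (data.frame `variable, imp_12m, imp_36m, chosen`),
#'   `selected` (chosen column names), `importance`, and the 16-covariate
#'   `model`.
#' @export
select_window_per_variable <- function(pres_cov, bg_cov, seed = 1L,
                                       beta_multiplier = 1, tol = 1e-7,
                                       max_iter = 1000L, n_perm = 1L,
                                       permute = sample.int) {
  cols <- grep("_(12|36)m$", colnames(bg_cov), value = TRUE)
  vars <- unique(sub("_(12|36)m$", "", cols))
  bgf <- build_features(bg_cov[, cols, drop = FALSE])
  prf <- build_features(pres_cov[, cols, drop = FALSE],
                        spec = attr(bgf, "feature_spec"))
  model <- fit_maxent(prf, bgf, beta_multiplier = beta_multiplier,
                      tol = tol, max_iter = max_iter)
  imp <- permutation_importance(model, pres_cov[, cols, drop = FALSE],
                                bg_cov[, cols, drop = FALSE], seed = seed,
                                n_perm = n_perm, permute = permute)
  choices <- do.call(rbind, lapply(vars, function(v) {
    i12 <- imp[[paste0(v, "_12m")]]
    i36 <- imp[[paste0(v, "_36m")]]
    data.frame(variable = v, imp_12m = i12, imp_36m = i36,
               chosen = if (i36 > i12) paste0(v, "_36m") else
                 paste0(v, "_12m"))
  }))
  list(choices = choices, selected = choices$chosen, importance = imp,
       model = model)
}

#' Flag highly correlated covariate pairs
#'
#' Pairwise Pearson correlations on the pooled presence + background table;
#' pairs at or above the threshold in absolute value are flagged.
#' Report-only: nothing is dropped automatically.
#'
#' @param cov_table pooled covariate table (at least two columns).
#' @param threshold absolute correlation flag level.
#' @return list: `correlations` (matrix), `flagged` (data.frame
#'   `var1, var2, r`).
#' @export
correlation_screen <- function(cov_table, threshold = 0.85) {
  cov_table <- as.matrix(cov_table)
  if (ncol(cov_table) < 2L) stop("need at least two covariates")
  r <- stats::cor(cov_table)
  idx <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = colnames(r)[idx[, 1L]],
                        var2 = colnames(r)[idx[, 2L]],
                        r = r[idx])
  list(correlations = r, flagged = flagged, threshold = threshold)
}

#' k-fold cross-validation of the maximum-entropy model
#'
#' Presences are partitioned into `k` random folds; each fold's model is
#' fitted on the remaining presences against the full background and scored
#' by AUC on the held-out presences versus the background.
#'
#' @param pres_cov,bg_cov covariate tables.
#' @param k number of folds (at most the number of presences).
#' @param seed seed for the fold assignment.
#' @param beta_multiplier,tol,max_iter passed to [fit_maxent()].
#' @return list: `mean_auc`, `sd_auc`, `fold_auc`.
#' @export
cross_validate <- function(pres_cov, bg_cov, k = 10L, seed = 1L,
                           beta_multiplier = 1, tol = 1e-7,
                           max_iter = 1000L) {
  m <- nrow(pres_cov)
  if (k > m) stop("k exceeds the number of presences")
  bgf <- build_features(bg_cov)
  spec <- attr(bgf, "feature_spec")
  prf <- build_features(pres_cov, spec = spec)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), m)))
  fold_auc <- vapply(seq_len(k), function(i) {
    fit <- fit_maxent(prf[folds != i, , drop = FALSE], bgf,
                      beta_multiplier = beta_multiplier, tol = tol,
                      max_iter = max_iter)
    link <- feature_link(fit, prf[folds == i, , drop = FALSE])
    auc(link, feature_link(fit, bgf))
  }, numeric(1L))
  list(mean_auc = mean(fold_auc), sd_auc = stats::sd(fold_auc),
       fold_auc = fold_auc)
}
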