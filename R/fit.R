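#' Specify a panel regression model
#'
#' Describes one estimated model: the outcome, the focal production
#' diversity regressor (optionally interacted with distance to the
#' nearest urban centre), the socio-economic controls, which regressors
#' get Mundlak household time-averages, the estimator and family, and
#' the clustering level for robust standard errors.
#'
#' The correlated random effects (CRE) estimator augments pooled OLS
#' with household means (over each household's observed waves) of the
#' potentially endogenous regressors, absorbing time-invariant
#' unobserved heterogeneity while keeping coefficients on
#' time-invariant variables estimable. `mundlak = "paper"` averages the
#' focal regressor(s) and all time-varying controls; `mundlak = "all"`
#' additionally averages the wave dummies, which makes CRE coefficients
#' on time-varying regressors agree with the fixed-effects within
#' estimator exactly, also on unbalanced panels.
#'
#' @param outcome outcome column name (e.g. `"hdds"`, `"latent_hdds"`,
#'   `"hdds_own"`, `"hdds_market"`).
#' @param focal focal regressor column (e.g. `"fpd_species"`,
#'   `"fpd_groups"`, `"lpd"`); may be `NULL` for covariate-only models.
#' @param covariates character vector of control columns.
#' @param interaction_distance logical; add `focal * distance_urban`.
#' @param mundlak `"paper"`, `"all"`, `"none"`, or explicit column names.
#' @param estimator `"cre"`, `"pooled"` (no Mundlak terms) or `"fe"`.
#' @param family `"linear"` or `"poisson"` (log link).
#' @param cluster column with cluster ids (default household).
#' @param wave_dummies,country_dummies include survey-round dummies /
#'   country dummies (country dummies only enter pooled multi-country
#'   samples and are dropped automatically for single-country data and
#'   for the FE estimator).
#' @param extra additional regressors entered linearly without Mundlak
#'   averaging (e.g. the number of sampled farmers at a spatial scale).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcome, focal = "fpd_groups",
                       covariates = default_covariates(),
                       interaction_distance = FALSE,
                       mundlak = c("paper", "all", "none"),
                       estimator = c("cre", "pooled", "fe"),
                       family = c("linear", "poisson"),
                       cluster = "household_id",
                       wave_dummies = TRUE, country_dummies = TRUE,
                       extra = character()) {
  if (!is.character(mundlak)) stop("mundlak must be character")
  if (all(mundlak %in% c("paper", "all", "none"))) mundlak <- match.arg(mundlak)
  estimator <- match.arg(estimator)
  if (estimator == "pooled" && identical(mundlak, "paper")) mundlak <- "none"
  structure(list(outcome = outcome, focal = focal, covariates = covariates,
                 interaction_distance = isTRUE(interaction_distance),
                 mundlak = mundlak, estimator = estimator,
                 family = match.arg(family), cluster = cluster,
                 wave_dummies = isTRUE(wave_dummies),
                 country_dummies = isTRUE(country_dummies),
                 extra = extra),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
default_covariates <- function() {
  c("head_sex", "head_age", "head_literate", "landholding", "phone",
    "motorbike", "electricity", "offfarm_wage", "self_employment",
    "cash_crop", "weather_shock", "distance_urban")
}

# columns with any within-household variation
time_varying_cols <- function(X, hh) {
  apply(X, 2L, function(v) {
    r <- range(tapply(v, hh, function(x) diff(range(x))))
    r[2L] > 1e-12
  })
}

#' Build the regression design matrix
#'
#' Assembles intercept, focal regressor (and its distance interaction
#' when requested), controls, extra regressors, wave dummies, country
#' dummies (multi-country pooled samples only) and Mundlak household
#' time-averages, per the [model_spec()]. Rows with missing values in
#' any used column are dropped and counted. Reference categories are
#' the first wave and the alphabetically first country.
#'
#' @param data a household-wave analysis table (see
#'   [build_analysis_frame()]).
#' @param spec a [model_spec()].
#' @return list with `X` (design matrix), `y`, `cluster`, `household`,
#'   `n_dropped_missing`, and `mundlak_cols`.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  base_cols <- c(spec$focal, spec$covariates, spec$extra,
                 if (spec$interaction_distance) "distance_urban")
  base_cols <- unique(base_cols)
  need <- unique(c(spec$outcome, base_cols, spec$cluster, "household_id",
                   "country", "wave"))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("analysis table is missing columns: ", paste(miss, collapse = ", "))
  use <- stats::complete.cases(data[need])
  rows_used <- use
  n_dropped <- sum(!use)
  d <- data[use, , drop = FALSE]
  if (!nrow(d)) stop("empty estimation sample after dropping missing rows")

  y <- as.numeric(d[[spec$outcome]])
  hh <- as.character(d$household_id)
  cl <- as.character(d[[spec$cluster]])

  cols <- list(`(Intercept)` = rep(1, nrow(d)))
  for (v in c(spec$focal, setdiff(spec$covariates, spec$focal), spec$extra))
    cols[[v]] <- as.numeric(d[[v]])
  if (spec$interaction_distance) {
    if (is.null(spec$focal)) stop("interaction requires a focal regressor")
    cols[[paste0(spec$focal, ":distance_urban")]] <-
      as.numeric(d[[spec$focal]]) * as.numeric(d$distance_urban)
    if (!"distance_urban" %in% names(cols))
      cols[["distance_urban"]] <- as.numeric(d$distance_urban)
  }
  wave_cols <- character()
  if (spec$wave_dummies) {
    for (w in sort(unique(d$wave))[-1L]) {
      nm <- paste0("wave_", w)
      cols[[nm]] <- as.numeric(d$wave == w)
      wave_cols <- c(wave_cols, nm)
    }
  }
  if (spec$country_dummies && spec$estimator != "fe") {
    for (co in sort(unique(d$country))[-1L])
      cols[[paste0("country_", co)]] <- as.numeric(d$country == co)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (anyDuplicated(colnames(X)))
    stop("duplicate design columns: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))

  mundlak_cols <- character()
  if (spec$estimator == "cre" && !identical(spec$mundlak, "none")) {
    cand <- setdiff(colnames(X), "(Intercept)")
    tv <- time_varying_cols(X[, cand, drop = FALSE], hh)
    mset <- if (identical(spec$mundlak, "paper")) {
      intersect(cand[tv], c(spec$focal,
                            paste0(spec$focal, ":distance_urban"),
                            spec$covariates))
    } else if (identical(spec$mundlak, "all")) {
      cand[tv]
    } else intersect(spec$mundlak, cand[tv])
    if (length(mset)) {
      M <- household_means(X[, mset, drop = FALSE], hh)
      colnames(M) <- paste0("mean_", mset)
      # drop averaged columns that are constant across households
      keep <- apply(M, 2L, function(v) diff(range(v)) > 1e-12)
      M <- M[, keep, drop = FALSE]
      mundlak_cols <- colnames(M)
      X <- cbind(X, M)
    }
  }
  list(X = X, y = y, cluster = cl, household = hh,
       n_dropped_missing = n_dropped, mundlak_cols = mundlak_cols,
       wave_cols = wave_cols, rows_used = rows_used)
}

# household means of each column, expanded back to rows
household_means <- function(X, hh) {
  g <- match(hh, unique(hh))
  cnt <- tabulate(g)
  S <- rowsum(X, g, reorder = FALSE)
  (S / cnt)[g, , drop = FALSE]
}

#' Ordinary least squares with cluster-robust covariance
#'
#' Solves the least-squares problem by QR decomposition and computes
#' the CR1 cluster-robust sandwich covariance
#' `c * (X'X)^-1 (sum_g u_g u_g') (X'X)^-1` with score sums
#' `u_g = sum_{i in g} w_i x_i e_i` and small-sample factor
#' `c = G/(G-1) * (N-1)/(N-K)`. Confidence intervals and p-values use
#' the normal approximation. With every observation its own cluster,
#' CR1 equals the HC1 heteroskedasticity-robust covariance.
#'
#' @param X design matrix (with intercept column if wanted).
#' @param y outcome vector.
#' @param cluster cluster ids (character/integer), length `nrow(X)`.
#' @param weights optional non-negative observation weights.
#' @param on_collinear `"error"` (default) or `"drop"` rank-deficient
#'   columns.
#' @param spec optional [model_spec()] echoed into the result.
#' @param extra_df extra model degrees of freedom already absorbed
#'   (used by the FE estimator for the household means).
#' @return an object of class `dietpanel_fit`.
#' @export
fit_ols <- function(X, y, cluster, weights = NULL,
                    on_collinear = c("error", "drop"), spec = NULL,
                    extra_df = 0L) {
  on_collinear <- match.arg(on_collinear)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, length(cluster) == n)
  if (length(unique(cluster)) < 2L) stop("need at least 2 clusters")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(all(w >= 0), length(w) == n)

  sw <- sqrt(w)
  qrx <- qr(X * sw)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    if (on_collinear == "error")
      stop("design matrix is rank deficient; collinear candidates: ",
           paste(dropped, collapse = ", "))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
    qrx <- qr(X * sw)
  } else dropped <- character()
  k <- ncol(X)
  if (n <= k + extra_df) stop("more parameters than observations")

  beta <- qr.coef(qrx, y * sw)
  fitted <- drop(X %*% beta)
  e <- y - fitted

  vc <- cr1_vcov(X, e, cluster, w, k_model = k + extra_df)
  wm <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * e^2) / sum(w * (y - wm)^2)

  new_fit(beta = beta, vcov = vc$vcov, n_obs = n,
          n_clusters = vc$G, fit_stat = c(r_squared = r2),
          residuals = e, fitted = fitted, family = "linear",
          estimator = if (is.null(spec)) "ols" else spec$estimator,
          spec = spec, dropped = dropped, weights = weights)
}

# CR1 cluster-robust sandwich for a fitted score x_i * e_i * w_i
cr1_vcov <- function(X, e, cluster, w, k_model) {
  n <- nrow(X)
  U <- rowsum(X * (w * e), cluster, reorder = FALSE)
  G <- nrow(U)
  meat <- crossprod(U)
  bread <- chol2inv(chol(crossprod(X * sqrt(w))))
  adj <- G / (G - 1) * (n - 1) / (n - k_model)
  V <- adj * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  list(vcov = (V + t(V)) / 2, G = G)
}

#' Fixed-effects (within) estimator
#'
#' Demeans the outcome and all time-varying regressors within
#' households and runs OLS on the transformed data. Time-invariant
#' regressors (and the intercept, country dummies and Mundlak terms,
#' which the transform annihilates) are dropped and recorded. The
#' degrees-of-freedom correction accounts for the absorbed household
#' means; standard errors are CR1 cluster-robust.
#'
#' @param data analysis table (see [build_analysis_frame()]).
#' @param spec a [model_spec()] with `estimator = "fe"`.
#' @param weights optional observation weights.
#' @return a `dietpanel_fit`.
#' @export
fit_fe <- function(data, spec, weights = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  spec$estimator <- "fe"
  des <- build_design(data, spec)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(data))
    weights <- weights[des$rows_used]
  }
  X <- des$X[, setdiff(colnames(des$X), "(Intercept)"), drop = FALSE]
  hh <- des$household
  Xd <- X - household_means(X, hh)
  yd <- des$y - drop(household_means(matrix(des$y), hh))
  tv <- apply(Xd, 2L, function(v) max(abs(v)) > 1e-10)
  dropped_ti <- colnames(Xd)[!tv]
  Xd <- Xd[, tv, drop = FALSE]
  if (!ncol(Xd)) stop("no within-household variation in any regressor")
  if (!is.null(spec$focal) && !(spec$focal %in% colnames(Xd)))
    stop("no within-household variation in focal regressor ", spec$focal)
  G_abs <- length(unique(hh))
  fit <- fit_ols(Xd, yd, des$cluster, weights = weights,
                 on_collinear = "drop", spec = spec, extra_df = G_abs)
  fit$dropped <- union(fit$dropped, dropped_ti)
  fit$n_dropped_missing <- des$n_dropped_missing
  fit
}

#' Poisson quasi-maximum-likelihood with cluster-robust covariance
#'
#' Log-link Poisson regression fitted by Newton–Raphson with analytic
#' gradient and Hessian and step-halving, converging when the maximum
#' absolute score falls below `1e-8` (relative to scale) within 100
#' iterations. The covariance is the CR1 cluster-robust sandwich on the
#' quasi-score, so only the conditional mean needs to be correct.
#'
#' @inheritParams fit_ols
#' @return a `dietpanel_fit` with log-likelihood as fit statistic.
#' @export
fit_poisson <- function(X, y, cluster, weights = NULL,
                        on_collinear = c("error", "drop"), spec = NULL) {
  on_collinear <- match.arg(on_collinear)
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(y < 0) || any(y != floor(y)))
    stop("Poisson outcome must be non-negative integers")
  if (all(y == 0))
    stop("all-zero outcome: mean zero is not representable with a finite intercept")
  if (length(unique(cluster)) < 2L) stop("need at least 2 clusters")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    if (on_collinear == "error")
      stop("design matrix is rank deficient; collinear candidates: ",
           paste(dropped, collapse = ", "))
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  } else dropped <- character()
  k <- ncol(X)

  beta <- numeric(k)
  names(beta) <- colnames(X)
  if ("(Intercept)" %in% colnames(X))
    beta["(Intercept)"] <- log(sum(w * y) / sum(w))
  ll <- function(b) {
    eta <- drop(X %*% b); sum(w * (y * eta - exp(eta)))
  }
  ll_old <- ll(beta)
  trace <- numeric(0)
  converged <- FALSE
  scale0 <- max(1, sum(w * y))
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    score <- drop(crossprod(X, w * (y - mu)))
    trace[it] <- max(abs(score))
    if (max(abs(score)) < 1e-8 * scale0) { converged <- TRUE; break }
    H <- crossprod(X * sqrt(w * mu))
    step <- tryCatch(solve(H, score),
                     error = function(e) stop("singular Hessian at iteration ",
                                              it, call. = FALSE))
    lam <- 1
    repeat {
      ll_new <- ll(beta + lam * step)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) stop("step-halving failed at iteration ", it)
    }
    beta <- beta + lam * step
    ll_old <- ll(beta)
  }
  if (!converged)
    stop("Poisson fit did not converge in 100 iterations; |score| trace: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "))

  mu <- exp(drop(X %*% beta))
  e <- y - mu
  U <- rowsum(X * (w * e), cluster, reorder = FALSE)
  G <- nrow(U)
  bread <- chol2inv(chol(crossprod(X * sqrt(w * mu))))
  adj <- G / (G - 1) * (n - 1) / (n - k)
  V <- adj * bread %*% crossprod(U) %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  loglik <- sum(w * (y * log(ifelse(mu > 0, mu, 1)) - mu - lgamma(y + 1)))

  new_fit(beta = beta, vcov = (V + t(V)) / 2, n_obs = n, n_clusters = G,
          fit_stat = c(loglik = loglik), residuals = e, fitted = mu,
          family = "poisson",
          estimator = if (is.null(spec)) "poisson" else spec$estimator,
          spec = spec, dropped = dropped, weights = weights)
}

#' Fit a specified model to an analysis table
#'
#' The single entry point tying [model_spec()] to the estimators:
#' builds the design (Mundlak terms, dummies, interaction) and
#' dispatches to [fit_ols()], [fit_fe()] or [fit_poisson()].
#'
#' @param data analysis table from [build_analysis_frame()].
#' @param spec a [model_spec()].
#' @param weights optional observation weights (e.g. from
#'   [ipw_attrition_weights()]), matched to `data` rows.
#' @param on_collinear passed through to the estimator.
#' @return a `dietpanel_fit`.
#' @export
fit_model <- function(data, spec, weights = NULL,
                      on_collinear = c("error", "drop")) {
  stopifnot(inherits(spec, "model_spec"))
  on_collinear <- match.arg(on_collinear)
  if (spec$estimator == "fe") {
    if (spec$family == "poisson")
      stop("fixed-effects Poisson is not implemented; use Poisson CRE")
    return(fit_fe(data, spec, weights = weights))
  }
  des <- build_design(data, spec)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(data))
    weights <- weights[des$rows_used]
  }
  fit <- if (spec$family == "poisson")
    fit_poisson(des$X, des$y, des$cluster, weights = weights,
                on_collinear = on_collinear, spec = spec)
  else
    fit_ols(des$X, des$y, des$cluster, weights = weights,
            on_collinear = on_collinear, spec = spec)
  fit$n_dropped_missing <- des$n_dropped_missing
  fit
}

#' Marginal effect of the focal regressor over a distance grid
#'
#' For a model with a focal-by-distance interaction, the marginal
#' effect at distance `d` is `beta_focal + beta_int * d` with
#' delta-method standard error
#' `sqrt(v11 + d^2 v22 + 2 d v12)` (exact, since the effect is linear
#' in the coefficients).
#'
#' @param fit a `dietpanel_fit` containing the focal and interaction
#'   coefficients.
#' @param focal focal coefficient name.
#' @param interaction interaction coefficient name (default
#'   `focal:distance_urban`).
#' @param at numeric grid of distances (km).
#' @return data.frame `distance, effect, se, ci_lower, ci_upper`.
#' @export
marginal_effects <- function(fit, focal = fit$spec$focal,
                             interaction = paste0(focal, ":distance_urban"),
                             at = seq(0, 100, by = 10)) {
  b <- coef(fit)
  if (!(focal %in% names(b))) stop("no coefficient named ", focal)
  if (!(interaction %in% names(b)))
    stop("no interaction coefficient named ", interaction)
  V <- fit$vcov[c(focal, interaction), c(focal, interaction)]
  eff <- b[focal] + b[interaction] * at
  se <- sqrt(V[1, 1] + at^2 * V[2, 2] + 2 * at * V[1, 2])
  data.frame(distance = at, effect = unname(eff), se = se,
             ci_lower = unname(eff) - 1.96 * se,
             ci_upper = unname(eff) + 1.96 * se)
}

#' Compare subsistence and non-subsistence households
#'
#' Welch two-sample comparison (unequal variances) of a score variable
#' between households obtaining more than half of their consumption
#' value from own production and the rest.
#'
#' @param scores output of [score_panel()].
#' @param variable column to compare (e.g. `"fpd_groups"`, `"hdds"`).
#' @return data.frame with group means, difference, Welch t statistic,
#'   degrees of freedom and p-value.
#' @export
group_comparison <- function(scores, variable = c("fpd_groups", "hdds")) {
  variable <- variable[1L]
  if (!variable %in% names(scores)) stop("no column ", variable)
  ok <- !is.na(scores$subsistence) & !is.na(scores[[variable]])
  x <- scores[[variable]][ok & scores$subsistence == 1L]
  y <- scores[[variable]][ok & scores$subsistence == 0L]
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need at least 2 observations (got ",
         length(x), " subsistence, ", length(y), " non-subsistence)")
  tt <- stats::t.test(x, y)
  data.frame(variable = variable,
             mean_subsistence = mean(x), mean_non_subsistence = mean(y),
             difference = mean(x) - mean(y),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, n_subsistence = length(x),
             n_non_subsistence = length(y))
}

#' Inverse-probability weights for panel attrition
#'
#' Estimates, for each survey wave after the first, a logistic model of
#' retention on baseline (first-wave) covariates among households still
#' present at the previous wave, then weights each retained
#' household-wave by the inverse of its cumulative predicted retention
#' probability. Weights are normalised to mean one within wave, so
#' weighted and unweighted fits coincide when attrition is unrelated to
#' the covariates.
#'
#' @param panel a [panel_dataset] with an `attrition` table.
#' @param covariates baseline covariate columns for the retention
#'   model; `NULL` fits intercept-only models.
#' @return data.frame `household_id, wave, weight` for observed
#'   household-waves.
#' @export
ipw_attrition_weights <- function(panel,
                                  covariates = c("head_literate",
                                                 "distance_urban", "phone")) {
  stopifnot(inherits(panel, "panel_dataset"))
  att <- panel$attrition
  if (is.null(att)) stop("panel has no attrition/retention table")
  hh <- panel$households
  base <- hh[hh$wave == 1L, , drop = FALSE]
  bm <- match(att$household_id, base$household_id)
  if (anyNA(bm)) stop("attrition table households missing baseline wave")

  att <- att[order(att$household_id, att$wave), , drop = FALSE]
  bm <- match(att$household_id, base$household_id)
  prob <- rep(1, nrow(att))
  for (w in sort(unique(att$wave[att$wave > 1L]))) {
    at_w <- att$wave == w
    prev <- att$retained[match(paste(att$household_id, w - 1L, sep = "\r"),
                               paste(att$household_id, att$wave, sep = "\r"))]
    risk <- at_w & !is.na(prev) & prev == 1L
    if (!any(risk)) next
    yv <- att$retained[risk]
    if (all(yv == 1L)) { prob[risk] <- 1; next }
    if (all(yv == 0L)) { prob[risk] <- NA; next }
    Xw <- matrix(1, sum(risk), 1L, dimnames = list(NULL, "(Intercept)"))
    if (length(covariates))
      Xw <- cbind(Xw, as.matrix(base[bm[risk], covariates, drop = FALSE]))
    fit <- suppressWarnings(
      stats::glm.fit(Xw, yv, family = stats::binomial()))
    p <- fit$fitted.values
    if (any(p < 1e-8) || any(p > 1 - 1e-8))
      stop("separation in the wave-", w, " retention model")
    prob[risk] <- p
  }
  # cumulative retention probability up to each wave
  cum <- stats::ave(prob, att$household_id, FUN = cumprod)
  keep <- att$retained == 1L
  out <- data.frame(household_id = att$household_id[keep],
                    wave = att$wave[keep],
                    weight = 1 / cum[keep], stringsAsFactors = FALSE)
  out$weight <- out$weight /
    stats::ave(out$weight, out$wave, FUN = mean)
  out
}

#' Assemble the household-wave analysis table
#'
#' Merges the household roster, the diversity scores and (when present)
#' the generator's latent linear-mode outcome into the flat table the
#' estimators consume. Optionally attaches unit-level production
#' diversity from [join_lpd_to_households()].
#'
#' @param panel a [panel_dataset].
#' @param scores output of [score_panel()]; computed if `NULL`.
#' @param lpd optional output of [join_lpd_to_households()]; households
#'   without a valid unit at that scale are dropped.
#' @return data.frame keyed by (household_id, wave).
#' @export
build_analysis_frame <- function(panel, scores = NULL, lpd = NULL) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (is.null(scores)) scores <- score_panel(panel)
  d <- merge(panel$households, scores, by = c("household_id", "wave"),
             suffixes = c("", ".score"))
  d$cash_crop <- d$cash_crop.score  # scored indicator is authoritative
  d$cash_crop.score <- NULL
  if (!is.null(panel$truth) && !is.null(panel$truth$latent))
    d <- merge(d, panel$truth$latent, by = c("household_id", "wave"))
  if (!is.null(lpd))
    d <- merge(d, lpd, by = c("household_id", "wave"))
  d[order(d$household_id, d$wave), , drop = FALSE]
}

new_fit <- function(beta, vcov, n_obs, n_clusters, fit_stat, residuals,
                    fitted, family, estimator, spec, dropped, weights) {
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  tab <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se),
                    ci_lower = unname(beta - 1.96 * se),
                    ci_upper = unname(beta + 1.96 * se),
                    p_value = 2 * stats::pnorm(-abs(unname(z))),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = beta, vcov = vcov, coef_table = tab,
                 n_obs = n_obs, n_clusters = n_clusters,
                 fit_stat = fit_stat, residuals = residuals,
                 fitted = fitted, family = family, estimator = estimator,
                 spec = spec, dropped = dropped,
                 n_dropped_missing = 0L, weights = weights),
            class = "dietpanel_fit")
}
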