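test_that("OLS matches the normal-equations oracle and nails exact fits", {
  set.seed(40)
  n <- 40
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = runif(n), x3 = rbinom(n, 1, .4))
  y <- drop(X %*% c(1, 2, -1, 0.5)) + rnorm(n)
  cl <- sample(letters[1:8], n, replace = TRUE)
  fit <- fit_ols(X, y, cl)
  oracle <- solve(crossprod(X), crossprod(X, y))   # explicit (X'X)^-1 X'y
  expect_lt(max(abs(coef(fit) - oracle[, 1])), 1e-10)
  expect_equal(fit$n_clusters, length(unique(cl)))

  # exact linear relationship: coefficient 2, zero residual variance
  X2 <- cbind(x = 1:10)
  f2 <- fit_ols(X2, 2 * (1:10), cluster = rep(1:5, each = 2))
  expect_equal(unname(coef(f2)), 2)
  expect_equal(unname(sqrt(diag(vcov(f2)))), 0, tolerance = 1e-12)

  # rank deficiency is reported with the offending columns
  X3 <- cbind(X, dup = X[, "x1"])
  expect_error(fit_ols(X3, y, cl), "rank deficient.*dup")
})

test_that("CR1 equals HC1 when every observation is its own cluster", {
  set.seed(41)
  n <- 60
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- drop(X %*% c(1, 0.5)) + rnorm(n) * (1 + abs(X[, 2]))
  fit <- fit_ols(X, y, cluster = seq_len(n))
  e <- residuals(fit)
  XtXi <- solve(crossprod(X))
  hc1 <- n / (n - ncol(X)) * XtXi %*% crossprod(X * e) %*% XtXi
  expect_equal(unname(vcov(fit)), unname(hc1), tolerance = 1e-10)
})

test_that("cluster-robust covariance agrees with the sandwich package", {
  set.seed(42)
  n <- 120
  d <- data.frame(x = rnorm(n), g = sample(letters[1:10], n, replace = TRUE))
  d$y <- 1 + 0.5 * d$x + rnorm(n) + stats::ave(rnorm(n), d$g)
  X <- cbind(`(Intercept)` = 1, x = d$x)
  fit <- fit_ols(X, d$y, d$g)
  lmfit <- lm(y ~ x, data = d)
  V <- sandwich::vcovCL(lmfit, cluster = d$g, type = "HC1", cadjust = TRUE)
  expect_equal(unname(vcov(fit)), unname(V), tolerance = 1e-8)
  expect_lt(max(abs(coef(fit) - coef(lmfit))), 1e-10)
})

test_that("the within transform demeans and drops time-invariant terms", {
  hh <- c("a", "a", "b", "b")
  X <- cbind(y = c(3, 5, 1, 2))
  M <- X - dietpanel:::household_means(X, hh)
  expect_equal(M[, 1], c(-1, 1, -0.5, 0.5))

  p <- simulate_panel(linear_config(50))
  d <- build_analysis_frame(p)
  fe <- fit_model(d, model_spec("latent_hdds", focal = "fpd_species",
                                estimator = "fe"))
  expect_false("head_sex" %in% names(coef(fe)))
  expect_false("distance_urban" %in% names(coef(fe)))
  expect_true(any(c("head_sex", "distance_urban") %in% fe$dropped))
})

test_that("CRE and FE coefficients agree (Mundlak equivalence)", {
  # balanced panel, default mundlak set
  p <- simulate_panel(linear_config(51))
  d <- build_analysis_frame(p)
  cre <- fit_model(d, model_spec("latent_hdds", focal = "fpd_species",
                                 estimator = "cre"))
  fe <- fit_model(d, model_spec("latent_hdds", focal = "fpd_species",
                                estimator = "fe"))
  shared <- intersect(names(coef(fe)), names(coef(cre)))
  expect_gt(length(shared), 5)
  expect_lt(max(abs(coef(cre)[shared] - coef(fe)[shared])), 1e-8)

  # unbalanced panel: equivalence requires wave-dummy means too
  pu <- simulate_panel(linear_config(52, waves = 4L, attrition = 0.12))
  du <- build_analysis_frame(pu)
  cre_u <- fit_model(du, model_spec("latent_hdds", focal = "fpd_species",
                                    estimator = "cre", mundlak = "all"))
  fe_u <- fit_model(du, model_spec("latent_hdds", focal = "fpd_species",
                                   estimator = "fe"))
  shared <- intersect(names(coef(fe_u)), names(coef(cre_u)))
  expect_lt(max(abs(coef(cre_u)[shared] - coef(fe_u)[shared])), 1e-8)
})

test_that("CRE removes the confounding bias that pooled OLS suffers", {
  bias_pool <- bias_cre <- numeric(5)
  for (r in 1:5) {
    p <- simulate_panel(linear_config(60 + r, kappa = 0.5))
    d <- build_analysis_frame(p)
    b_pool <- coef(fit_model(d, model_spec("latent_hdds", "fpd_species",
                                           estimator = "pooled")))["fpd_species"]
    b_cre <- coef(fit_model(d, model_spec("latent_hdds", "fpd_species",
                                          estimator = "cre")))["fpd_species"]
    bias_pool[r] <- b_pool - 0.044
    bias_cre[r] <- b_cre - 0.044
  }
  expect_gt(abs(mean(bias_pool)), 5 * abs(mean(bias_cre)))
})

test_that("Poisson fits reproduce closed forms and glm", {
  X <- cbind(`(Intercept)` = rep(1, 3))
  f <- fit_poisson(X, c(1, 2, 3), cluster = 1:3)
  expect_equal(unname(coef(f)), log(2), tolerance = 1e-10)

  set.seed(43)
  n <- 400
  x <- rnorm(n)
  y <- rpois(n, exp(0.5 + 0.3 * x))
  X2 <- cbind(`(Intercept)` = 1, x = x)
  cl <- sample(1:40, n, replace = TRUE)
  f2 <- fit_poisson(X2, y, cl)
  g <- glm(y ~ x, family = poisson())
  expect_lt(max(abs(coef(f2) - coef(g))), 1e-8)
  expect_equal(unname(f2$fit_stat["loglik"]), as.numeric(logLik(g)),
               tolerance = 1e-8)

  expect_error(fit_poisson(X2, rep(0L, n), cl), "all-zero")
  expect_error(fit_poisson(X2, y - 0.5, cl), "non-negative integers")
})

test_that("Poisson recovers a known slope within Monte-Carlo error", {
  set.seed(44)
  n <- 5000
  x <- rnorm(n)
  y <- rpois(n, exp(1 + 0.1 * x))
  f <- fit_poisson(cbind(`(Intercept)` = 1, x = x), y, cluster = seq_len(n))
  se <- sqrt(vcov(f)["x", "x"])
  expect_lt(abs(coef(f)["x"] - 0.1), 3 * se)
})

test_that("interaction marginal effects follow the delta method exactly", {
  p <- simulate_panel(linear_config(53, true_beta_interaction = 0.002))
  d <- build_analysis_frame(p)
  fit <- fit_model(d, model_spec("latent_hdds", focal = "fpd_species",
                                 interaction_distance = TRUE,
                                 estimator = "cre"))
  me <- marginal_effects(fit, at = c(0, 50))
  b <- coef(fit)
  expect_equal(me$effect[1], unname(b["fpd_species"]))
  expect_equal(me$se[1],
               unname(sqrt(vcov(fit)["fpd_species", "fpd_species"])))
  expect_equal(me$effect[2],
               unname(b["fpd_species"] + 50 * b["fpd_species:distance_urban"]))

  # parametric-bootstrap oracle for the delta-method SE
  V <- vcov(fit)[c("fpd_species", "fpd_species:distance_urban"),
                 c("fpd_species", "fpd_species:distance_urban")]
  set.seed(7)
  draws <- matrix(rnorm(5000 * 2), ncol = 2) %*% chol(V)
  boot_se <- sd(draws[, 1] + 50 * draws[, 2])
  expect_lt(abs(me$se[2] - boot_se) / boot_se, 0.05)
  expect_error(marginal_effects(fit, interaction = "nope"), "interaction")
})

test_that("the arithmetic of a marginal effect is beta1 + beta2 * d", {
  fake <- structure(list(
    coefficients = c(f = 0.10, `f:distance_urban` = -0.001),
    vcov = diag(c(1e-4, 1e-8)) |>
      `dimnames<-`(list(c("f", "f:distance_urban"),
                        c("f", "f:distance_urban"))),
    spec = list(focal = "f")), class = "dietpanel_fit")
  me <- marginal_effects(fake, focal = "f", at = 50)
  expect_equal(me$effect, 0.05)
})

test_that("Welch comparison behaves at the boundary and under shift", {
  sc <- data.frame(fpd_groups = c(1, 2, 3, 1, 2, 3),
                   hdds = c(4, 5, 6, 4, 5, 6),
                   subsistence = c(1, 1, 1, 0, 0, 0))
  r <- group_comparison(sc, "fpd_groups")
  expect_equal(r$difference, 0)
  expect_equal(r$statistic, 0)

  set.seed(45)
  sc2 <- data.frame(hdds = c(rnorm(500, 5), rnorm(500, 6)),
                    fpd_groups = 0,
                    subsistence = rep(c(1L, 0L), each = 500))
  r2 <- group_comparison(sc2, "hdds")
  expect_lt(r2$p_value, 0.05)
  expect_lt(r2$difference, 0)

  sc3 <- data.frame(hdds = c(1, rnorm(10)), fpd_groups = 0,
                    subsistence = c(1L, rep(0L, 10)))
  expect_error(group_comparison(sc3, "hdds"), "at least 2")
})

test_that("attrition weights reduce to identity without selective dropout", {
  p0 <- simulate_panel(structural_config(55))
  pa <- apply_attrition(generator_config(
    seed = 55, districts_per_country = 2, towns_per_district = 3,
    villages_per_town = 3, households_per_village = 8,
    waves_per_country = 3, attrition_base_rate = 0), p0)
  w <- ipw_attrition_weights(pa)
  expect_true(all(w$weight == 1))
  d <- build_analysis_frame(pa, score_panel(pa))
  dw <- merge(d, w, by = c("household_id", "wave"))
  spec <- model_spec("hdds", focal = "fpd_groups", estimator = "cre")
  f_u <- fit_model(dw, spec)
  f_w <- fit_model(dw, spec, weights = dw$weight)
  expect_equal(coef(f_w), coef(f_u), tolerance = 1e-12)
})

test_that("covariate-free retention models give constant weights per wave", {
  pa <- simulate_panel(structural_config(56, attrition = 0.3))
  w <- ipw_attrition_weights(pa, covariates = NULL)
  spread <- tapply(w$weight, w$wave, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
  expect_equal(as.vector(tapply(w$weight, w$wave, mean)), rep(1, 3),
               tolerance = 1e-12)
})

test_that("weights rise with estimated dropout propensity", {
  pa <- simulate_panel(structural_config(57, attrition = 0.25))
  w <- ipw_attrition_weights(pa)
  base <- pa$households[pa$households$wave == 1L, ]
  m <- merge(w[w$wave == 3L, ], base[, c("household_id", "head_literate")])
  # literacy lowers dropout, hence lowers the weight
  expect_lt(mean(m$weight[m$head_literate == 1L]),
            mean(m$weight[m$head_literate == 0L]))
  # weighted fit stays consistent with the generator truth
  pl <- simulate_panel(linear_config(58, waves = 4L, attrition = 0.2))
  dl <- build_analysis_frame(pl)
  wl <- ipw_attrition_weights(pl)
  dlw <- merge(dl, wl, by = c("household_id", "wave"))
  f <- fit_model(dlw, model_spec("latent_hdds", "fpd_species",
                                 estimator = "cre"), weights = dlw$weight)
  se <- f$coef_table$se[f$coef_table$term == "fpd_species"]
  expect_lt(abs(coef(f)["fpd_species"] - 0.044), 3 * se)
})

test_that("fit objects expose the standard modelling interface", {
  p <- simulate_panel(linear_config(59))
  d <- build_analysis_frame(p)
  fit <- fit_model(d, model_spec("latent_hdds", focal = "fpd_species",
                                 estimator = "cre"))
  expect_s3_class(fit, "dietpanel_fit")
  expect_equal(nobs(fit), fit$n_obs)
  ci <- confint(fit, "fpd_species")
  expect_lt(ci[1], coef(fit)["fpd_species"])
  expect_gt(ci[2], coef(fit)["fpd_species"])
  expect_equal(length(residuals(fit)), nobs(fit))
  expect_equal(fitted(fit) + residuals(fit), d$latent_hdds[
    stats::complete.cases(d[c("latent_hdds", "fpd_species")])],
    ignore_attr = TRUE)
  expect_output(print(fit), "cre linear model")
  expect_output(print(summary(fit)), "cluster-robust")
  pr <- predict(fit, d)
  expect_equal(unname(pr), unname(fitted(fit)), tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nobs(fit), 2L))
})
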