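#' Descriptive table of dietary and production diversity
#'
#' Pooled and per-country means with standard deviations for the
#' household dietary diversity score (total and by source), the value
#' shares of each food source, and — among households with own farm
#' production — the farm production diversity metrics and the share of
#' farms growing non-food cash crops.
#'
#' @param panel a [panel_dataset].
#' @param scores output of [score_panel()]; computed if `NULL`.
#' @return tidy data.frame `statistic, sample, mean, sd, n` where
#'   `sample` is `"pooled"` or a country code.
#' @export
describe_panel <- function(panel, scores = NULL) {
  d <- build_analysis_frame(panel, scores)
  farm <- d$fpd_species > 0L
  one <- function(sub, label) {
    s <- function(stat, v) {
      v <- v[!is.na(v)]
      data.frame(statistic = stat, sample = label, mean = mean(v),
                 sd = stats::sd(v), n = length(v), stringsAsFactors = FALSE)
    }
    x <- d[sub, , drop = FALSE]
    xf <- d[sub & farm, , drop = FALSE]
    rbind(
      s("hdds", x$hdds), s("hdds_own", x$hdds_own),
      s("hdds_market", x$hdds_market), s("hdds_other", x$hdds_other),
      s("value_share_own_pct", 100 * x$own_value_share),
      s("fpd_species", xf$fpd_species),
      s("fpd_groups", xf$fpd_groups),
      s("crop_groups", xf$crop_groups),
      s("livestock_groups", xf$livestock_groups),
      s("cash_crop_pct", 100 * xf$cash_crop)
    )
  }
  out <- one(rep(TRUE, nrow(d)), "pooled")
  for (co in sort(unique(d$country))) out <- rbind(out, one(d$country == co, co))
  rownames(out) <- NULL
  out
}

# countries with at least two observed waves (others cannot support
# within-household estimation and are skipped with a warning)
countries_estimable <- function(d) {
  co <- sort(unique(d$country))
  ok <- vapply(co, function(c) length(unique(d$wave[d$country == c])) >= 2L,
               TRUE)
  if (any(!ok))
    warning("skipping countries with <2 waves: ",
            paste(co[!ok], collapse = ", "))
  co[ok]
}

focal_row <- function(fit, metric, sample) {
  tab <- fit$coef_table
  r <- tab[tab$term == metric, , drop = FALSE]
  data.frame(metric = metric, sample = sample, estimate = r$estimate,
             se = r$se, ci_lower = r$ci_lower, ci_upper = r$ci_upper,
             p_value = r$p_value, n_obs = fit$n_obs,
             stringsAsFactors = FALSE)
}

#' Farm production diversity coefficient battery
#'
#' Fits the correlated random effects model of dietary diversity on
#' farm production diversity for both FPD metrics (species count and
#' food-group count), pooled over all countries and separately per
#' country, and returns the focal coefficient of each fit with its
#' cluster-robust 95% confidence interval.
#'
#' @param panel a [panel_dataset].
#' @param outcome outcome column; default `"latent_hdds"` when the
#'   panel carries a linear-mode latent outcome, else `"hdds"`.
#' @param scores optional precomputed [score_panel()] output.
#' @return tidy data.frame `metric, sample, estimate, se, ci_lower,
#'   ci_upper, p_value, n_obs`.
#' @export
run_fpd_models <- function(panel, outcome = NULL, scores = NULL) {
  d <- build_analysis_frame(panel, scores)
  if (is.null(outcome))
    outcome <- if ("latent_hdds" %in% names(d)) "latent_hdds" else "hdds"
  out <- NULL
  for (metric in c("fpd_species", "fpd_groups")) {
    spec <- model_spec(outcome, focal = metric, estimator = "cre")
    out <- rbind(out, focal_row(fit_model(d, spec), metric, "pooled"))
    for (co in countries_estimable(d)) {
      fit <- fit_model(d[d$country == co, , drop = FALSE], spec)
      out <- rbind(out, focal_row(fit, metric, co))
    }
  }
  rownames(out) <- NULL
  out
}

#' Socio-economic covariate battery
#'
#' One pooled correlated random effects fit (food-group FPD metric)
#' whose covariate coefficients — weather shocks, cash crops, off-farm
#' income, literacy, assets, head characteristics — are reported with
#' cluster-robust confidence intervals.
#'
#' @inheritParams run_fpd_models
#' @return the covariate rows of the coefficient table plus the fit as
#'   attribute `fit`.
#' @export
run_covariate_model <- function(panel, outcome = NULL, scores = NULL) {
  d <- build_analysis_frame(panel, scores)
  if (is.null(outcome))
    outcome <- if ("latent_hdds" %in% names(d)) "latent_hdds" else "hdds"
  spec <- model_spec(outcome, focal = "fpd_groups", estimator = "cre")
  fit <- fit_model(d, spec)
  tab <- fit$coef_table
  keep <- tab$term %in% spec$covariates
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Distance-interaction and subsistence batteries
#'
#' `run_distance_analysis()` fits the correlated random effects model
#' with a focal-by-distance interaction and evaluates the marginal
#' effect of FPD over a grid of distances to the nearest urban centre.
#' `run_subsistence_comparison()` compares production and dietary
#' diversity between subsistence households (own-production value share
#' strictly above 50%) and the rest with Welch tests.
#' `run_source_models()` fits separate models for dietary diversity
#' obtained from own production and from market purchases.
#'
#' @inheritParams run_fpd_models
#' @param focal focal FPD metric.
#' @param at distance grid in km.
#' @return see each description; all outputs are tidy data.frames.
#' @export
run_distance_analysis <- function(panel, outcome = NULL, scores = NULL,
                                  focal = "fpd_groups",
                                  at = seq(0, 100, by = 10)) {
  d <- build_analysis_frame(panel, scores)
  if (is.null(outcome))
    outcome <- if ("latent_hdds" %in% names(d)) "latent_hdds" else "hdds"
  spec <- model_spec(outcome, focal = focal, interaction_distance = TRUE,
                     estimator = "cre")
  fit <- fit_model(d, spec)
  me <- marginal_effects(fit, at = at)
  attr(me, "fit") <- fit
  me
}

#' @rdname run_distance_analysis
#' @export
run_subsistence_comparison <- function(panel, scores = NULL) {
  d <- build_analysis_frame(panel, scores)
  rbind(group_comparison(d[d$is_farmer == 1L, , drop = FALSE], "fpd_groups"),
        group_comparison(d, "hdds"))
}

#' @rdname run_distance_analysis
#' @export
run_source_models <- function(panel, scores = NULL, focal = "fpd_groups") {
  d <- build_analysis_frame(panel, scores)
  out <- NULL
  for (oc in c("hdds_own", "hdds_market")) {
    fit <- fit_model(d, model_spec(oc, focal = focal, estimator = "cre"))
    r <- focal_row(fit, focal, "pooled")
    r$outcome <- oc
    out <- rbind(out, r)
  }
  rownames(out) <- NULL
  out
}

#' Production diversity across spatial scales
#'
#' Aggregates food-group production diversity to village, town and
#' district scale, applies the village exclusions (missing village ids
#' and singleton-farm village-waves), forms one common estimation
#' sample valid at all scales, and fits four correlated random effects
#' models on that identical sample: own-farm food-group diversity, and
#' the unit-level diversity at each spatial scale with the number of
#' sampled farmers as an additional control.
#'
#' @inheritParams run_fpd_models
#' @return tidy data.frame `scale, estimate, se, ci_lower, ci_upper,
#'   p_value, n_obs, dropped` with one row per focal regressor.
#' @export
run_spatial_models <- function(panel, outcome = NULL, scores = NULL) {
  if (is.null(scores)) scores <- score_panel(panel)
  joined <- list()
  for (sc in c("village", "town", "district")) {
    rec <- aggregate_lpd(panel, sc)
    if (sc == "village") rec <- apply_village_exclusions(rec)
    joined[[sc]] <- join_lpd_to_households(panel, rec, sc)
  }
  keys <- lapply(joined, function(j) paste(j$household_id, j$wave, sep = "\r"))
  common <- Reduce(intersect, keys)
  if (!length(common)) stop("empty common estimation sample across scales")

  d0 <- build_analysis_frame(panel, scores)
  d0 <- d0[paste(d0$household_id, d0$wave, sep = "\r") %in% common, ,
           drop = FALSE]
  if (is.null(outcome))
    outcome <- if ("latent_hdds" %in% names(d0)) "latent_hdds" else "hdds"

  out <- NULL
  fits <- list()
  # own-farm scale
  spec <- model_spec(outcome, focal = "fpd_groups", estimator = "cre")
  fit <- fit_model(d0, spec, on_collinear = "drop")
  r <- focal_row(fit, "fpd_groups", "pooled"); r$scale <- "farm"
  r$dropped <- paste(fit$dropped, collapse = ";")
  out <- rbind(out, r); fits$farm <- fit
  for (sc in c("village", "town", "district")) {
    j <- joined[[sc]]
    d <- merge(d0, j, by = c("household_id", "wave"))
    spec <- model_spec(outcome, focal = "lpd", estimator = "cre",
                       extra = "n_farmers")
    fit <- fit_model(d, spec, on_collinear = "drop")
    if ("lpd" %in% names(coef(fit))) {
      r <- focal_row(fit, "lpd", "pooled")
    } else {
      r <- data.frame(metric = "lpd", sample = "pooled", estimate = NA_real_,
                      se = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                      p_value = NA_real_, n_obs = fit$n_obs)
    }
    r$scale <- sc
    r$dropped <- paste(fit$dropped, collapse = ";")
    out <- rbind(out, r); fits[[sc]] <- fit
  }
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Robustness battery
#'
#' Re-estimates the pooled FPD model under the alternative estimators
#' and samples: fixed effects, Poisson correlated random effects (on
#' the integer diet score), the farming subsample, the balanced panel,
#' and — when a retention table is available — the farmer sample with
#' inverse-probability attrition weights. Returns the focal coefficient
#' side by side with the main estimate.
#'
#' @inheritParams run_fpd_models
#' @param focal focal FPD metric.
#' @return tidy data.frame with one row per variant.
#' @export
run_robustness <- function(panel, outcome = NULL, scores = NULL,
                           focal = "fpd_groups") {
  if (is.null(scores)) scores <- score_panel(panel)
  d <- build_analysis_frame(panel, scores)
  if (is.null(outcome))
    outcome <- if ("latent_hdds" %in% names(d)) "latent_hdds" else "hdds"
  row_of <- function(fit, variant) {
    r <- focal_row(fit, focal, "pooled"); r$variant <- variant; r
  }
  cre <- model_spec(outcome, focal = focal, estimator = "cre")
  out <- row_of(fit_model(d, cre), "cre_main")
  # full Mundlak set (incl. wave-dummy means): the CRE fit whose
  # time-varying coefficients equal the FE estimator exactly
  out <- rbind(out, row_of(fit_model(d, model_spec(
    outcome, focal = focal, estimator = "cre", mundlak = "all")),
    "cre_full_mundlak"))
  out <- rbind(out, row_of(fit_model(d, model_spec(
    outcome, focal = focal, estimator = "fe")), "fe"))
  out <- rbind(out, row_of(fit_model(d, model_spec(
    "hdds", focal = focal, estimator = "cre", family = "poisson")),
    "poisson_cre"))
  farmers <- filter_sample(panel, "farmers_only")
  df <- build_analysis_frame(farmers, score_panel(farmers))
  out <- rbind(out, row_of(fit_model(df, cre), "farmers_only"))
  bal <- filter_sample(panel, "balanced")
  db <- build_analysis_frame(bal, score_panel(bal))
  out <- rbind(out, row_of(fit_model(db, cre), "balanced"))
  if (!is.null(panel$attrition)) {
    wt <- ipw_attrition_weights(panel)
    dw <- merge(df, wt, by = c("household_id", "wave"))
    out <- rbind(out, row_of(fit_model(dw, cre, weights = dw$weight),
                             "farmers_ipw"))
  }
  rownames(out) <- NULL
  out
}

#' Run a full analysis plan
#'
#' Orchestrates the descriptive and regression batteries on one panel
#' and returns all result tables in a named list. Every battery is a
#' deterministic function of the panel, so re-running reproduces the
#' outputs bit for bit.
#'
#' @param panel a [panel_dataset].
#' @param batteries subset of `c("table1", "fpd", "covariates",
#'   "distance", "subsistence", "sources", "spatial", "robustness")`.
#' @param outcome optional outcome override for the regression
#'   batteries.
#' @return named list of tidy result tables.
#' @export
run_analysis <- function(panel,
                         batteries = c("table1", "fpd", "covariates",
                                       "distance", "subsistence", "sources",
                                       "spatial", "robustness"),
                         outcome = NULL) {
  scores <- score_panel(panel)
  out <- list()
  if ("table1" %in% batteries) out$table1 <- describe_panel(panel, scores)
  if ("fpd" %in% batteries) out$fpd <- run_fpd_models(panel, outcome, scores)
  if ("covariates" %in% batteries)
    out$covariates <- run_covariate_model(panel, outcome, scores)
  if ("distance" %in% batteries)
    out$distance <- run_distance_analysis(panel, outcome, scores)
  if ("subsistence" %in% batteries)
    out$subsistence <- run_subsistence_comparison(panel, scores)
  if ("sources" %in% batteries) out$sources <- run_source_models(panel, scores)
  if ("spatial" %in% batteries)
    out$spatial <- run_spatial_models(panel, outcome, scores)
  if ("robustness" %in% batteries)
    out$robustness <- run_robustness(panel, outcome, scores)
  out
}
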