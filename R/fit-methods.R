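#' Methods for fitted panel models
#'
#' `dietpanel_fit` objects support the usual accessors: `coef`, `vcov`,
#' `confint` (normal approximation on cluster-robust SEs), `nobs`,
#' `residuals`, `fitted`, `predict` (on the stored fit or a new
#' analysis table, whose Mundlak means are recomputed within the new
#' table), `simulate` and a coefficient `plot`.
#'
#' @param x,object a `dietpanel_fit`.
#' @param ... unused.
#' @name dietpanel_fit-methods
NULL

#' @rdname dietpanel_fit-methods
#' @export
print.dietpanel_fit <- function(x, ...) {
  cat(sprintf("<dietpanel_fit> %s %s model, %d obs, %d clusters\n",
              x$estimator, x$family, x$n_obs, x$n_clusters))
  if (!is.null(x$spec))
    cat("  outcome:", x$spec$outcome,
        if (!is.null(x$spec$focal)) paste("  focal:", x$spec$focal), "\n")
  stat <- x$fit_stat
  cat(sprintf("  %s = %.4f\n", names(stat)[1L], stat[1L]))
  print(utils::head(x$coef_table, 8), digits = 4, row.names = FALSE)
  if (nrow(x$coef_table) > 8)
    cat("  ... and", nrow(x$coef_table) - 8, "more terms\n")
  invisible(x)
}

#' @rdname dietpanel_fit-methods
#' @export
summary.dietpanel_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.dietpanel_fit")
}

#' @export
print.summary.dietpanel_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("%s %s model (cluster-robust CR1 SEs, %d clusters)\n",
              toupper(f$estimator), f$family, f$n_clusters))
  cat(sprintf("n = %d observations", f$n_obs))
  if (f$n_dropped_missing > 0)
    cat(sprintf(" (%d rows dropped for missing values)", f$n_dropped_missing))
  cat("\n")
  if (length(f$dropped))
    cat("dropped terms:", paste(f$dropped, collapse = ", "), "\n")
  print(f$coef_table, digits = 4, row.names = FALSE)
  cat(sprintf("%s = %.4f\n", names(f$fit_stat)[1L], f$fit_stat[1L]))
  invisible(x)
}

#' @rdname dietpanel_fit-methods
#' @export
coef.dietpanel_fit <- function(object, ...) object$coefficients

#' @rdname dietpanel_fit-methods
#' @export
vcov.dietpanel_fit <- function(object, ...) object$vcov

#' @rdname dietpanel_fit-methods
#' @param parm coefficients to include (names or indices).
#' @param level confidence level.
#' @export
confint.dietpanel_fit <- function(object, parm, level = 0.95, ...) {
  b <- coef(object)
  se <- sqrt(diag(vcov(object)))
  if (missing(parm)) parm <- names(b)
  q <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(b[parm] - q * se[parm], b[parm] + q * se[parm])
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' @rdname dietpanel_fit-methods
#' @export
nobs.dietpanel_fit <- function(object, ...) object$n_obs

#' @rdname dietpanel_fit-methods
#' @export
residuals.dietpanel_fit <- function(object, ...) object$residuals

#' @rdname dietpanel_fit-methods
#' @export
fitted.dietpanel_fit <- function(object, ...) object$fitted

#' @rdname dietpanel_fit-methods
#' @param newdata optional analysis table; the design (including
#'   Mundlak means within `newdata`) is rebuilt from the stored spec.
#' @export
predict.dietpanel_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.null(object$spec))
    stop("prediction on new data requires a fit built from a model_spec")
  if (object$estimator == "fe")
    stop("FE fits absorb household effects; out-of-sample prediction is undefined")
  des <- build_design(newdata, object$spec)
  b <- coef(object)
  X <- des$X[, names(b), drop = FALSE]
  eta <- drop(X %*% b)
  if (object$family == "poisson") exp(eta) else eta
}

#' @rdname dietpanel_fit-methods
#' @param nsim number of simulated outcome vectors.
#' @param seed optional RNG seed.
#' @export
simulate.dietpanel_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  n <- length(mu)
  sims <- if (object$family == "poisson") {
    replicate(nsim, stats::rpois(n, mu), simplify = FALSE)
  } else {
    sigma <- sqrt(sum(object$residuals^2) /
                  (object$n_obs - length(coef(object))))
    replicate(nsim, mu + stats::rnorm(n, 0, sigma), simplify = FALSE)
  }
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' @rdname dietpanel_fit-methods
#' @param terms coefficients to display; defaults to all but the
#'   intercept, dummies and Mundlak means.
#' @export
plot.dietpanel_fit <- function(x, terms = NULL, ...) {
  tab <- x$coef_table
  if (is.null(terms)) {
    hide <- c("(Intercept)", grep("^(mean_|wave_|country_)", tab$term,
                                  value = TRUE))
    terms <- setdiff(tab$term, hide)
  }
  tab <- tab[tab$term %in% terms, , drop = FALSE]
  yy <- rev(seq_len(nrow(tab)))
  old <- graphics::par(mar = c(4, 9, 2, 1)); on.exit(graphics::par(old))
  plot(tab$estimate, yy, xlim = range(tab$ci_lower, tab$ci_upper, 0),
       pch = 16, yaxt = "n", ylab = "", xlab = "coefficient (95% CI)", ...)
  graphics::segments(tab$ci_lower, yy, tab$ci_upper, yy)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = yy, labels = tab$term, las = 1, cex.axis = 0.8)
  invisible(x)
}
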