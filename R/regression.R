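# OLS, spatial-lag (SLM) and spatial-error (SEM) regression by maximum
# likelihood with AIC model comparison.
#
# Both spatial models are estimated by concentrating the Gaussian
# log-likelihood in the scalar autoregressive parameter: at each candidate
# value the regression coefficients and the error variance are profiled out
# by least squares, the Jacobian term log|I - rho W| is evaluated from a
# one-time eigenvalue decomposition of W, and the concentrated likelihood is
# maximised by bounded scalar search on the admissible interval.

#' Build a regression design
#'
#' Assembles the outcome vector and the predictor matrix (with a leading
#' intercept column) from an aligned attribute table, checking for missing
#' values and collinearity.
#'
#' @param table data frame with a `unit_id` column and numeric variables, in
#'   weight-matrix unit order (see [align_attributes()]).
#' @param outcome name of the outcome variable.
#' @param predictors character vector of predictor names.
#' @return list of class `design_matrix` with `y`, `X`, `outcome_name`,
#'   `predictor_names`, `n`.
#' @export
design_matrix <- function(table, outcome, predictors) {
  .assert(outcome %in% names(table), "outcome '", outcome, "' not in table")
  missing_p <- setdiff(predictors, names(table))
  .assert(length(missing_p) == 0,
          "predictors not in table: ", paste(missing_p, collapse = ", "))
  .assert(!(outcome %in% predictors), "outcome cannot be one of the predictors")
  y <- as.numeric(table[[outcome]])
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  .assert(all(is.finite(y)) && all(is.finite(X)),
          "design contains missing or non-finite values")
  n <- length(y)
  .assert(n > ncol(X) + 2, "too few units (", n, ") for ", ncol(X),
          " design columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    .assert(FALSE, "collinear design; dependent columns: ",
            paste(dep, collapse = ", "), class = "sbaspatial_collinear")
  }
  structure(list(y = y, X = X, outcome_name = outcome,
                 predictor_names = predictors, n = n),
            class = "design_matrix")
}

.new_regression_result <- function(model_kind, coef_tab, spatial_parameter,
                                   sigma2, log_likelihood, k, r2_kind, r2,
                                   n, residuals, fitted, outcome_name) {
  structure(list(
    model_kind = model_kind,
    coefficients = coef_tab,
    spatial_parameter = spatial_parameter,
    sigma2 = sigma2,
    log_likelihood = log_likelihood,
    aic = 2 * k - 2 * log_likelihood,
    k = k,
    r2_measure = list(kind = r2_kind, value = r2),
    n = n,
    residuals = residuals,
    fitted = fitted,
    outcome_name = outcome_name
  ), class = "spatial_regression")
}

#' @export
print.spatial_regression <- function(x, ...) {
  cat("<spatial_regression> ", toupper(x$model_kind), " on ", x$outcome_name,
      ", n = ", x$n, "\n", sep = "")
  stats::printCoefmat(as.matrix(x$coefficients[, c("estimate", "se", "p_value")]),
               P.values = TRUE, has.Pvalue = TRUE)
  if (!is.null(x$spatial_parameter)) {
    sp <- x$spatial_parameter
    cat(sp$name, " = ", format(sp$estimate, digits = 4),
        " (se ", format(sp$se, digits = 3), ", p ",
        format(sp$p_value, digits = 3), ")\n", sep = "")
  }
  cat("logLik = ", format(x$log_likelihood, digits = 6),
      ", AIC = ", format(x$aic, digits = 6),
      ", ", x$r2_measure$kind, " = ", format(x$r2_measure$value, digits = 3),
      "\n", sep = "")
  invisible(x)
}

.coef_table <- function(est, se, df = Inf) {
  p <- if (is.finite(df)) 2 * stats::pt(-abs(est / se), df) else
    2 * stats::pnorm(-abs(est / se))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             p_value = unname(p), row.names = names(est),
             stringsAsFactors = FALSE)
}

#' Ordinary least squares fit
#'
#' Classical linear regression `y = a + Xb + e` via [stats::lm()], reported
#' with the Gaussian log-likelihood at the ML variance (residual sum of
#' squares over n) so that its AIC is directly comparable with the spatial
#' models'. `k` counts the coefficients plus one for the error variance.
#'
#' @param design a [design_matrix()].
#' @return a `spatial_regression` result with `model_kind = "ols"` and
#'   adjusted R-squared as the fit measure.
#' @export
fit_ols <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  dat <- data.frame(.y = design$y, design$X[, -1, drop = FALSE],
                    check.names = FALSE)
  fml <- stats::as.formula(paste0(
    ".y ~ ", paste(sprintf("`%s`", design$predictor_names), collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  est <- stats::coef(fit)
  names(est) <- colnames(design$X)
  se <- sm$coefficients[, 2]
  names(se) <- colnames(design$X)
  n <- design$n
  res <- stats::residuals(fit)
  ll <- as.numeric(stats::logLik(fit))
  k <- length(est) + 1
  coef_tab <- .coef_table(est, se, df = fit$df.residual)
  coef_tab$p_value <- sm$coefficients[, 4]
  .new_regression_result("ols", coef_tab, NULL, sum(res^2) / n, ll, k,
                         "adjusted_r2", sm$adj.r.squared, n,
                         as.numeric(res), as.numeric(stats::fitted(fit)),
                         design$outcome_name)
}

.check_spatial_fit_inputs <- function(weights, design) {
  stopifnot(inherits(weights, "spatial_weights"),
            inherits(design, "design_matrix"))
  .assert(weights$n == design$n, "weights index ", weights$n,
          " units but the design has ", design$n)
  .assert(weights$style == "row_standardized",
          "spatial models require row-standardized weights; ",
          "call row_standardize() first")
  invisible(TRUE)
}

.ols_loglik <- function(y, X) {
  e <- stats::lm.fit(X, y)$residuals
  n <- length(y)
  -n / 2 * (log(2 * pi) + 1) - n / 2 * log(sum(e^2) / n)
}

#' Concentrated log-likelihood of the spatial lag model
#'
#' Profile log-likelihood in the autoregressive parameter:
#' at a given `delta`, `(y - delta W y)` is regressed on X, the error
#' variance is profiled out, and the Jacobian term `log|I - delta W|` is
#' added from the eigenvalues of W. At `delta = 0` it equals the OLS
#' Gaussian log-likelihood.
#'
#' @param weights row-standardized `spatial_weights`.
#' @param design a [design_matrix()].
#' @param delta scalar autoregressive parameter.
#' @param ev optional precomputed eigenvalues of W.
#' @return scalar log-likelihood.
#' @export
slm_profile_loglik <- function(weights, design, delta, ev = NULL) {
  .check_spatial_fit_inputs(weights, design)
  ev <- ev %||% .weights_eigenvalues(weights)
  Wy <- as.numeric(weights$W %*% design$y)
  n <- design$n
  e <- stats::lm.fit(design$X, design$y - delta * Wy)$residuals
  -n / 2 * (log(2 * pi) + 1) - n / 2 * log(sum(e^2) / n) +
    sum(log(1 - delta * ev))
}

#' Concentrated log-likelihood of the spatial error model
#'
#' At a given `lambda` both sides are spatially filtered,
#' `(I - lambda W) y` on `(I - lambda W) X`, the coefficients and variance
#' profiled out, and `log|I - lambda W|` added. At `lambda = 0` it equals
#' the OLS Gaussian log-likelihood.
#'
#' @inheritParams slm_profile_loglik
#' @param lambda scalar autoregressive error parameter.
#' @return scalar log-likelihood.
#' @export
sem_profile_loglik <- function(weights, design, lambda, ev = NULL) {
  .check_spatial_fit_inputs(weights, design)
  ev <- ev %||% .weights_eigenvalues(weights)
  n <- design$n
  ys <- design$y - lambda * as.numeric(weights$W %*% design$y)
  Xs <- design$X - lambda * as.matrix(weights$W %*% design$X)
  e <- stats::lm.fit(Xs, ys)$residuals
  -n / 2 * (log(2 * pi) + 1) - n / 2 * log(sum(e^2) / n) +
    sum(log(1 - lambda * ev))
}

# bounded scalar maximisation on the admissible interval, shrunk by `shrink`
# from the theoretical bounds; errors if the optimum sits at the boundary
.profile_optimize <- function(f, ev, shrink = 1e-5, tol = 1e-8, name = "rho") {
  iv <- .admissible_interval(ev)
  lo <- iv[1] + shrink; hi <- iv[2] - shrink
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
  est <- opt$maximum
  if (est - lo < 10 * tol || hi - est < 10 * tol) {
    # optimize() never lands exactly on a bound; make sure the interior
    # really is a maximum rather than a monotone edge
    eps <- max(1e-6, 10 * tol)
    inner <- if (est - lo < 10 * tol) est + eps else est - eps
    if (f(inner) > opt$objective) {
      .assert(FALSE, "spatial parameter ", name,
              " did not converge in the interior of its admissible interval",
              class = "sbaspatial_nonconvergence")
    }
  }
  list(estimate = est, loglik = opt$objective, interval = c(lo, hi))
}

# standard errors from the numerically differentiated observed information
# of the full log-likelihood over (rho, beta); sigma2 concentrated out
.spatial_se <- function(full_ll, theta_hat, names_out) {
  H <- tryCatch(pracma::hessian(full_ll, theta_hat, h = 1e-6),
                error = function(e) NULL)
  se <- rep(NA_real_, length(theta_hat))
  if (!is.null(H)) {
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      se[d > 0] <- sqrt(d[d > 0])
    }
  }
  names(se) <- names_out
  se
}

#' Maximum-likelihood spatial lag model
#'
#' Fits \eqn{y = \delta W y + X\beta + \varepsilon} by maximising the
#' concentrated log-likelihood in `delta` over the admissible interval
#' determined by the eigenvalue range of W (bounded scalar search, tolerance
#' 1e-8). Standard errors come from the numerically differentiated observed
#' information at the optimum. `k` adds one parameter over OLS for `delta`;
#' the fit measure is a pseudo R-squared (squared correlation of fitted and
#' observed values).
#'
#' @param weights row-standardized `spatial_weights`.
#' @param design a [design_matrix()].
#' @param ev optional precomputed eigenvalues of W (see
#'   [weights_eigenvalues()]).
#' @return a `spatial_regression` result with `model_kind = "slm"` and
#'   `spatial_parameter` named `delta`.
#' @export
fit_spatial_lag <- function(weights, design, ev = NULL) {
  .check_spatial_fit_inputs(weights, design)
  ev <- ev %||% .weights_eigenvalues(weights)
  y <- design$y; X <- design$X; n <- design$n
  Wy <- as.numeric(weights$W %*% y)
  b0 <- qr.coef(qr(X), y)
  bL <- qr.coef(qr(X), Wy)
  e0 <- y - X %*% b0
  eL <- Wy - X %*% bL
  conc <- function(d) {
    e <- e0 - d * eL
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(sum(e^2) / n) +
      sum(log(1 - d * ev))
  }
  opt <- .profile_optimize(conc, ev, name = "delta")
  delta <- opt$estimate
  beta <- as.numeric(b0 - delta * bL)
  names(beta) <- colnames(X)
  resid <- as.numeric(e0 - delta * eL)
  sigma2 <- sum(resid^2) / n
  ll <- opt$loglik
  k <- length(beta) + 2
  fitted <- delta * Wy + as.numeric(X %*% beta)
  full_ll <- function(th) {
    d <- th[1]
    if (d <= opt$interval[1] || d >= opt$interval[2]) return(-Inf)
    e <- y - d * Wy - X %*% th[-1]
    s2 <- sum(e^2) / n
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(s2) + sum(log(1 - d * ev))
  }
  se <- .spatial_se(full_ll, c(delta, beta), c("delta", names(beta)))
  sp <- list(name = "delta", estimate = delta, se = unname(se[1]),
             p_value = unname(2 * stats::pnorm(-abs(delta / se[1]))))
  coef_tab <- .coef_table(beta, se[-1])
  .new_regression_result("slm", coef_tab, sp, sigma2, ll, k, "pseudo_r2",
                         stats::cor(y, fitted)^2, n, resid, fitted,
                         design$outcome_name)
}

#' Maximum-likelihood spatial error model
#'
#' Fits \eqn{y = X\beta + u,\; u = \lambda W u + \varepsilon} (the
#' autoregressive-disturbance model capturing omitted spatially structured
#' factors) by maximising the concentrated log-likelihood in `lambda`: both
#' sides are spatially filtered with `(I - lambda W)`, the coefficients and
#' variance profiled out, and the Jacobian added from the eigenvalues of W.
#' Reporting conventions match [fit_spatial_lag()].
#'
#' @inheritParams fit_spatial_lag
#' @return a `spatial_regression` result with `model_kind = "sem"` and
#'   `spatial_parameter` named `lambda`.
#' @export
fit_spatial_error <- function(weights, design, ev = NULL) {
  .check_spatial_fit_inputs(weights, design)
  ev <- ev %||% .weights_eigenvalues(weights)
  y <- design$y; X <- design$X; n <- design$n
  Wy <- as.numeric(weights$W %*% y)
  WX <- as.matrix(weights$W %*% X)
  conc <- function(l) {
    e <- stats::lm.fit(X - l * WX, y - l * Wy)$residuals
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(sum(e^2) / n) +
      sum(log(1 - l * ev))
  }
  opt <- .profile_optimize(conc, ev, name = "lambda")
  lambda <- opt$estimate
  fitl <- stats::lm.fit(X - lambda * WX, y - lambda * Wy)
  beta <- fitl$coefficients
  names(beta) <- colnames(X)
  eps <- fitl$residuals                      # filtered innovations
  sigma2 <- sum(eps^2) / n
  u <- y - as.numeric(X %*% beta)            # spatially correlated residual
  ll <- opt$loglik
  k <- length(beta) + 2
  fitted <- as.numeric(X %*% beta) + lambda * as.numeric(weights$W %*% u)
  full_ll <- function(th) {
    l <- th[1]
    if (l <= opt$interval[1] || l >= opt$interval[2]) return(-Inf)
    e <- (y - l * Wy) - (X - l * WX) %*% th[-1]
    s2 <- sum(e^2) / n
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(s2) + sum(log(1 - l * ev))
  }
  se <- .spatial_se(full_ll, c(lambda, beta), c("lambda", names(beta)))
  sp <- list(name = "lambda", estimate = lambda, se = unname(se[1]),
             p_value = unname(2 * stats::pnorm(-abs(lambda / se[1]))))
  coef_tab <- .coef_table(beta, se[-1])
  .new_regression_result("sem", coef_tab, sp, sigma2, ll, k, "pseudo_r2",
                         stats::cor(y, fitted)^2, n, u, fitted,
                         design$outcome_name)
}

#' Rank fitted models by AIC
#'
#' Builds a model-comparison table over results fitted on the same design:
#' lower AIC fits best, ties broken by higher R-squared measure and then by
#' model simplicity (OLS before SLM before SEM).
#'
#' @param results list of `spatial_regression` results on the same outcome
#'   and n.
#' @return data frame of class `model_comparison`, one row per model in rank
#'   order, with columns `model`, `spatial_parameter`, `spatial_estimate`,
#'   `log_likelihood`, `aic`, `k`, `r2_kind`, `r2`, `n`, `rank`.
#' @export
compare_models <- function(results) {
  .assert(is.list(results) && length(results) >= 2,
          "need at least two results to compare")
  .assert(all(vapply(results, inherits, TRUE, "spatial_regression")),
          "all elements must be spatial_regression results")
  ns <- vapply(results, `[[`, 1, "n")
  outs <- vapply(results, `[[`, "", "outcome_name")
  .assert(length(unique(ns)) == 1, "results have mismatched n: ",
          paste(unique(ns), collapse = ", "))
  .assert(length(unique(outs)) == 1, "results have mismatched outcomes: ",
          paste(unique(outs), collapse = ", "))
  simplicity <- c(ols = 1, slm = 2, sem = 3)
  df <- do.call(rbind, lapply(results, function(r) {
    sp <- r$spatial_parameter
    data.frame(
      model = r$model_kind,
      spatial_parameter = if (is.null(sp)) NA_character_ else sp$name,
      spatial_estimate = if (is.null(sp)) NA_real_ else sp$estimate,
      log_likelihood = r$log_likelihood,
      aic = r$aic,
      k = r$k,
      r2_kind = r$r2_measure$kind,
      r2 = r$r2_measure$value,
      n = r$n,
      stringsAsFactors = FALSE
    )
  }))
  ord <- order(df$aic, -df$r2, simplicity[df$model])
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, class = c("model_comparison", "data.frame"),
            results = results[ord])
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> ranked by AIC (best first)\n")
  print.data.frame(as.data.frame(x), digits = 5)
  invisible(x)
}
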