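#' Baseline penalized regressions
#'
#' Reference fits that do not distinguish hubs from non-hubs: the adaptive
#' lasso, lasso, elastic net and ridge regression, each penalizing the
#' confounders and all features uniformly (only the intercept is free).
#' Tuning is by k-fold cross-validation: the glmnet-based baselines at the
#' minimum mean error (`lambda.min` convention), the adaptive lasso with the
#' one-standard-error guard of its two-dimensional `(nu, lambda)` search,
#' matching [cv_ng()]; both rules are exposed via `cv_rule`. The
#' adaptive lasso shares the network-guided machinery — the same perturbed
#' elastic-net initialization (recomputed inside each training fold) and the
#' same `(nu, lambda)` grid search — but with an empty hub set and the
#' confounders moved into the penalized block, so it differs from the
#' network-guided fit only in what is left unpenalized.
#'
#' @param method `"alasso"`, `"lasso"`, `"enet"` or `"ridge"`.
#' @param cv_rule `"min"` or `"1se"`; default `"1se"` for the adaptive lasso
#'   (as in [cv_ng()]) and `"min"` for the glmnet-based baselines.
#' @param x feature matrix.
#' @param z optional confounder matrix.
#' @param y outcome vector.
#' @param nfolds folds for cross-validation.
#' @param seed controls fold assignment.
#' @param enet_mixing mixing parameter for the elastic net (and for the
#'   adaptive-lasso initializer).
#' @param nu_grid adaptive-lasso exponent grid.
#' @param ... passed to [cv_ng()] (adaptive lasso) or
#'   [glmnet::cv.glmnet()] (others).
#' @return an object of class `"baseline_fit"`: `method`, `coefficients`
#'   (named: intercept, confounders, features), `lambda`, `extra`.
#' @export
#' @examples
#' d <- sim_data(sim_scenario(n = 60, p = 20, signal = "weak", seed = 5, test_n = 10))
#' f <- fit_baseline("lasso", d$x_train, d$z_train, d$y_train, seed = 1)
#' sum(coef(f) != 0)
fit_baseline <- function(method = c("alasso", "lasso", "enet", "ridge"),
                         x, z = NULL, y, cv_rule = NULL,
                         nfolds = 5L, seed = NULL,
                         enet_mixing = 0.5, nu_grid = c(0.5, 1, 2), ...) {
  method <- match.arg(method)
  if (is.null(cv_rule)) cv_rule <- if (method == "alasso") "1se" else "min"
  cv_rule <- match.arg(cv_rule, c("min", "1se"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (is.null(colnames(z))) colnames(z) <- paste0("Z", seq_len(ncol(z)))
  }
  n <- nrow(x)

  if (method == "alasso") {
    # empty hub set; confounders penalized along with every feature
    d <- cbind(z, x)
    hubs <- select_hubs(setNames(numeric(ncol(d)), colnames(d)), 0L)
    part <- build_partition(d, z = NULL, y = y, hubs = hubs)
    sel <- cv_ng(part, nu_grid = nu_grid, cv_rule = cv_rule, nfolds = nfolds,
                 seed = seed, enet_mixing = enet_mixing, ...)
    coefs <- c(sel$fit$alpha, sel$fit$beta)
    extra <- list(nu = sel$nu, cv = sel$cv)
    lambda <- sel$lambda
  } else {
    alpha <- switch(method, lasso = 1, enet = enet_mixing, ridge = 0)
    d <- cbind(z, x)
    foldid <- .foldid(n, nfolds, seed)
    cv <- glmnet::cv.glmnet(d, y, alpha = alpha, foldid = foldid, ...)
    s_choice <- if (cv_rule == "1se") "lambda.1se" else "lambda.min"
    co <- as.numeric(coef(cv, s = s_choice))
    coefs <- setNames(co, c("(Intercept)", colnames(d)))
    extra <- list(mixing = alpha)
    lambda <- cv[[s_choice]]
  }
  structure(
    list(method = method, coefficients = coefs, lambda = lambda,
         extra = extra,
         c = if (is.null(z)) 0L else ncol(z), p = ncol(x)),
    class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("Baseline fit (%s): %d of %d penalized terms nonzero, lambda = %.4g\n",
              x$method, sum(x$coefficients[-1L] != 0),
              length(x$coefficients) - 1L, x$lambda))
  invisible(x)
}

#' @export
coef.baseline_fit <- function(object, ...) object$coefficients

#' @export
predict.baseline_fit <- function(object, newx, newz = NULL, ...) {
  d <- cbind(if (is.null(newz)) NULL else as.matrix(newz), as.matrix(newx))
  if (ncol(d) != length(object$coefficients) - 1L)
    stop("prediction design does not match the fitted coefficients")
  drop(object$coefficients[1L] + d %*% object$coefficients[-1L])
}
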