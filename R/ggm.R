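#' Maximum-likelihood covariance of a feature matrix
#'
#' Empirical variance-covariance matrix with divisor `n` (the Gaussian MLE),
#' matching the covariance that enters the graphical-lasso objective.
#'
#' @param x numeric matrix, samples in rows.
#' @param center subtract column means first (default `TRUE`).
#' @return a symmetric positive semidefinite `p x p` matrix.
#' @export
#' @examples
#' empirical_covariance(matrix(c(1, 2, 3, 2, 4, 6), 3, 2))
empirical_covariance <- function(x, center = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    stop("`x` must be numeric with no missing values")
  if (nrow(x) < 2L) stop("need at least two samples")
  if (center) x <- sweep(x, 2L, colMeans(x))
  S <- crossprod(x) / nrow(x)
  (S + t(S)) / 2
}

.check_cov <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("`S` must be a symmetric square matrix")
  S
}

#' Graphical lasso at a fixed penalty
#'
#' Estimates a sparse precision matrix by maximizing the penalized Gaussian
#' log-likelihood `log det(Theta) - tr(S Theta) - lambda * sum_{j != k}
#' |theta_jk|`; the l1 penalty applies to off-diagonal entries only. The
#' solver is block coordinate descent on the covariance estimate, with each
#' column updated through a lasso regression.
#'
#' @param S covariance matrix (see [empirical_covariance()]).
#' @param lambda nonnegative penalty.
#' @param tol convergence tolerance on the average absolute change of the
#'   working covariance, relative to the average absolute off-diagonal of `S`.
#' @param maxit maximum number of full sweeps.
#' @param warm optional list with elements `w` and `B` from a previous fit at
#'   a nearby penalty, used as a warm start.
#' @return an object of class `"precision_fit"`: `theta` (the estimate),
#'   `w` (its inverse, the fitted covariance), `lambda`, `n_edges` (strictly
#'   nonzero upper-triangular off-diagonals), `objective` (the penalized
#'   log-likelihood kernel `log det - tr - lambda * l1`), `iterations`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-4, maxit = 200L, warm = NULL) {
  S <- .check_cov(S)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("`lambda` must be a single nonnegative number")
  fit <- .glasso_cd(S, lambda, tol, as.integer(maxit),
                    W_init = warm$w, B_init = warm$B)
  if (!fit$converged)
    stop(sprintf("graphical lasso did not converge in %d sweeps", fit$iterations))
  theta <- fit$theta
  dimnames(theta) <- dimnames(S)
  ut <- upper.tri(theta)
  pen <- sum(abs(theta[ut])) * 2
  obj <- determinant(theta, logarithm = TRUE)$modulus[1] -
    sum(S * theta) - lambda * pen
  structure(
    list(theta = theta, w = fit$w, B = fit$B, lambda = lambda,
         n_edges = sum(theta[ut] != 0), objective = obj,
         iterations = fit$iterations),
    class = "precision_fit")
}

#' @export
print.precision_fit <- function(x, ...) {
  cat(sprintf("Graphical-lasso precision estimate: p = %d, lambda = %.4g, %d edges\n",
              nrow(x$theta), x$lambda, x$n_edges))
  invisible(x)
}

#' Extended BIC of a graphical-lasso fit
#'
#' `eBIC = -2 l(Theta) + E log(n) + 4 gamma E log(p)` where `l` is the
#' penalized Gaussian log-likelihood of the fit, `E` its edge count and
#' `gamma` in `[0, 1]` the sparsity hyperparameter; `gamma = 0` gives the
#' ordinary BIC.
#'
#' @param fit a `"precision_fit"`.
#' @param n number of samples behind the covariance.
#' @param p number of features; defaults to the fit's dimension.
#' @param gamma eBIC hyperparameter in `[0, 1]`.
#' @return the eBIC value (smaller is better).
#' @export
ebic <- function(fit, n, p = nrow(fit$theta), gamma = 0.5) {
  stopifnot(inherits(fit, "precision_fit"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1)
    stop("`gamma` must be in [0, 1]")
  ll <- (n / 2) * fit$objective
  e <- fit$n_edges
  -2 * ll + e * log(n) + 4 * gamma * e * log(p)
}

#' Partial correlations from a precision matrix
#'
#' Standardizes the off-diagonal precision entries with a sign reversal:
#' `rho_jk = -theta_jk / sqrt(theta_jj theta_kk)`. The diagonal is set to
#' zero by convention, and the sparsity pattern equals that of `theta`.
#'
#' @param fit a `"precision_fit"` or a precision matrix.
#' @return a symmetric matrix of partial correlations with zero diagonal.
#' @export
#' @examples
#' partial_correlations(matrix(c(2, -1, -1, 2), 2, 2))
partial_correlations <- function(fit) {
  theta <- if (inherits(fit, "precision_fit")) fit$theta else .check_cov(fit)
  d <- diag(theta)
  if (any(d <= 0))
    stop("invalid precision matrix: nonpositive diagonal entry")
  rho <- -theta / sqrt(d %o% d)
  diag(rho) <- 0
  rho
}

#' Estimate a partial-correlation network with eBIC-tuned graphical lasso
#'
#' The workhorse of the network stage. Columns are standardized to unit
#' variance (so the graphical lasso operates on the correlation scale and
#' hub ranking is scale-invariant), a decreasing log-spaced penalty grid is
#' built from `lambda_max = max |S_jk|` (the smallest penalty giving a fully
#' disconnected network), the graphical lasso is fit along the grid with warm
#' starts, and the fit minimizing the eBIC is selected, breaking ties toward
#' the larger (sparser) penalty.
#'
#' @param x numeric sample-by-feature matrix with named columns.
#' @param gamma eBIC hyperparameter (default 0, the ordinary BIC; larger
#'   values remove more edges but degrade hub ranking, see the vignette).
#' @param nlambda grid size (default 30).
#' @param patience stop fitting the path after this many consecutive grid
#'   points without an eBIC improvement (the criterion is effectively
#'   unimodal along the path); use `Inf` to fit the whole grid.
#' @param lambda_min_ratio smallest grid value as a fraction of `lambda_max`.
#' @param lambda optional explicit penalty grid (overrides the two above).
#' @param standardize scale columns to unit variance first (default `TRUE`).
#' @param tol,maxit passed to [glasso_fit()].
#' @return an object of class `"ggm_network"`: the selected `fit`, the
#'   partial-correlation matrix `rho`, `lambda` (selected), `gamma`,
#'   `ebic` and `n_edges` along the fitted part of the grid, `lambda_grid`,
#'   `feature_names`, the covariance `S` the fits used, `n`, `p`.
#' @export
ggm_network <- function(x, gamma = 0, nlambda = 30L, lambda_min_ratio = 0.01,
                        lambda = NULL, standardize = TRUE, patience = 6L,
                        tol = 1e-4, maxit = 200L) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stop("`x` must be numeric with no missing values")
  if (ncol(x) < 2L) stop("need at least two features")
  if (nrow(x) < 3L) stop("need at least three samples")
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(nms)) stop("feature names must be unique")
  if (standardize) {
    s <- apply(x, 2L, sd)
    if (any(s == 0)) stop("zero-variance feature(s): ", paste(nms[s == 0], collapse = ", "))
    x <- sweep(x, 2L, s, "/")
  }
  S <- empirical_covariance(x)
  dimnames(S) <- list(nms, nms)
  if (is.null(lambda)) {
    lmax <- max(abs(S[upper.tri(S)]))
    if (lmax <= 0) lmax <- 1e-4
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  } else {
    lambda <- sort(lambda, decreasing = TRUE)
  }
  n <- nrow(x)
  p <- ncol(x)
  fits_ebic <- rep(NA_real_, length(lambda))
  edges <- rep(NA_integer_, length(lambda))
  best <- NULL
  warm <- NULL
  since_best <- 0L
  used <- 0L
  for (i in seq_along(lambda)) {
    f <- glasso_fit(S, lambda[i], tol = tol, maxit = maxit, warm = warm)
    warm <- list(w = f$w, B = f$B)
    fits_ebic[i] <- ebic(f, n = n, p = p, gamma = gamma)
    edges[i] <- f$n_edges
    used <- i
    if (is.null(best) || fits_ebic[i] < best$ebic) {
      best <- list(fit = f, ebic = fits_ebic[i])
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= patience) break
    }
  }
  fits_ebic <- fits_ebic[seq_len(used)]
  edges <- edges[seq_len(used)]
  lambda <- lambda[seq_len(used)]
  rho <- partial_correlations(best$fit)
  structure(
    list(fit = best$fit, rho = rho, lambda = best$fit$lambda, gamma = gamma,
         ebic = fits_ebic, n_edges = edges, lambda_grid = lambda,
         feature_names = nms, S = S, n = n, p = p),
    class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf(
    "Partial-correlation network: p = %d features, %d edges (lambda = %.4g by eBIC, gamma = %.2g)\n",
    x$p, x$fit$n_edges, x$lambda, x$gamma))
  invisible(x)
}

#' Check the graphical-lasso stationarity conditions
#'
#' For the fitted precision `Theta` with inverse `W`, optimality of the
#' penalized log-likelihood requires `W_jk - S_jk = lambda * sign(theta_jk)`
#' on nonzero off-diagonals and `|W_jk - S_jk| <= lambda` on zero ones
#' (and `W_jj = S_jj` on the diagonal, since it is unpenalized).
#'
#' @param fit a `"precision_fit"`.
#' @param S the covariance the fit was computed from.
#' @return the maximum absolute violation of the conditions.
#' @export
glasso_kkt <- function(fit, S) {
  stopifnot(inherits(fit, "precision_fit"))
  S <- .check_cov(S)
  W <- solve(fit$theta)
  D <- W - S
  lam <- fit$lambda
  off <- row(D) != col(D)
  nz <- off & fit$theta != 0
  z <- off & fit$theta == 0
  v <- max(abs(diag(D)))
  if (any(nz)) v <- max(v, abs(D[nz] - lam * sign(fit$theta[nz])))
  if (any(z)) v <- max(v, pmax(abs(D[z]) - lam, 0))
  v
}
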