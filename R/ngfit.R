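#' Split the design into unpenalized and penalized blocks
#'
#' Builds the design partition of the partially penalized regression:
#' `u = [1 | z | x[, hubs]]` collects the intercept, confounders and hub
#' features (never penalized), `n_mat = x[, non-hubs]` the features subject
#' to the adaptive-lasso penalty. A column map records the provenance of
#' every coefficient.
#'
#' @param x sample-by-feature matrix.
#' @param z confounder matrix (or `NULL`).
#' @param y outcome vector.
#' @param hubs a `"hub_partition"`; hubs may be empty.
#' @return an object of class `"design_partition"` with elements `u`,
#'   `n_mat`, `y`, `column_map` (data frame: `block`, `name`), `t`, `q`.
#' @export
build_partition <- function(x, z = NULL, y, hubs) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (nrow(z) != n) stop("`x` and `z` row counts differ")
    if (is.null(colnames(z))) colnames(z) <- paste0("Z", seq_len(ncol(z)))
  }
  if (length(y) != n) stop("`y` length does not match `x` rows")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  stopifnot(inherits(hubs, "hub_partition"))
  if (length(hubs$hub_indices) &&
      (max(hubs$hub_indices) > ncol(x) || min(hubs$hub_indices) < 1))
    stop("hub indices out of range for `x`")
  hub_idx <- hubs$hub_indices
  nonhub_idx <- hubs$nonhub_indices
  if (length(intersect(hub_idx, nonhub_idx)))
    stop("internal error: hub and non-hub sets overlap")
  u <- cbind(`(Intercept)` = rep(1, n), z, x[, hub_idx, drop = FALSE])
  n_mat <- x[, nonhub_idx, drop = FALSE]
  column_map <- data.frame(
    block = c("intercept",
              rep("confounder", if (is.null(z)) 0L else ncol(z)),
              rep("hub", length(hub_idx)),
              rep("nonhub", length(nonhub_idx))),
    name = c("(Intercept)",
             if (is.null(z)) character(0) else colnames(z),
             colnames(x)[hub_idx], colnames(x)[nonhub_idx]),
    stringsAsFactors = FALSE)
  if (anyDuplicated(column_map$name))
    stop("duplicate column names across blocks")
  structure(list(u = u, n_mat = n_mat, y = as.numeric(y),
                 column_map = column_map,
                 t = ncol(u), q = ncol(n_mat),
                 hub_indices = hub_idx, nonhub_indices = nonhub_idx),
            class = "design_partition")
}

.foldid <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Perturbed elastic-net initial estimator
#'
#' Fits an elastic net of `y` on the full design with the unpenalized block
#' free of penalty, picks its penalty by cross-validation, and returns the
#' absolute non-hub coefficients floored by a small perturbation. These
#' magnitudes feed [adaptive_weights()]; the perturbation keeps every weight
#' finite even for features the elastic net zeroes out.
#'
#' @param part a `"design_partition"`.
#' @param enet_mixing elastic-net mixing parameter in (0, 1].
#' @param ridge_perturb perturbation added to each magnitude; default `1/n`.
#' @param nfolds folds for the internal cross-validation.
#' @param seed seed controlling the internal fold assignment.
#' @return positive magnitudes, one per penalized column.
#' @export
initial_estimator <- function(part, enet_mixing = 0.5, ridge_perturb = NULL,
                              nfolds = 5L, seed = NULL) {
  stopifnot(inherits(part, "design_partition"))
  if (enet_mixing <= 0 || enet_mixing > 1) stop("`enet_mixing` must be in (0, 1]")
  n <- length(part$y)
  if (is.null(ridge_perturb)) ridge_perturb <- 1 / n
  q <- part$q
  if (q == 0L) return(numeric(0))
  d <- cbind(part$u[, -1L, drop = FALSE], part$n_mat)
  zv <- apply(part$n_mat, 2L, function(col) var(col) == 0)
  if (any(zv))
    warning("zero-variance penalized column(s) receive the perturbation floor")
  if (ncol(d) < 2L) {
    # too small for glmnet: unpenalized least squares
    beta <- coef(lm(part$y ~ d))[-1L]
    beta[is.na(beta)] <- 0
    return(abs(beta) + ridge_perturb)
  }
  pf <- c(rep(0, part$t - 1L), rep(1, q))
  foldid <- .foldid(n, nfolds, seed)
  cv <- glmnet::cv.glmnet(d, part$y, alpha = enet_mixing, penalty.factor = pf,
                          foldid = foldid, nlambda = 50)
  beta <- as.numeric(coef(cv, s = "lambda.min"))[-1L]
  mag <- abs(beta[(part$t - 1L + 1L):(part$t - 1L + q)]) + ridge_perturb
  setNames(mag, colnames(part$n_mat))
}

#' Adaptive-lasso weights
#'
#' `w_j = m_j^(-nu)` from positive initial magnitudes `m_j`: features with
#' larger initial coefficients are penalized less.
#'
#' @param beta_tilde_mag positive magnitudes (see [initial_estimator()]).
#' @param nu positive exponent.
#' @return positive weights.
#' @export
#' @examples
#' adaptive_weights(c(2, 0.5), nu = 1)  # 0.5, 2
adaptive_weights <- function(beta_tilde_mag, nu) {
  if (any(beta_tilde_mag <= 0)) stop("initial magnitudes must be strictly positive")
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0) stop("`nu` must be positive")
  beta_tilde_mag^(-nu)
}

#' Partially penalized weighted-lasso fit at fixed tuning
#'
#' Minimizes `||y - U alpha - N beta||^2 + lambda * sum_j w_j |beta_j|` by
#' block coordinate descent: an exact least-squares update of `alpha` given
#' `beta`, then cyclic soft-thresholding over the penalized coordinates,
#' iterated until the largest single-update decrease of the quadratic part
#' falls below `tol * ||y||^2`. The unpenalized block is never shrunk, and
#' the objective is guaranteed non-increasing across sweeps.
#'
#' @param part a `"design_partition"`.
#' @param lambda nonnegative penalty.
#' @param weights nonnegative per-coordinate penalty weights, length `q`.
#' @param tol convergence tolerance (relative to `||y||^2`).
#' @param maxit maximum sweeps.
#' @param kkt_tol absolute stationarity tolerance verified before accepting
#'   convergence; nonpositive disables the check.
#' @return an object of class `"ng_fit"`: `alpha`, `beta` (named),
#'   `lambda`, `weights`, `objective_value`, `selected_nonhubs`
#'   (indices into the penalized block with nonzero coefficients),
#'   `iterations`, `column_map`.
#' @export
fit_ng <- function(part, lambda, weights, tol = 1e-14, maxit = 50000L,
                   kkt_tol = 1e-8) {
  stopifnot(inherits(part, "design_partition"))
  if (lambda < 0) stop("`lambda` must be nonnegative")
  if (length(weights) != part$q) stop("`weights` must have length q")
  if (any(weights < 0)) stop("`weights` must be nonnegative")
  res <- .ng_cd_path(part$u, part$n_mat, part$y, as.numeric(lambda),
                     as.numeric(weights), tol, as.integer(maxit), kkt_tol)
  if (!res$rank_ok)
    warning("rank-deficient unpenalized block; fit uses a pseudoinverse")
  if (any(res$iterations >= maxit))
    stop(sprintf("coordinate descent did not converge in %d sweeps", maxit))
  if (!res$monotone)
    stop("internal error: objective increased during coordinate descent")
  .ng_fit_obj(part, drop(res$alpha), drop(res$beta), lambda, weights,
              drop(res$objective), max(res$iterations))
}

.ng_fit_obj <- function(part, alpha, beta, lambda, weights, objective, iterations) {
  names(alpha) <- colnames(part$u)
  names(beta) <- colnames(part$n_mat)
  structure(
    list(alpha = alpha, beta = beta, lambda = lambda, weights = weights,
         objective_value = objective,
         selected_nonhubs = which(beta != 0),
         iterations = iterations, column_map = part$column_map,
         t = part$t, q = part$q),
    class = "ng_fit")
}

#' @export
print.ng_fit <- function(x, ...) {
  cat(sprintf(
    "Partially penalized fit: %d unpenalized + %d penalized terms, lambda = %.4g, %d selected\n",
    x$t, x$q, x$lambda, length(x$selected_nonhubs)))
  invisible(x)
}

#' @export
coef.ng_fit <- function(object, ...) c(object$alpha, object$beta)

#' Predict from a partially penalized fit
#'
#' @param object an `"ng_fit"`.
#' @param u_new,n_new design blocks matching the training partition.
#' @param ... unused.
#' @return predicted values `u_new alpha + n_new beta`.
#' @export
predict.ng_fit <- function(object, u_new, n_new, ...) {
  u_new <- as.matrix(u_new)
  n_new <- as.matrix(n_new)
  if (ncol(u_new) != object$t || ncol(n_new) != object$q)
    stop("column counts do not match the training partition")
  drop(u_new %*% object$alpha + n_new %*% object$beta)
}

#' Stationarity check for a partially penalized fit
#'
#' At the optimum, `U'(y - U alpha - N beta) = 0`, and for each penalized
#' coordinate `|2 N_j' r| <= lambda w_j` when `beta_j = 0` with equality and
#' the matching sign when `beta_j != 0`.
#'
#' @param fit an `"ng_fit"`.
#' @param part the `"design_partition"` it was fitted on.
#' @return maximum absolute violation of the conditions.
#' @export
ng_kkt <- function(fit, part) {
  r <- part$y - drop(part$u %*% fit$alpha) - drop(part$n_mat %*% fit$beta)
  v <- if (ncol(part$u)) max(abs(crossprod(part$u, r))) else 0
  if (part$q > 0L) {
    g <- 2 * drop(crossprod(part$n_mat, r))
    lw <- fit$lambda * fit$weights
    nz <- fit$beta != 0
    if (any(nz)) v <- max(v, abs(g[nz] - lw[nz] * sign(fit$beta[nz])))
    if (any(!nz)) v <- max(v, pmax(abs(g[!nz]) - lw[!nz], 0))
  }
  v
}

.lambda_path_ng <- function(part, weights, nlambda, lambda_min_ratio) {
  # smallest lambda that zeroes the whole penalized block, given that the
  # unpenalized block is profiled out
  a0 <- qr.coef(qr(part$u), part$y)
  a0[is.na(a0)] <- 0
  r0 <- part$y - drop(part$u %*% a0)
  g <- abs(2 * drop(crossprod(part$n_mat, r0))) / weights
  lmax <- max(g, 1e-12)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Cross-validated partially penalized adaptive lasso
#'
#' Selects the adaptive-weight exponent `nu` and penalty `lambda` jointly by
#' k-fold cross-validation. For each `nu`, a decreasing penalty path is built
#' from the full-data adaptive weights; within each fold the initial
#' estimator is recomputed on the training portion only (no leakage), the
#' path is refit, and held-out squared error is accumulated. The pair with
#' the smallest mean CV error wins, ties going to the larger `lambda` and
#' then the larger `nu` (the sparser model). The final fit uses the full data
#' at the chosen pair.
#'
#' @param part a `"design_partition"`.
#' @param nu_grid positive exponents to try.
#' @param cv_rule `"min"` or `"1se"`.
#' @param nfolds 5 or 10.
#' @param seed controls fold assignment and the internal elastic-net folds.
#' @param nlambda,lambda_min_ratio penalty-path geometry.
#' @param enet_mixing,ridge_perturb passed to [initial_estimator()].
#' @param tol,maxit passed to the coordinate-descent solver.
#' @return a list with `fit` (the chosen `"ng_fit"`), `nu`, `lambda`, and
#'   `cv` (grids, per-pair mean CV errors, fold ids).
#' @export
cv_ng <- function(part, nu_grid = c(0.5, 1, 2), cv_rule = c("1se", "min"),
                  nfolds = 5L, seed = NULL,
                  nlambda = 50L, lambda_min_ratio = 0.001,
                  enet_mixing = 0.5, ridge_perturb = NULL,
                  tol = 1e-9, maxit = 2000L) {
  stopifnot(inherits(part, "design_partition"))
  cv_rule <- match.arg(cv_rule)
  if (!nfolds %in% c(5L, 10L)) stop("`nfolds` must be 5 or 10")
  n <- length(part$y)
  if (n < 2L * nfolds) stop("need at least 2 observations per fold")
  q <- part$q

  if (q == 0L) {
    # no penalized block: plain least squares on u
    a <- qr.coef(qr(part$u), part$y)
    a[is.na(a)] <- 0
    r <- part$y - drop(part$u %*% a)
    fit <- .ng_fit_obj(part, a, numeric(0), 0, numeric(0), sum(r^2), 0L)
    return(list(fit = fit, nu = NA_real_, lambda = 0, cv = NULL))
  }

  mag_full <- initial_estimator(part, enet_mixing, ridge_perturb,
                                nfolds = nfolds, seed = seed)
  paths <- lapply(nu_grid, function(nu) {
    w <- adaptive_weights(mag_full, nu)
    list(nu = nu, w = w,
         lambda = .lambda_path_ng(part, w, nlambda, lambda_min_ratio))
  })

  foldid <- .foldid(n, nfolds, seed)
  fold_mse <- array(NA_real_, c(nfolds, length(nu_grid), nlambda))
  used_folds <- logical(nfolds)
  for (k in seq_len(nfolds)) {
    idx <- foldid == k
    if (var(part$y[!idx]) == 0) {
      warning(sprintf("fold %d has constant training outcome; skipped", k))
      next
    }
    tr <- .subset_partition(part, !idx)
    mag_k <- initial_estimator(tr, enet_mixing, ridge_perturb,
                               nfolds = nfolds,
                               seed = if (is.null(seed)) NULL else seed + k)
    for (i in seq_along(nu_grid)) {
      w_k <- adaptive_weights(mag_k, nu_grid[i])
      res <- .ng_cd_path(tr$u, tr$n_mat, tr$y, paths[[i]]$lambda, w_k,
                         tol, as.integer(maxit))
      pred <- part$u[idx, , drop = FALSE] %*% res$alpha +
        part$n_mat[idx, , drop = FALSE] %*% res$beta
      fold_mse[k, i, ] <- colMeans((pred - part$y[idx])^2)
    }
    used_folds[k] <- TRUE
  }
  if (!any(used_folds)) stop("all cross-validation folds were skipped")
  kk <- sum(used_folds)
  cvm <- apply(fold_mse[used_folds, , , drop = FALSE], c(2, 3), mean)
  cvse <- apply(fold_mse[used_folds, , , drop = FALSE], c(2, 3), sd) / sqrt(kk)

  # candidate pairs: at the minimum mean CV error, or (1se rule) within one
  # standard error of it; ties -> larger lambda, then larger nu
  m <- min(cvm)
  thr <- if (cv_rule == "1se") m + cvse[which.min(cvm)] else
    m + 1e-12 * (abs(m) + 1)
  cand <- which(cvm <= thr, arr.ind = TRUE)
  lam_cand <- mapply(function(i, l) paths[[i]]$lambda[l],
                     cand[, 1], cand[, 2])
  nu_cand <- sapply(cand[, 1], function(i) paths[[i]]$nu)
  pick <- order(-lam_cand, -nu_cand)[1]
  i <- cand[pick, 1]; l <- cand[pick, 2]
  w <- paths[[i]]$w
  res <- .ng_cd_path(part$u, part$n_mat, part$y,
                     paths[[i]]$lambda[seq_len(l)], w, tol, as.integer(maxit))
  fit <- .ng_fit_obj(part, res$alpha[, l], res$beta[, l],
                     paths[[i]]$lambda[l], w, res$objective[l],
                     max(res$iterations))
  list(fit = fit, nu = paths[[i]]$nu, lambda = paths[[i]]$lambda[l],
       cv = list(nu_grid = nu_grid, cv_rule = cv_rule,
                 lambda_paths = lapply(paths, `[[`, "lambda"),
                 cv_errors = cvm, cv_se = cvse, foldid = foldid,
                 chosen = c(nu = paths[[i]]$nu, lambda = paths[[i]]$lambda[l])))
}

.subset_partition <- function(part, keep) {
  structure(list(u = part$u[keep, , drop = FALSE],
                 n_mat = part$n_mat[keep, , drop = FALSE],
                 y = part$y[keep],
                 column_map = part$column_map,
                 t = part$t, q = part$q,
                 hub_indices = part$hub_indices,
                 nonhub_indices = part$nonhub_indices),
            class = "design_partition")
}
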