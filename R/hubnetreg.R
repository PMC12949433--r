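#' Network-guided penalized regression
#'
#' Fits the full two-stage pipeline. Stage one estimates a sparse
#' partial-correlation network over the columns of `x` by graphical lasso
#' with eBIC-selected penalty, scores features by network centrality and
#' declares the top `h = min(floor(p * delta), tau)` of them hubs
#' (`tau = floor((p + 20) / 16)` by default). Stage two regresses `y` on the
#' intercept, the confounders `z` and the hub features without penalty, with
#' an adaptive-lasso penalty on the remaining features, choosing the weight
#' exponent `nu` and penalty `lambda` jointly by k-fold cross-validation.
#'
#' With `delta` small enough that `h = 0` the model degenerates gracefully to
#' a plain adaptive lasso on all features (confounders still unpenalized).
#' Hub identification is performed once on the training data before
#' cross-validation, so the hub set is common across folds; the adaptive
#' weights, in contrast, are recomputed inside each training fold.
#'
#' @param x numeric sample-by-feature matrix with named columns.
#' @param z optional numeric confounder matrix (low-dimensional).
#' @param y continuous outcome vector.
#' @param delta hub proportion in (0, 1).
#' @param tau optional cap on the hub count.
#' @param gamma eBIC hyperparameter for the network stage.
#' @param centrality `"degree"` (default), `"betweenness"` or `"eigenvector"`.
#' @param nu_grid candidate adaptive-weight exponents.
#' @param cv_rule `"min"` or `"1se"` (see [cv_ng()]).
#' @param nfolds cross-validation folds (5 or 10).
#' @param seed integer seed controlling fold assignments.
#' @param standardize standardize columns before the network stage.
#' @param nlambda_net,lambda_min_ratio_net graphical-lasso path geometry.
#' @param nlambda,lambda_min_ratio regression penalty-path geometry.
#' @param enet_mixing,ridge_perturb initial-estimator settings.
#' @param ... passed on to [cv_ng()].
#' @return an object of class `"hubnetreg"` with components `network`
#'   (`"ggm_network"`), `centrality`, `hubs` (`"hub_partition"`), `partition`,
#'   `fit` (`"ng_fit"`), `nu`, `lambda`, `cv`, `coefficients` (full named
#'   vector), `call`, and the training data dimensions.
#' @seealso [predict.hubnetreg()], [coef.hubnetreg()], [fit_baseline()]
#' @export
#' @examples
#' d <- sim_data(sim_scenario(n = 60, p = 20, signal = "weak", seed = 3, test_n = 50))
#' m <- hubnetreg(d$x_train, d$z_train, d$y_train, delta = 0.1, seed = 1)
#' coef(m)[1:6]
hubnetreg <- function(x, z = NULL, y, delta = 0.02, tau = NULL, gamma = 0,
                      centrality = c("degree", "betweenness", "eigenvector"),
                      nu_grid = c(0.5, 1, 2), cv_rule = c("1se", "min"),
                      nfolds = 5L, seed = NULL,
                      standardize = TRUE,
                      nlambda_net = 30L, lambda_min_ratio_net = 0.01,
                      nlambda = 50L, lambda_min_ratio = 0.001,
                      enet_mixing = 0.5, ridge_perturb = NULL, ...) {
  centrality <- match.arg(centrality)
  x <- as.matrix(x)
  net <- ggm_network(x, gamma = gamma, nlambda = nlambda_net,
                     lambda_min_ratio = lambda_min_ratio_net,
                     standardize = standardize)
  sc <- centrality_scores(net, centrality)
  if (sc$degenerate)
    warning("estimated network has no edges; hub choice falls back to the index tie-break")
  h <- hub_count(ncol(x), delta, tau)
  hubs <- select_hubs(sc, h, delta = delta,
                      tau = if (is.null(tau)) floor((ncol(x) + 20) / 16) else tau)
  part <- build_partition(x, z, y, hubs)
  cv_rule <- match.arg(cv_rule)
  sel <- cv_ng(part, nu_grid = nu_grid, cv_rule = cv_rule, nfolds = nfolds,
               seed = seed,
               nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
               enet_mixing = enet_mixing, ridge_perturb = ridge_perturb, ...)
  coefs <- c(sel$fit$alpha, sel$fit$beta)
  structure(
    list(network = net, centrality = sc, hubs = hubs, partition = part,
         fit = sel$fit, nu = sel$nu, lambda = sel$lambda, cv = sel$cv,
         coefficients = coefs, delta = delta, gamma = gamma,
         seed = seed, n = nrow(x), p = ncol(x),
         c = if (is.null(z)) 0L else ncol(z),
         call = match.call()),
    class = "hubnetreg")
}

#' @export
print.hubnetreg <- function(x, ...) {
  cat("Network-guided penalized regression\n\n")
  cat(sprintf("  n = %d samples, p = %d features, %d confounder(s)\n",
              x$n, x$p, x$c))
  cat(sprintf("  network: %d edges (lambda = %.4g by eBIC, gamma = %.2g)\n",
              x$network$fit$n_edges, x$network$lambda, x$gamma))
  hn <- x$hubs$feature_names[x$hubs$hub_indices]
  cat(sprintf("  hubs (h = %d, delta = %.3g): %s\n", x$hubs$h, x$delta,
              if (length(hn)) paste(hn, collapse = ", ") else "none"))
  cat(sprintf("  selected non-hubs: %d of %d (nu = %.2g, lambda = %.4g)\n",
              length(x$fit$selected_nonhubs), x$fit$q, x$nu, x$lambda))
  invisible(x)
}

#' @export
summary.hubnetreg <- function(object, ...) {
  cm <- object$fit$column_map
  est <- c(object$fit$alpha, object$fit$beta)
  tab <- data.frame(feature = cm$name, block = cm$block,
                    estimate = as.numeric(est),
                    selected = as.numeric(est) != 0 | cm$block != "nonhub",
                    row.names = NULL)
  out <- list(coefficients = tab, nu = object$nu, lambda = object$lambda,
              h = object$hubs$h, n_edges = object$network$fit$n_edges,
              network_lambda = object$network$lambda, obj = object)
  class(out) <- "summary.hubnetreg"
  out
}

#' @export
print.summary.hubnetreg <- function(x, ...) {
  print(x$obj)
  cat("\nNonzero coefficients:\n")
  tab <- x$coefficients
  print(tab[tab$estimate != 0, ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Coefficients of a network-guided fit
#'
#' @param object a `"hubnetreg"`.
#' @param block `"all"` for the full named vector in design order
#'   (intercept, confounders, hubs, non-hubs), or one of the block names.
#' @param ... unused.
#' @export
coef.hubnetreg <- function(object, block = c("all", "intercept", "confounder",
                                             "hub", "nonhub"), ...) {
  block <- match.arg(block)
  est <- c(object$fit$alpha, object$fit$beta)
  if (block == "all") return(est)
  est[object$fit$column_map$block == block]
}

.design_blocks <- function(object, newx, newz) {
  newx <- as.matrix(newx)
  if (ncol(newx) != object$p) stop("`newx` must have p columns")
  n <- nrow(newx)
  if (object$c > 0L) {
    if (is.null(newz)) stop("model was fitted with confounders; supply `newz`")
    newz <- as.matrix(newz)
    if (nrow(newz) != n || ncol(newz) != object$c)
      stop("`newz` dimensions do not match the fitted confounder block")
  } else newz <- NULL
  u <- cbind(rep(1, n), newz, newx[, object$hubs$hub_indices, drop = FALSE])
  nm <- newx[, object$hubs$nonhub_indices, drop = FALSE]
  list(u = u, n = nm)
}

#' Predict method for network-guided fits
#'
#' @param object a `"hubnetreg"`.
#' @param newx feature matrix with the same columns as training `x`.
#' @param newz confounder matrix (required iff the model used one).
#' @param ... unused.
#' @return predicted outcomes.
#' @export
predict.hubnetreg <- function(object, newx, newz = NULL, ...) {
  b <- .design_blocks(object, newx, newz)
  predict(object$fit, b$u, b$n)
}

#' @export
fitted.hubnetreg <- function(object, ...) {
  predict(object$fit, object$partition$u, object$partition$n_mat)
}

#' @export
residuals.hubnetreg <- function(object, ...) {
  object$partition$y - fitted(object)
}

#' Plot a network-guided fit
#'
#' `type = "network"` draws the estimated partial-correlation network with
#' hub nodes highlighted; `type = "cv"` shows the cross-validation error
#' across the penalty path for each weight exponent.
#'
#' @param x a `"hubnetreg"`.
#' @param type `"network"` or `"cv"`.
#' @param ... passed to the underlying plotting function.
#' @export
plot.hubnetreg <- function(x, type = c("network", "cv"), ...) {
  type <- match.arg(type)
  if (type == "network") {
    a <- abs(x$network$rho)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    cols <- ifelse(seq_len(x$p) %in% x$hubs$hub_indices, "tomato", "grey70")
    igraph::plot.igraph(g, vertex.color = cols,
                        vertex.size = 6 + 10 * (seq_len(x$p) %in% x$hubs$hub_indices),
                        edge.width = 3 * igraph::E(g)$weight, ...)
  } else {
    cvm <- x$cv$cv_errors
    lams <- x$cv$lambda_paths
    graphics::matplot(log(lams[[1]]), t(cvm), type = "l", lty = 1,
                      xlab = "log lambda", ylab = "mean CV error", ...)
    graphics::legend("topleft", legend = paste("nu =", x$cv$nu_grid),
                     col = seq_along(x$cv$nu_grid), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Simulate outcomes from a fitted model
#'
#' Draws new outcomes from the fitted linear predictor plus Gaussian noise
#' with the residual standard deviation.
#'
#' @param object a `"hubnetreg"`.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return a data frame with `nsim` columns.
#' @export
simulate.hubnetreg <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  df_res <- max(1, object$n - object$fit$t - length(object$fit$selected_nonhubs))
  s <- sqrt(sum(residuals(object)^2) / df_res)
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), sd = s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
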