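# Independent solvers used as oracles. Both attack the same convex objectives
# as the package but with different algorithm families, so agreement is a
# genuine cross-check rather than a reimplementation.

# ADMM solver for the graphical-lasso objective
#   max log det(Theta) - tr(S Theta) - lam * sum_{j != k} |theta_jk|
# (off-diagonal penalty only). Returns the sparse iterate Z.
admm_glasso <- function(S, lam, rho = 1, iter = 3000, abstol = 1e-7) {
  p <- nrow(S)
  Theta <- diag(1 / diag(S))
  Z <- Theta
  U <- matrix(0, p, p)
  off <- row(Z) != col(Z)
  for (k in seq_len(iter)) {
    e <- eigen((rho * (Z - U) - S) / rho, symmetric = TRUE)
    d <- (e$values + sqrt(e$values^2 + 4 / rho)) / 2
    Theta <- e$vectors %*% (d * t(e$vectors))
    Zold <- Z
    A <- Theta + U
    Z <- A
    Z[off] <- sign(A[off]) * pmax(abs(A[off]) - lam / rho, 0)
    U <- U + Theta - Z
    if (max(abs(Theta - Z)) < abstol && max(abs(Z - Zold)) < abstol) break
  }
  (Z + t(Z)) / 2
}

glasso_objective <- function(Theta, S, lam) {
  determinant(Theta, logarithm = TRUE)$modulus[1] - sum(S * Theta) -
    lam * sum(abs(Theta[row(Theta) != col(Theta)]))
}

# Proximal-gradient (ISTA) solver for the partially penalized objective
#   ||y - U a - N b||^2 + lam * sum_j w_j |b_j|
# over the joint coefficient vector; the prox leaves the unpenalized block
# untouched.
ista_ng <- function(u, n_mat, y, lam, w, iter = 200000, tol = 1e-14) {
  d <- cbind(u, n_mat)
  t_ <- ncol(u)
  q <- ncol(n_mat)
  L <- 2 * max(eigen(crossprod(d), symmetric = TRUE, only.values = TRUE)$values)
  s <- 1 / L
  th <- numeric(t_ + q)
  for (k in seq_len(iter)) {
    r <- y - d %*% th
    g <- -2 * drop(crossprod(d, r))
    th_new <- th - s * g
    idx <- (t_ + 1):(t_ + q)
    th_new[idx] <- sign(th_new[idx]) * pmax(abs(th_new[idx]) - s * lam * w, 0)
    if (max(abs(th_new - th)) < tol) { th <- th_new; break }
    th <- th_new
  }
  list(alpha = th[seq_len(t_)], beta = th[(t_ + 1):(t_ + q)])
}

ng_objective <- function(u, n_mat, y, alpha, beta, lam, w) {
  sum((y - u %*% alpha - n_mat %*% beta)^2) + lam * sum(w * abs(beta))
}

# small correlated regression fixture used across regression tests
make_toy <- function(n = 30, p = 8, seed = 1, rho = 0.5) {
  set.seed(seed)
  S <- rho^abs(outer(1:p, 1:p, "-"))
  x <- matrix(rnorm(n * p), n, p) %*% chol(S)
  colnames(x) <- paste0("P", 1:p)
  z <- cbind(Z1 = runif(n))
  beta <- c(2, -1.5, rep(0, p - 2))
  y <- drop(1 + z %*% 0.5 + x %*% beta + rnorm(n))
  list(x = x, z = z, y = y, beta = beta)
}
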