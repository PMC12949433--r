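test_that("empirical covariance is the divisor-n MLE", {
  x <- matrix(c(1, 2, 3, 4, 2, 4, 7, 9, 0, 1, 1, 3), 4, 3)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(empirical_covariance(x), crossprod(xc) / 4)
  # two identical samples carry no variance
  expect_equal(empirical_covariance(rbind(c(1, 2), c(1, 2))),
               matrix(0, 2, 2))
  # a collinear column forces singularity (the motivation for regularizing)
  y <- cbind(rnorm(6), 0)
  y[, 2] <- 3 * y[, 1]
  expect_equal(det(empirical_covariance(y)), 0)
  expect_error(empirical_covariance(matrix(c(1, NA, 2, 3), 2)), "missing")
  expect_error(empirical_covariance(matrix(1, 1, 2)), "two samples")
})

test_that("graphical lasso obeys its closed-form limits", {
  set.seed(42)
  x <- matrix(rnorm(300 * 4), 300, 4) %*% chol(0.5^abs(outer(1:4, 1:4, "-")))
  S <- empirical_covariance(x)
  lmax <- max(abs(S[upper.tri(S)]))
  # fully penalized: diagonal estimate with 1/S_jj
  f <- glasso_fit(S, lmax + 0.01)
  expect_equal(f$n_edges, 0L)
  expect_equal(diag(f$theta), 1 / diag(S), tolerance = 1e-8)
  expect_equal(f$theta[upper.tri(f$theta)], rep(0, 6))
  # unpenalized: the precision MLE
  f0 <- glasso_fit(S, 0, tol = 1e-7)
  expect_equal(f0$theta, solve(S), tolerance = 1e-4, ignore_attr = TRUE)
  expect_error(glasso_fit(S, -1), "nonnegative")
  expect_error(glasso_fit(S[, 1:3], 0.1), "symmetric")
})

test_that("graphical lasso agrees with an ADMM oracle on the same objective", {
  # 3x3 covariance with a known sparse inverse structure
  Th_true <- matrix(c(2, -1, 0, -1, 2, -1, 0, -1, 2), 3, 3)
  S_pop <- solve(Th_true)
  for (lam in c(0.02, 0.1)) {
    f <- glasso_fit(S_pop, lam, tol = 1e-7)
    z <- admm_glasso(S_pop, lam)
    expect_gte(glasso_objective(f$theta, S_pop, lam),
               glasso_objective(z, S_pop, lam) - 1e-5)
    expect_lt(max(abs(f$theta - z)), 1e-3)
  }
  # a larger random instance, objective equivalence only
  set.seed(5)
  x <- matrix(rnorm(200 * 5), 200, 5)
  S <- empirical_covariance(x)
  f <- glasso_fit(S, 0.08, tol = 1e-7)
  z <- admm_glasso(S, 0.08)
  expect_gte(glasso_objective(f$theta, S, 0.08),
             glasso_objective(z, S, 0.08) - 1e-6)
})

test_that("stationarity conditions hold along a penalty path", {
  set.seed(11)
  d <- sim_data(sim_scenario(n = 80, p = 12, signal = "weak", seed = 11, test_n = 5))
  S <- empirical_covariance(scale(d$x_train, scale = TRUE))
  lmax <- max(abs(S[upper.tri(S)]))
  warm <- NULL
  for (lam in exp(seq(log(lmax), log(0.05 * lmax), length.out = 8))) {
    f <- glasso_fit(S, lam, tol = 1e-6, warm = warm)
    warm <- list(w = f$w, B = f$B)
    expect_lt(glasso_kkt(f, S), 1e-3)
  }
})

test_that("eBIC matches its formula and penalizes edges monotonically", {
  set.seed(3)
  x <- matrix(rnorm(50 * 2), 50, 2)
  S <- empirical_covariance(x)
  f <- glasso_fit(S, 0.01)
  expect_equal(f$n_edges, 1L)
  # penalized log-likelihood, hand-computed plug-in value, E = 1
  ll <- (50 / 2) * (determinant(f$theta, logarithm = TRUE)$modulus[1] -
                      sum(S * f$theta) - 0.01 * 2 * abs(f$theta[1, 2]))
  expect_equal(ebic(f, n = 50, p = 2, gamma = 0.25),
               -2 * ll + 1 * log(50) + 4 * 0.25 * 1 * log(2),
               ignore_attr = TRUE)
  # gamma = 0 reduces to the ordinary BIC
  expect_equal(ebic(f, n = 50, gamma = 0), -2 * ll + log(50), ignore_attr = TRUE)
  # for equal likelihood, more edges always score worse when gamma > 0
  f2 <- f
  f2$n_edges <- f$n_edges + 3L
  expect_gt(ebic(f2, n = 50, gamma = 0.5), ebic(f, n = 50, gamma = 0.5))
  expect_error(ebic(f, n = 50, gamma = 1.5), "0, 1")
})

test_that("partial correlations standardize with a sign reversal", {
  expect_equal(partial_correlations(diag(3)), matrix(0, 3, 3))
  th <- matrix(c(2, -1, -1, 2), 2, 2)
  expect_equal(partial_correlations(th)[1, 2], 0.5)
  set.seed(8)
  a <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
  r <- partial_correlations(a)
  expect_equal(r, t(r))
  expect_equal(diag(r), rep(0, 6))
  expect_true(all(abs(r) <= 1 + 1e-12))
  bad <- diag(3); bad[1, 1] <- -1
  expect_error(partial_correlations(bad), "diagonal")
})

test_that("network selection respects the grid and the gamma ordering", {
  set.seed(21)
  d <- sim_data(sim_scenario(n = 120, p = 10, signal = "weak", seed = 21, test_n = 5))
  x <- d$x_train
  # a one-value grid returns that fit
  net1 <- ggm_network(x, lambda = 0.2)
  expect_equal(net1$lambda, 0.2)
  expect_length(net1$ebic, 1L)
  # higher gamma never selects a denser model on the same grid
  S <- empirical_covariance(scale(x))
  lmax <- max(abs(S[upper.tri(S)]))
  grid <- exp(seq(log(lmax), log(0.05 * lmax), length.out = 12))
  prev_edges <- Inf
  for (g in c(0, 0.5, 1)) {
    net <- ggm_network(x, gamma = g, lambda = grid, patience = Inf)
    expect_lte(net$fit$n_edges, prev_edges)
    prev_edges <- net$fit$n_edges
  }
  # the path starts empty at lambda_max and is denser at the small end
  net <- ggm_network(x, gamma = 0)
  expect_equal(net$n_edges[1], 0L)
  expect_gt(net$n_edges[length(net$n_edges)], net$n_edges[1])
})

test_that("the penalty path recovers a planted two-block structure", {
  blockS <- matrix(0, 6, 6)
  blockS[1:3, 1:3] <- 0.6
  blockS[4:6, 4:6] <- 0.6
  diag(blockS) <- 1
  ch <- chol(blockS)
  true_pattern <- blockS != 0 & row(blockS) != col(blockS)
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    x <- matrix(rnorm(400 * 6), 400, 6) %*% ch
    colnames(x) <- paste0("V", 1:6)
    S <- empirical_covariance(scale(x))
    lmax <- max(abs(S[upper.tri(S)]))
    warm <- NULL
    found <- FALSE
    for (lam in exp(seq(log(lmax), log(0.01 * lmax), length.out = 30))) {
      f <- glasso_fit(S, lam, warm = warm)
      warm <- list(w = f$w, B = f$B)
      if (identical(unname(f$theta != 0 & row(blockS) != col(blockS)),
                    unname(true_pattern))) { found <- TRUE; break }
    }
    hits <- hits + found
  }
  expect_gte(hits, 9L)
})
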