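test_that("design partitioning keeps blocks disjoint and mapped", {
  toy <- make_toy(40, 10, seed = 4)
  hubs <- select_hubs(setNames(10:1, colnames(toy$x)), 3L)
  part <- build_partition(toy$x, toy$z, toy$y, hubs)
  expect_identical(part$t, 5L)   # intercept + 1 confounder + 3 hubs
  expect_identical(part$q, 7L)
  expect_identical(part$column_map$block,
                   c("intercept", "confounder", rep("hub", 3), rep("nonhub", 7)))
  # round trip: every design column is recoverable by name
  expect_setequal(part$column_map$name,
                  c("(Intercept)", "Z1", colnames(toy$x)))
  # boundary: no hubs, no confounders -> intercept-only unpenalized block
  p0 <- build_partition(toy$x, NULL, toy$y, select_hubs(rep(0, 10), 0L))
  expect_identical(p0$t, 1L)
  expect_identical(p0$q, 10L)
  expect_error(build_partition(toy$x, toy$z[1:5, , drop = FALSE], toy$y, hubs),
               "row counts")
})

test_that("initial magnitudes are positive and reduce to OLS on tiny designs", {
  toy <- make_toy(40, 10, seed = 5)
  hubs <- select_hubs(setNames(rep(0, 10), colnames(toy$x)), 0L)
  part <- build_partition(toy$x, toy$z, toy$y, hubs)
  mag <- initial_estimator(part, seed = 1)
  expect_length(mag, 10L)
  expect_true(all(mag > 0))
  # one penalized predictor and intercept only: closed-form OLS fallback
  x1 <- toy$x[, 1, drop = FALSE]
  p1 <- build_partition(x1, NULL, toy$y, select_hubs(setNames(0, "P1"), 0L))
  mag1 <- initial_estimator(p1, ridge_perturb = 0.025)
  ols <- unname(coef(lm(toy$y ~ x1))[2])
  expect_equal(unname(mag1), abs(ols) + 0.025, tolerance = 1e-10)
  expect_error(initial_estimator(part, enet_mixing = 0), "0, 1")
})

test_that("adaptive weights are reciprocal powers of the magnitudes", {
  expect_equal(adaptive_weights(c(2, 0.5), 1), c(0.5, 2))
  expect_equal(adaptive_weights(4, 0.5), 0.5)
  expect_equal(adaptive_weights(c(2, 0.5), 1e-9), c(1, 1), tolerance = 1e-6)
  expect_error(adaptive_weights(c(1, 0), 1), "positive")
  expect_error(adaptive_weights(c(1, 2), -1), "positive")
})

test_that("the partially penalized solver hits its exact limits", {
  toy <- make_toy(60, 6, seed = 6)
  hubs <- select_hubs(setNames(6:1, colnames(toy$x)), 2L)
  part <- build_partition(toy$x, toy$z, toy$y, hubs)
  w <- rep(1, part$q)
  # lambda = 0: joint OLS
  f0 <- fit_ng(part, 0, w)
  ols <- unname(coef(lm(toy$y ~ cbind(part$u[, -1], part$n_mat))))
  expect_equal(unname(c(f0$alpha, f0$beta)), ols, tolerance = 1e-6)
  # huge lambda: penalized block zeroed, alpha = OLS on u alone
  fL <- fit_ng(part, 1e7, w)
  expect_equal(unname(fL$beta), rep(0, part$q))
  expect_equal(unname(fL$alpha),
               unname(coef(lm(toy$y ~ part$u[, -1]))), tolerance = 1e-8)
  expect_length(fL$selected_nonhubs, 0L)
  # objective value recomputes from the stored coefficients
  f <- fit_ng(part, 3, w)
  expect_equal(f$objective_value,
               ng_objective(part$u, part$n_mat, toy$y, f$alpha, f$beta, 3, w),
               tolerance = 1e-8)
  expect_lt(ng_kkt(f, part), 1e-6)
  expect_error(fit_ng(part, -1, w), "nonnegative")
  expect_error(fit_ng(part, 1, w[-1]), "length q")
})

test_that("solver matches proximal-gradient and glmnet oracles", {
  for (s in 1:2) {
    toy <- make_toy(30, 8, seed = 20 + s)
    hubs <- select_hubs(setNames(8:1, colnames(toy$x)), 2L)
    part <- build_partition(toy$x, toy$z, toy$y, hubs)
    set.seed(s)
    w <- runif(part$q, 0.2, 3)
    lam <- 2.5
    f <- fit_ng(part, lam, w)
    o <- ista_ng(part$u, part$n_mat, part$y, lam, w)
    expect_lt(max(abs(c(f$alpha, f$beta) - c(o$alpha, o$beta))), 1e-6)
    # glmnet solves the same objective under the penalty.factor mapping
    d <- cbind(part$u[, -1], part$n_mat)
    pf <- c(rep(0, part$t - 1), w)
    m <- ncol(d)
    lam_g <- lam * sum(pf) / (2 * length(toy$y) * m)
    g <- glmnet::glmnet(d, toy$y, alpha = 1, penalty.factor = pf,
                        lambda = lam_g, standardize = FALSE, thresh = 1e-14)
    gc_ <- as.numeric(coef(g))
    expect_lt(max(abs(c(f$alpha, f$beta) -
                        c(gc_[1], gc_[-1]))), 1e-4)
  }
})

test_that("predictions satisfy least-squares stationarity in the free block", {
  toy <- make_toy(50, 6, seed = 9)
  hubs <- select_hubs(setNames(6:1, colnames(toy$x)), 1L)
  part <- build_partition(toy$x, toy$z, toy$y, hubs)
  f <- fit_ng(part, 4, rep(1, part$q))
  pred <- predict(f, part$u, part$n_mat)
  expect_lt(max(abs(crossprod(part$u, toy$y - pred))), 1e-6)
  # all-zero inputs with an intercept column give the intercept back
  expect_equal(unname(predict(f, matrix(c(1, 0, 0), 1), matrix(0, 1, part$q))),
               unname(f$alpha[1]))
  expect_error(predict(f, part$u[, -1], part$n_mat), "column counts")
})

test_that("cross-validated selection is seed-deterministic and degenerates sanely", {
  toy <- make_toy(50, 8, seed = 10)
  hubs <- select_hubs(setNames(8:1, colnames(toy$x)), 2L)
  part <- build_partition(toy$x, toy$z, toy$y, hubs)
  a <- cv_ng(part, seed = 77)
  b <- cv_ng(part, seed = 77)
  expect_identical(a$nu, b$nu)
  expect_identical(a$lambda, b$lambda)
  expect_equal(a$fit$beta, b$fit$beta)
  # one-point nu grid returns that exponent
  c1 <- cv_ng(part, nu_grid = 1, seed = 1)
  expect_identical(c1$nu, 1)
  # empty penalized block: plain least squares on u
  pfull <- build_partition(toy$x, toy$z, toy$y,
                           select_hubs(setNames(8:1, colnames(toy$x)), 8L))
  cf <- cv_ng(pfull, seed = 1)
  expect_identical(cf$lambda, 0)
  expect_equal(unname(c(cf$fit$alpha)),
               unname(coef(lm(toy$y ~ cbind(toy$z, toy$x)))), tolerance = 1e-8)
  expect_error(cv_ng(part, nfolds = 3L), "5 or 10")
})

test_that("hub and confounder coefficients are never zeroed by the penalty", {
  for (s in 1:4) {
    d <- sim_data(sim_scenario(n = 60, p = 20, signal = "weak",
                               seed = 30 + s, test_n = 5))
    m <- suppressWarnings(hubnetreg(d$x_train, d$z_train, d$y_train,
                                    delta = 0.1, seed = s))
    free <- coef(m)[m$fit$column_map$block %in% c("confounder", "hub")]
    expect_true(all(free != 0))
  }
})

test_that("the fitted model object supports the standard S3 surface", {
  d <- sim_data(sim_scenario(n = 60, p = 15, signal = "weak", seed = 44, test_n = 40))
  m <- suppressWarnings(hubnetreg(d$x_train, d$z_train, d$y_train,
                                  delta = 0.1, seed = 2))
  expect_s3_class(m, "hubnetreg")
  expect_output(print(m), "Network-guided")
  expect_output(print(summary(m)), "Nonzero coefficients")
  expect_length(coef(m), 16L + 3L)  # p + c + intercept
  expect_identical(names(coef(m))[1], "(Intercept)")
  pr <- predict(m, d$x_test, d$z_test)
  expect_length(pr, 40L)
  expect_equal(fitted(m) + residuals(m), d$y_train, ignore_attr = TRUE)
  sim <- simulate(m, nsim = 2, seed = 1)
  expect_identical(dim(sim), c(60L, 2L))
  expect_error(predict(m, d$x_test), "confounders")
})
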