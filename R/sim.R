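#' Feature covariance for the simulation design
#'
#' Builds the hub-cluster / autoregressive covariance used by the synthetic
#' data generator: unit variances, correlation 0.9 between every pair of the
#' first four features (a tightly knit clique that acts as the hub cluster),
#' and correlation \eqn{0.9^{|j-k|}} for every other pair (an AR(1)-type chain
#' that decays with index distance, so the clique sits embedded in the chain).
#' Positive definiteness is verified at construction.
#'
#' @param p number of features (at least 5).
#' @return a `p x p` covariance (correlation) matrix.
#' @export
#' @examples
#' S <- sim_sigma(8)
#' all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0)
sim_sigma <- function(p) {
  if (p < 5) stop("sim_sigma() requires p >= 5")
  S <- 0.9^abs(outer(seq_len(p), seq_len(p), "-"))
  S[1:4, 1:4] <- 0.9
  diag(S) <- 1
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("internal error: simulation covariance not positive definite")
  S
}

#' Specify a simulation scenario
#'
#' A scenario bundles the sample size, feature dimension, signal pattern and
#' seed of one synthetic data configuration. The named settings are
#' `"I"` = (n = 50, p = 60), `"II"` = (n = 100, p = 60) and
#' `"III"` = (n = 100, p = 300); `n` and `p` may also be given directly.
#'
#' Under the strong signal the feature coefficients are 3.5 on features 1-5,
#' -1.5 on features 11-15 and 0 elsewhere; under the weak signal they are
#' (1, -0.8, 0.6, 0, 0, -1.5, -0.5, 1.2) on features 1-8 and 0 elsewhere.
#' Confounders are Z1 ~ U(0,1), Z2 ~ Bernoulli(0.25), Z3 ~ Bernoulli(0.65)
#' with coefficients `zeta`, and the outcome is linear Gaussian:
#' `y = mu + Z zeta + X eta + eps`, `eps ~ N(0, sigma^2)`.
#'
#' @param setting one of `"I"`, `"II"`, `"III"`, or `NULL` when `n`, `p` given.
#' @param signal `"strong"` or `"weak"`.
#' @param n,p sample size and dimension (override the named setting).
#' @param seed integer seed; the test draw uses a fixed offset of this seed.
#' @param test_n size of the independent evaluation set.
#' @param sigma noise standard deviation.
#' @param mu intercept.
#' @param zeta length-3 confounder coefficients.
#' @return an object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(setting = NULL, signal = c("strong", "weak"),
                         n = NULL, p = NULL, seed = 1L, test_n = 1000L,
                         sigma = 1, mu = 0.5, zeta = c(2.5, 2.5, 2.5)) {
  signal <- match.arg(signal)
  if (!is.null(setting)) {
    setting <- match.arg(as.character(setting), c("I", "II", "III"))
    dims <- switch(setting, I = c(50L, 60L), II = c(100L, 60L), III = c(100L, 300L))
    if (is.null(n)) n <- dims[1]
    if (is.null(p)) p <- dims[2]
  }
  if (is.null(n) || is.null(p)) stop("give either `setting` or both `n` and `p`")
  pmin_needed <- if (signal == "strong") 15L else 8L
  if (p < pmin_needed)
    stop(sprintf("p must be at least %d for the %s signal", pmin_needed, signal))
  if (sigma <= 0) stop("sigma must be positive")
  if (length(zeta) != 3L) stop("zeta must have length 3")
  structure(
    list(setting = if (is.null(setting)) NA_character_ else setting,
         signal = signal, n = as.integer(n), p = as.integer(p),
         seed = as.integer(seed), test_n = as.integer(test_n),
         sigma = sigma, mu = mu, zeta = zeta),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario%s: n = %d, p = %d, %s signal, seed = %d\n",
              if (is.na(x$setting)) "" else paste0(" ", x$setting),
              x$n, x$p, x$signal, x$seed))
  invisible(x)
}

#' True feature coefficients for a signal scenario
#' @param p number of features.
#' @param signal `"strong"` or `"weak"`.
#' @return numeric vector of length `p`.
#' @export
sim_eta <- function(p, signal = c("strong", "weak")) {
  signal <- match.arg(signal)
  eta <- numeric(p)
  if (signal == "strong") {
    eta[1:5] <- 3.5
    eta[11:15] <- -1.5
  } else {
    eta[1:8] <- c(1, -0.8, 0.6, 0, 0, -1.5, -0.5, 1.2)
  }
  eta
}

.sim_draw <- function(m, p, chol_S, scn) {
  x <- matrix(rnorm(m * p), m, p) %*% chol_S
  z <- cbind(Z1 = runif(m), Z2 = rbinom(m, 1, 0.25), Z3 = rbinom(m, 1, 0.65))
  colnames(x) <- paste0("P", seq_len(p))
  eta <- sim_eta(p, scn$signal)
  lp <- drop(scn$mu + z %*% scn$zeta + x %*% eta)
  y <- lp + scn$sigma * rnorm(m)
  list(x = x, z = z, y = y, lp = lp)
}

#' Generate one training/evaluation dataset from a scenario
#'
#' Draws an independent training set of size `n` and evaluation set of size
#' `test_n` from the scenario's data-generating process. The two draws use
#' seeds derived from the scenario seed by fixed offsets, so a dataset is
#' fully reproducible from its scenario. The noiseless linear predictor of
#' both splits is returned alongside the noisy outcome, since prediction
#' performance is measured against the regression surface.
#'
#' @param scenario a [sim_scenario()] object.
#' @return an object of class `"sim_data"` with elements `x_train`, `z_train`,
#'   `y_train`, `mu_train`, `x_test`, `z_test`, `y_test`, `mu_test`,
#'   `eta`, `true_support` (indices of nonzero feature coefficients) and
#'   the generating `scenario`.
#' @export
#' @examples
#' d <- sim_data(sim_scenario("I", "strong", seed = 7, test_n = 50))
#' dim(d$x_train)
sim_data <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  chol_S <- chol(sim_sigma(scenario$p))
  set.seed(scenario$seed)
  tr <- .sim_draw(scenario$n, scenario$p, chol_S, scenario)
  set.seed(scenario$seed + 1000003L)
  te <- .sim_draw(scenario$test_n, scenario$p, chol_S, scenario)
  eta <- sim_eta(scenario$p, scenario$signal)
  support <- which(eta != 0)
  expected <- if (scenario$signal == "strong") c(1:5, 11:15) else c(1:3, 6:8)
  stopifnot(identical(support, as.integer(expected)))
  structure(
    list(x_train = tr$x, z_train = tr$z, y_train = tr$y, mu_train = tr$lp,
         x_test = te$x, z_test = te$z, y_test = te$y, mu_test = te$lp,
         eta = eta, true_support = support, scenario = scenario),
    class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  train %d x %d, test %d x %d, %d nonzero feature coefficients\n",
              nrow(x$x_train), ncol(x$x_train), nrow(x$x_test), ncol(x$x_test),
              length(x$true_support)))
  invisible(x)
}
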