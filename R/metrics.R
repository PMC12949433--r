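#' Root-mean-squared error
#'
#' @param y_true reference values. When evaluating prediction models on
#'   synthetic data this is the noiseless regression surface, so the value
#'   measures estimation error rather than irreducible noise.
#' @param y_pred predictions.
#' @export
#' @examples
#' rmse(c(0, 0, 0), c(1, -1, 1))  # 1
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  sqrt(mean((y_true - y_pred)^2))
}

#' Calibration slope
#'
#' Slope of the least-squares regression of observed outcomes on predictions
#' (with intercept). An ideal model has slope 1; slopes above 1 indicate
#' over-shrunk (under-dispersed) predictions.
#'
#' @param y_true observed outcomes.
#' @param y_pred predictions.
#' @return the slope, or `NA` when the predictions are constant.
#' @export
calibration_slope <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (var(y_pred) == 0) return(NA_real_)
  unname(coef(lm(y_true ~ y_pred))[2L])
}

#' Selection confusion counts
#'
#' Compares the nonzero pattern of fitted coefficients against the true
#' support over a candidate set of variables (all features plus all
#' confounders; the intercept is excluded). "Nonzero" means exactly nonzero
#' as stored — coordinate-descent solvers produce exact zeros — so
#' unpenalized coefficients (confounders, hubs) always count as selected.
#'
#' @param fitted_coefs named numeric vector over the candidate variables.
#' @param true_support names (or indices into `fitted_coefs`) of the truly
#'   nonzero variables.
#' @return integer vector `c(tp, fp, tn, fn)`.
#' @export
selection_counts <- function(fitted_coefs, true_support) {
  k <- length(fitted_coefs)
  truth <- rep(FALSE, k)
  if (is.character(true_support)) {
    if (is.null(names(fitted_coefs))) stop("named support requires named coefficients")
    miss <- setdiff(true_support, names(fitted_coefs))
    if (length(miss)) stop("support outside candidate set: ", paste(miss, collapse = ", "))
    truth[match(true_support, names(fitted_coefs))] <- TRUE
  } else {
    if (any(true_support < 1 | true_support > k))
      stop("support indices outside candidate set")
    truth[true_support] <- TRUE
  }
  sel <- fitted_coefs != 0
  c(tp = sum(sel & truth), fp = sum(sel & !truth),
    tn = sum(!sel & !truth), fn = sum(!sel & truth))
}

#' F1 score and Matthews correlation from confusion counts
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`;
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' The MCC is undefined (returned as `NA`) whenever a marginal factor of its
#' denominator is zero — as happens for methods that select every candidate,
#' where TN = FN = 0.
#'
#' @param tp,fp,tn,fn nonnegative counts.
#' @return list with elements `f1` and `mcc`.
#' @export
#' @examples
#' f1_mcc(13, 50, 0, 0)$f1  # ~0.342; mcc is NA
f1_mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) NA_real_ else
    (tp * tn - fp * fn) / sqrt(prod(marg))
  list(f1 = f1, mcc = mcc)
}

#' Evaluate a fitted model on a test set
#'
#' Computes the standard report for one fitted model: RMSE of the test-set
#' predictions against the noiseless regression surface, calibration slope
#' against the noisy test outcomes, and selection metrics over the candidate
#' set of all features plus confounders (confounders count as truly active;
#' the intercept is excluded).
#'
#' @param fit a `"hubnetreg"` or `"baseline_fit"`.
#' @param data a `"sim_data"` object.
#' @return an object of class `"eval_report"`: `rmse`, `csl`, `f1`, `mcc`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_fit <- function(fit, data) {
  stopifnot(inherits(data, "sim_data"))
  pred <- predict(fit, newx = data$x_test, newz = data$z_test)
  cand <- candidate_coefficients(fit)
  truth <- c(colnames(data$z_train),
             colnames(data$x_train)[data$true_support])
  cnt <- selection_counts(cand, truth)
  fm <- f1_mcc(cnt[["tp"]], cnt[["fp"]], cnt[["tn"]], cnt[["fn"]])
  structure(
    list(rmse = rmse(data$mu_test, pred),
         csl = calibration_slope(data$y_test, pred),
         f1 = fm$f1, mcc = fm$mcc,
         tp = unname(cnt["tp"]), fp = unname(cnt["fp"]),
         tn = unname(cnt["tn"]), fn = unname(cnt["fn"])),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("RMSE %.3f | CSL %.3f | F1 %.3f | MCC %s | TP %d FP %d TN %d FN %d\n",
              x$rmse, x$csl, x$f1,
              if (is.na(x$mcc)) "NA" else sprintf("%.3f", x$mcc),
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Candidate-variable coefficients of a fit
#'
#' The named coefficient vector over the selection candidate set — every
#' confounder and every feature, intercept dropped — used by
#' [selection_counts()].
#'
#' @param fit a `"hubnetreg"` or `"baseline_fit"`.
#' @return named numeric vector.
#' @export
candidate_coefficients <- function(fit) {
  if (inherits(fit, "hubnetreg")) {
    est <- c(fit$fit$alpha, fit$fit$beta)
    keep <- fit$fit$column_map$block != "intercept"
    setNames(as.numeric(est[keep]), fit$fit$column_map$name[keep])
  } else if (inherits(fit, "baseline_fit")) {
    fit$coefficients[-1L]
  } else stop("unsupported fit object")
}
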