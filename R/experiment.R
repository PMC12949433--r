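#' Run a simulation benchmark
#'
#' Repeats, for `reps` independent replicates of a scenario, the generation
#' of a training and evaluation set, fits each requested method on the
#' training data and evaluates it on the test set. Replicate `r` uses
#' seed `base_seed + r`, so any subset of replicates is reproducible in
#' isolation. The network-guided method is run once per value of
#' `delta_list`; per-replicate fit failures are recorded and excluded from
#' that method's summary.
#'
#' @param setting,signal,n,p,test_n,sigma scenario specification
#'   (see [sim_scenario()]).
#' @param methods subset of `"ng"`, `"alasso"`, `"lasso"`, `"enet"`, `"ridge"`.
#' @param delta_list hub proportions for the network-guided method.
#' @param reps number of replicates.
#' @param base_seed integer; replicate `r` uses `base_seed + r`.
#' @param nfolds cross-validation folds for every method.
#' @param ... passed to [hubnetreg()] (network-guided fits only).
#' @return a data frame, one row per replicate-method(-delta), with columns
#'   `setting`, `signal`, `n`, `p`, `method`, `delta`, `rep`, `rmse`, `csl`,
#'   `f1`, `mcc`, `tp`, `fp`, `tn`, `fn`, `runtime`; failures (if any) are
#'   attached as attribute `"failures"`.
#' @export
run_experiment <- function(setting = NULL, signal = "strong", n = NULL, p = NULL,
                           methods = c("ng", "alasso", "lasso", "enet", "ridge"),
                           delta_list = 0.06, reps = 10L, base_seed = 0L,
                           test_n = 1000L, sigma = 1, nfolds = 5L, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  failures <- list()
  for (r in seq_len(reps)) {
    seed_r <- base_seed + r
    scn <- sim_scenario(setting = setting, signal = signal, n = n, p = p,
                        seed = seed_r, test_n = test_n, sigma = sigma)
    d <- sim_data(scn)
    tasks <- list()
    for (m in methods) {
      if (m == "ng") {
        for (dl in delta_list) tasks[[length(tasks) + 1L]] <- list(m = "ng", delta = dl)
      } else tasks[[length(tasks) + 1L]] <- list(m = m, delta = NA_real_)
    }
    for (tk in tasks) {
      t0 <- proc.time()[3L]
      res <- tryCatch({
        fit <- if (tk$m == "ng") {
          hubnetreg(d$x_train, d$z_train, d$y_train, delta = tk$delta,
                    nfolds = nfolds, seed = seed_r, ...)
        } else {
          fit_baseline(tk$m, d$x_train, d$z_train, d$y_train,
                       nfolds = nfolds, seed = seed_r)
        }
        evaluate_fit(fit, d)
      }, error = function(e) e)
      rt <- proc.time()[3L] - t0
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(rep = r, method = tk$m, delta = tk$delta,
                     message = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        setting = if (is.null(setting)) NA_character_ else as.character(setting),
        signal = signal, n = scn$n, p = scn$p,
        method = tk$m, delta = tk$delta, rep = r,
        rmse = res$rmse, csl = res$csl, f1 = res$f1, mcc = res$mcc,
        tp = res$tp, fp = res$fp, tn = res$tn, fn = res$fn,
        runtime = rt, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures) else NULL
  out
}

#' Summarize a benchmark table
#'
#' Mean and standard deviation of each metric per method (and per `delta`
#' for the network-guided rows). The Matthews correlation is averaged over
#' the replicates where it is defined; its count is reported separately.
#'
#' @param results output of [run_experiment()].
#' @return a data frame with one row per method/delta and columns
#'   `rmse`, `rmse_sd`, `csl`, `csl_sd`, `f1`, `f1_sd`, `mcc`, `mcc_sd`,
#'   `mcc_n`, `runtime`, `n_reps`.
#' @export
summarize_experiment <- function(results) {
  key <- paste(results$method, ifelse(is.na(results$delta), "", results$delta))
  parts <- split(results, key)
  out <- lapply(parts, function(g) {
    mcc_ok <- !is.na(g$mcc)
    data.frame(
      method = g$method[1L], delta = g$delta[1L],
      rmse = mean(g$rmse), rmse_sd = sd(g$rmse),
      csl = mean(g$csl, na.rm = TRUE), csl_sd = sd(g$csl, na.rm = TRUE),
      f1 = mean(g$f1), f1_sd = sd(g$f1),
      mcc = if (any(mcc_ok)) mean(g$mcc[mcc_ok]) else NA_real_,
      mcc_sd = if (sum(mcc_ok) > 1L) sd(g$mcc[mcc_ok]) else NA_real_,
      mcc_n = sum(mcc_ok),
      runtime = mean(g$runtime), n_reps = nrow(g),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$method, out$delta), ]
}
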