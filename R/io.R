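#' Read a delimited numeric table
#'
#' Reads a CSV or TSV file (dialect inferred from the extension, falling back
#' to sniffing the header line) into the typed object each pipeline role
#' expects: a named numeric matrix for `"expression"` and `"confounders"`,
#' a numeric vector for `"outcome"`. A non-numeric first column is treated
#' as sample identifiers and preserved as row names. Missing or non-numeric
#' payload entries are reported with their position.
#'
#' @param path file path.
#' @param role `"expression"`, `"confounders"` or `"outcome"`.
#' @return matrix (features in columns) or numeric vector, with names.
#' @export
read_tabular <- function(path, role = c("expression", "confounders", "outcome")) {
  role <- match.arg(role)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else {
      first <- readLines(path, n = 1L)
      if (grepl("\t", first)) "\t" else ","
    }
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 0L) stop("empty table: ", path)
  ids <- NULL
  if (!is.numeric(df[[1L]]) && ncol(df) > 1L) {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!apply(df, 2L, is.numeric))
    stop("non-numeric column(s) in ", path, ": ",
         paste(colnames(df)[bad], collapse = ", "))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing values in %s, e.g. row %d column '%s'",
                 path, idx[1, 1], colnames(m)[idx[1, 2]]))
  }
  if (!is.null(ids)) rownames(m) <- ids
  if (role == "outcome") {
    if (ncol(m) != 1L) stop("outcome table must have exactly one numeric column")
    return(setNames(as.numeric(m[, 1L]), rownames(m)))
  }
  m
}

.align_samples <- function(x, z, y) {
  have_ids <- !is.null(rownames(x))
  if (have_ids && !is.null(z) && !is.null(rownames(z))) {
    if (!setequal(rownames(x), rownames(z)))
      stop("sample ids differ between expression and confounders: ",
           paste(symdiff <- union(setdiff(rownames(x), rownames(z)),
                                  setdiff(rownames(z), rownames(x))),
                 collapse = ", "))
    z <- z[rownames(x), , drop = FALSE]
  }
  if (have_ids && !is.null(names(y)) && any(nzchar(names(y)))) {
    if (!setequal(rownames(x), names(y)))
      stop("sample ids differ between expression and outcome")
    y <- y[rownames(x)]
  }
  if (!have_ids) message("no sample id column found; aligning tables by row order")
  list(x = x, z = z, y = y)
}

#' Write the edge list of a partial-correlation network
#'
#' @param net a `"ggm_network"`.
#' @param path output TSV path with columns
#'   `protein_a`, `protein_b`, `partial_correlation`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ggm_network"))
  ut <- which(upper.tri(net$rho) & net$rho != 0, arr.ind = TRUE)
  df <- data.frame(protein_a = net$feature_names[ut[, 1L]],
                   protein_b = net$feature_names[ut[, 2L]],
                   partial_correlation = net$rho[ut])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on files and write its artifact bundle
#'
#' Reads the expression, confounder and outcome tables, fits the
#' network-guided model, and writes: the network edge list (`edges.tsv`),
#' the full partial-correlation matrix (`rho.csv`), the hub table
#' (`hubs.tsv`), the coefficient table (`coefficients.csv`), optional test
#' predictions (`predictions.csv`), and a JSON metadata record
#' (`metadata.json`) holding every tuning choice and seed, so a run is fully
#' reproducible. Stage errors are re-signalled with the failing stage named.
#'
#' @param expression path to the feature table (samples x named features).
#' @param confounders optional path to the confounder table.
#' @param outcome path to the outcome table (one numeric column), or the
#'   name of a column of `confounders` to use as outcome.
#' @param out_dir output directory (created if absent).
#' @param delta,tau,gamma,centrality,nfolds,seed model settings
#'   (see [hubnetreg()]).
#' @param test_expression,test_confounders optional paths to held-out data
#'   to score.
#' @param ... passed to [hubnetreg()].
#' @return invisibly, a list with the fitted model and the artifact paths.
#' @export
run_pipeline <- function(expression, confounders = NULL, outcome, out_dir,
                         delta = 0.02, tau = NULL, gamma = 0,
                         centrality = "degree", nfolds = 5L, seed = 1L,
                         test_expression = NULL, test_confounders = NULL, ...) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  x <- stage("read expression", read_tabular(expression, "expression"))
  z <- if (!is.null(confounders))
    stage("read confounders", read_tabular(confounders, "confounders")) else NULL
  y <- if (!is.null(z) && length(outcome) == 1L && outcome %in% colnames(z)) {
    yy <- setNames(z[, outcome], rownames(z))
    z <- z[, setdiff(colnames(z), outcome), drop = FALSE]
    if (ncol(z) == 0L) z <- NULL
    yy
  } else stage("read outcome", read_tabular(outcome, "outcome"))
  al <- stage("sample alignment", .align_samples(x, z, y))

  fit <- stage("model fit",
               hubnetreg(al$x, al$z, al$y, delta = delta, tau = tau,
                         gamma = gamma, centrality = centrality,
                         nfolds = nfolds, seed = seed, ...))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage("write artifacts", {
    paths$edges <- write_edge_list(fit$network, file.path(out_dir, "edges.tsv"))
    rho_df <- as.data.frame(fit$network$rho)
    write.csv(cbind(feature = fit$network$feature_names, rho_df),
              file.path(out_dir, "rho.csv"), row.names = FALSE)
    paths$rho <- file.path(out_dir, "rho.csv")
    ht <- hub_table(fit$centrality, fit$hubs)
    utils::write.table(ht, file.path(out_dir, "hubs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$hubs <- file.path(out_dir, "hubs.tsv")
    st <- summary(fit)$coefficients
    write.csv(st, file.path(out_dir, "coefficients.csv"), row.names = FALSE)
    paths$coefficients <- file.path(out_dir, "coefficients.csv")
    if (!is.null(test_expression)) {
      xt <- read_tabular(test_expression, "expression")
      zt <- if (!is.null(test_confounders))
        read_tabular(test_confounders, "confounders") else NULL
      pr <- predict(fit, xt, zt)
      write.csv(data.frame(sample = if (is.null(rownames(xt)))
        seq_along(pr) else rownames(xt), prediction = pr),
        file.path(out_dir, "predictions.csv"), row.names = FALSE)
      paths$predictions <- file.path(out_dir, "predictions.csv")
    }
    meta <- list(
      delta = delta, tau = fit$hubs$tau, gamma = gamma,
      centrality = centrality, nfolds = nfolds, seed = seed,
      h = fit$hubs$h, hubs = fit$hubs$feature_names[fit$hubs$hub_indices],
      network_lambda = fit$network$lambda,
      network_edges = fit$network$fit$n_edges,
      nu = fit$nu, lambda = fit$lambda,
      n = fit$n, p = fit$p,
      package_version = as.character(utils::packageVersion("hubnetreg")))
    jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$metadata <- file.path(out_dir, "metadata.json")
  })
  invisible(list(fit = fit, paths = paths))
}
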