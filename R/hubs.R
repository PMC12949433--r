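#' Node centrality on a partial-correlation network
#'
#' Degree centrality (the default, used for hub identification) is the
#' marginal sum of absolute partial correlations incident to a node,
#' `phi_k = sum_j |rho_jk|`. Betweenness is computed on the weighted graph
#' whose edge distances are `1 / |rho_jk|` over nonzero edges, so stronger
#' conditional associations mean shorter paths; eigenvector centrality is the
#' principal eigenvector of `|rho|`, normalized to maximum 1.
#'
#' @param net a `"ggm_network"` or a partial-correlation matrix.
#' @param measure `"degree"`, `"betweenness"` or `"eigenvector"`.
#' @return an object of class `"centrality_scores"`: numeric `scores` (named),
#'   the `measure`, and a `degenerate` flag set when the network has no edges
#'   (uniform scores carry no ranking information).
#' @export
#' @examples
#' rho <- matrix(0, 5, 5); rho[1, 2:5] <- rho[2:5, 1] <- 0.2
#' centrality_scores(rho)$scores
centrality_scores <- function(net, measure = c("degree", "betweenness", "eigenvector")) {
  measure <- match.arg(measure)
  rho <- if (inherits(net, "ggm_network")) net$rho else as.matrix(net)
  p <- nrow(rho)
  nms <- colnames(rho)
  if (is.null(nms)) nms <- paste0("V", seq_len(p))
  a <- abs(rho)
  diag(a) <- 0
  degenerate <- all(a == 0)
  if (measure == "degree") {
    sc <- colSums(a)
  } else if (measure == "eigenvector") {
    if (degenerate) {
      sc <- rep(1, p)
    } else {
      e <- eigen(a, symmetric = TRUE)
      v <- abs(e$vectors[, 1L])
      sc <- v / max(v)
    }
  } else {
    if (degenerate) {
      sc <- rep(0, p)
    } else {
      g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                               weighted = TRUE, diag = FALSE)
      sc <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
    }
  }
  structure(list(scores = setNames(as.numeric(sc), nms), measure = measure,
                 degenerate = degenerate),
            class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat(sprintf("%s centrality for %d nodes%s\n", x$measure, length(x$scores),
              if (x$degenerate) " (degenerate: empty network)" else ""))
  print(head(sort(x$scores, decreasing = TRUE), 10L))
  invisible(x)
}

#' Number of hubs under the capped-proportion rule
#'
#' `h = min(floor(p * delta), tau)` with the default cap
#' `tau = floor((p + 20) / 16)`, which keeps the unpenalized block of the
#' downstream regression moderate. `h` may be 0, in which case the pipeline
#' degenerates to a plain adaptive lasso.
#'
#' @param p number of features.
#' @param delta hub proportion in (0, 1).
#' @param tau optional cap overriding the default.
#' @return integer hub count.
#' @export
#' @examples
#' hub_count(337, 0.01)  # 3
#' hub_count(337, 0.03)  # 10
hub_count <- function(p, delta, tau = NULL) {
  if (!is.numeric(p) || p < 1) stop("`p` must be a positive integer")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1)
    stop("`delta` must lie strictly between 0 and 1")
  if (is.null(tau)) tau <- floor((p + 20) / 16)
  as.integer(min(floor(p * delta), tau))
}

#' Partition features into hubs and non-hubs
#'
#' The `h` highest-centrality features become hubs; centrality ties are broken
#' deterministically by ascending feature index.
#'
#' @param scores a `"centrality_scores"` object or a numeric vector.
#' @param h number of hubs, `0 <= h <= p`.
#' @param delta,tau optional metadata recording how `h` was derived.
#' @return an object of class `"hub_partition"`: integer vectors
#'   `hub_indices` (ordered by decreasing centrality) and `nonhub_indices`
#'   (ascending), `h`, the scores and names.
#' @export
select_hubs <- function(scores, h, delta = NA_real_, tau = NA_integer_) {
  sc <- if (inherits(scores, "centrality_scores")) scores$scores else scores
  p <- length(sc)
  if (h < 0 || h > p) stop("`h` must be between 0 and p")
  ord <- order(-sc, seq_len(p))
  hub <- if (h > 0) ord[seq_len(h)] else integer(0)
  nonhub <- sort(setdiff(seq_len(p), hub))
  stopifnot(length(hub) + length(nonhub) == p)
  structure(
    list(hub_indices = hub, nonhub_indices = nonhub, h = as.integer(h),
         delta = delta, tau = tau, scores = sc,
         feature_names = names(sc)),
    class = "hub_partition")
}

#' @export
print.hub_partition <- function(x, ...) {
  cat(sprintf("Hub partition: %d hubs, %d non-hubs\n", x$h, length(x$nonhub_indices)))
  if (x$h > 0) {
    nm <- if (is.null(x$feature_names)) as.character(x$hub_indices) else
      x$feature_names[x$hub_indices]
    cat("  hubs:", paste(nm, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hub table
#'
#' Features ranked by centrality with their hub status, ready for export.
#'
#' @param scores a `"centrality_scores"` object.
#' @param hubs a `"hub_partition"` from the same network.
#' @return a data frame with columns `rank`, `feature`, `centrality`, `is_hub`.
#' @export
hub_table <- function(scores, hubs) {
  sc <- scores$scores
  ord <- order(-sc, seq_along(sc))
  data.frame(rank = seq_along(sc),
             feature = names(sc)[ord],
             centrality = as.numeric(sc[ord]),
             is_hub = ord %in% hubs$hub_indices,
             row.names = NULL)
}
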