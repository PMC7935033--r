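weights_to_graph <- function(W, mode = "distance") {
  W <- as.matrix(W)
  if (!isSymmetric(unname(W), tol = 1e-10)) stop("W must be symmetric")
  if (any(W < 0)) stop("W must be non-negative")
  diag(W) <- 0
  A <- if (mode == "distance") ifelse(W > 0, 1 / W, 0) else W
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs, with edge
#' lengths taken as the inverse of the connection weight (a strong
#' functional connection is a short path) and `1/Inf = 0` for disconnected
#' pairs. For weights in `[0, 1]` the result lies in `[0, 1]`; it measures
#' how easily activity can be exchanged across the network.
#'
#' @param W symmetric non-negative weight matrix; zero entries mean no edge.
#' @return scalar efficiency, or `NA` for fewer than 2 nodes.
#' @export
global_efficiency <- function(W) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (n < 2L) return(NA_real_)
  g <- weights_to_graph(W, "distance")
  d <- igraph::distances(g, weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency
#'
#' For each node, the global efficiency of the weighted subgraph induced by
#' its neighbours (the node itself removed). It quantifies fault tolerance:
#' how well the node's neighbourhood keeps communicating if the node drops
#' out. A node whose neighbours form a unit-weight clique scores 1; an
#' isolated node, or one with a single neighbour, scores 0.
#'
#' @param W symmetric non-negative weight matrix.
#' @return numeric vector, one value per node (named like `W`'s rows).
#' @export
local_efficiency <- function(W) {
  W <- as.matrix(W)
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2L) {
      out[i] <- 0
    } else {
      sub <- W[nb, nb, drop = FALSE]
      e <- global_efficiency(sub)
      out[i] <- if (is.na(e)) 0 else e
    }
  }
  names(out) <- rownames(W)
  out
}

#' Louvain community detection with best-of-repeats modularity
#'
#' Runs the Louvain algorithm `n_repeats` times under distinct sub-seeds
#' (the algorithm's greedy passes depend on vertex order) and keeps the
#' partition with the highest weighted modularity Q at resolution `gamma`.
#' Q near 0 means no better-than-chance community structure; higher Q means
#' denser within-community connectivity relative to a degree-matched random
#' network.
#'
#' @param W symmetric non-negative weight matrix.
#' @param gamma resolution parameter (default 1, the standard modularity).
#' @param n_repeats number of independent Louvain restarts (default 100).
#' @param seed master seed for the restarts.
#' @return list with `partition` (integer community label per node,
#'   contiguous from 1), `Q` (modularity of the returned partition; `NA`
#'   for an edgeless graph), `n_communities`.
#' @export
louvain_partition <- function(W, gamma = 1, n_repeats = 100, seed = 1L) {
  W <- as.matrix(W)
  n <- nrow(W)
  g <- weights_to_graph(W, "affinity")
  if (igraph::ecount(g) == 0L) {
    return(list(partition = rep(1L, n), Q = NA_real_, n_communities = 1L))
  }
  best_q <- -Inf
  best_membership <- NULL
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max, n_repeats)
  })
  for (r in seq_len(n_repeats)) {
    memb <- with_seed(sub_seeds[r], {
      cl <- igraph::cluster_louvain(g, resolution = gamma)
      igraph::membership(cl)
    })
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                            resolution = gamma)
    if (q > best_q) {
      best_q <- q
      best_membership <- memb
    }
  }
  part <- as.integer(factor(best_membership, levels = unique(best_membership)))
  names(part) <- rownames(W)
  list(partition = part, Q = best_q,
       n_communities = length(unique(part)))
}

#' All graph measures of a functional network
#'
#' Convenience wrapper computing weighted global efficiency, per-node and
#' mean local efficiency, and the Louvain community structure (number of
#' communities and modularity Q) of one network.
#'
#' @param network a `functional_network` from [build_functional_network()],
#'   or a bare symmetric weight matrix.
#' @param gamma Louvain resolution (default 1).
#' @param n_repeats Louvain restarts (default 100).
#' @param seed seed for the Louvain restarts.
#' @param local if `FALSE`, skip the (quadratic-cost) local efficiency.
#' @return list of class `network_metrics`: `global_efficiency`,
#'   `local_efficiency` (vector), `mean_local_efficiency`, `n_communities`,
#'   `Q`, `partition`, `gamma`, `n_repeats`.
#' @export
network_metrics <- function(network, gamma = 1, n_repeats = 100, seed = 1L,
                            local = TRUE) {
  W <- if (inherits(network, "functional_network")) network$W else
    as.matrix(network)
  eg <- global_efficiency(W)
  el <- if (local) local_efficiency(W) else NULL
  lv <- louvain_partition(W, gamma = gamma, n_repeats = n_repeats, seed = seed)
  structure(list(
    global_efficiency = eg,
    local_efficiency = el,
    mean_local_efficiency = if (local) mean(el) else NA_real_,
    n_communities = lv$n_communities,
    Q = lv$Q,
    partition = lv$partition,
    gamma = gamma, n_repeats = n_repeats
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "<network_metrics> E_glob %.4f | mean E_loc %s | %d communities | Q %.4f\n",
    x$global_efficiency,
    if (is.na(x$mean_local_efficiency)) "-" else
      sprintf("%.4f", x$mean_local_efficiency),
    x$n_communities, x$Q))
  invisible(x)
}

#' Write a partition file (node label, community id)
#'
#' @param partition named integer vector from [louvain_partition()].
#' @param path file path.
#' @export
write_partition <- function(partition, path) {
  nodes <- if (is.null(names(partition))) as.character(seq_along(partition))
    else names(partition)
  utils::write.table(
    data.frame(node = nodes, community = as.integer(partition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
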