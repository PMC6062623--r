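# Node and global graph metrics on binary graphs: efficiencies, betweenness
# centrality, flow coefficient, participation coefficient, and the bundled
# per-graph computation used by the density sweep.
#
# Degenerate conventions (fixed throughout): degree-0 and degree-1 nodes get
# flow, participation and local efficiency 0; disconnected pairs contribute
# 0 to efficiency and betweenness.

#' Global efficiency
#'
#' Mean over ordered distinct node pairs of the inverse geodesic distance
#' (1/Inf := 0 for disconnected pairs). 1 for a complete graph.
#'
#' @param g A `bin_graph`.
#' @param ps Optional precomputed [shortest_paths()] result.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g, ps = shortest_paths(g)) {
  n <- nrow(g$adj)
  if (n < 2L) return(0)
  inv <- 1 / ps$dist
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Local efficiency of a node
#'
#' Global efficiency of the subgraph induced by the immediate neighbours of
#' `i` (node `i` excluded), with geodesics confined to that subgraph.
#' Nodes of degree < 2 have local efficiency 0.
#'
#' @param g A `bin_graph`.
#' @param i Node index or label.
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(g, i) {
  i <- resolve_node(g, i)
  nb <- which(g$adj[i, ] > 0)
  if (length(nb) < 2L) return(0)
  sub <- bin_graph(g$adj[nb, nb, drop = FALSE])
  global_efficiency(sub)
}

#' Betweenness centrality of a node
#'
#' Normalised fraction of all-pairs geodesics passing through `i`:
#' `b_i = (1 / ((n-1)(n-2))) * sum_{h != j, h,j != i} sigma_hj(i) / sigma_hj`,
#' over ordered pairs; disconnected pairs contribute 0. 1 for the centre of
#' a star, 0 for any node of a complete graph.
#'
#' @param g A `bin_graph` with at least 3 nodes.
#' @param i Node index or label.
#' @param ps Optional precomputed [shortest_paths()] result.
#' @return Scalar in `[0, 1]`.
#' @export
betweenness <- function(g, i, ps = shortest_paths(g)) {
  n <- nrow(g$adj)
  if (n < 3L) stop("betweenness needs at least 3 nodes", call. = FALSE)
  i <- resolve_node(g, i)
  D <- ps$dist; S <- ps$sigma
  through <- outer(D[, i], D[i, ], "+") == D & is.finite(D)
  through[i, ] <- FALSE; through[, i] <- FALSE
  diag(through) <- FALSE
  num <- outer(S[, i], S[i, ]) # sigma_si * sigma_it
  frac <- ifelse(through & S > 0, num / S, 0)
  sum(frac) / ((n - 1) * (n - 2))
}

#' Flow coefficient of a node
#'
#' Fraction of ordered pairs of distinct neighbours of `i` that are not
#' directly connected to each other, i.e. the fraction of possible
#' length-two paths through `i` that actually carry flow (p0 / pp with
#' pp = d(d-1)). Degree < 2 gives 0.
#'
#' @param g A `bin_graph`.
#' @param i Node index or label.
#' @return Scalar in `[0, 1]`.
#' @export
flow_coefficient <- function(g, i) {
  i <- resolve_node(g, i)
  nb <- which(g$adj[i, ] > 0)
  d <- length(nb)
  if (d < 2L) return(0)
  sub <- g$adj[nb, nb, drop = FALSE]
  p0 <- d * (d - 1) - sum(sub)           # ordered pairs lacking a direct edge
  p0 / (d * (d - 1))
}

#' Global flow
#'
#' Unweighted mean of the flow coefficient over all nodes.
#'
#' @param g A `bin_graph`.
#' @return Scalar in `[0, 1]`.
#' @export
global_flow <- function(g) {
  mean(vapply(seq_len(nrow(g$adj)), function(i) flow_coefficient(g, i), 0))
}

#' Participation coefficient of a node
#'
#' `y_i = 1 - sum_m (k_i(m) / k_i)^2` where `k_i(m)` is the number of edges
#' from `i` into module `m` of the supplied partition. 0 when every edge
#' stays in one module (and for isolated nodes).
#'
#' @param g A `bin_graph`.
#' @param partition Integer membership vector covering all nodes.
#' @param i Node index or label.
#' @return Scalar in `[0, 1)`.
#' @export
participation <- function(g, partition, i) {
  i <- resolve_node(g, i)
  stopifnot(length(partition) == nrow(g$adj))
  nb <- which(g$adj[i, ] > 0)
  k_i <- length(nb)
  if (k_i == 0L) return(0)
  km <- table(partition[nb])
  1 - sum((as.numeric(km) / k_i)^2)
}

#' Global and nodal metric bundle for one graph
#'
#' Computes the geodesic substrate once and evaluates the global metrics
#' (spectral modularity Q, global efficiency, global flow) plus, for each
#' target node, betweenness, flow coefficient, participation (against the
#' spectral partition of this same graph) and neighbourhood local
#' efficiency.
#'
#' @param g A `bin_graph`.
#' @param partition Optional partition; default the [modularity_spectral()]
#'   partition of `g`.
#' @param target_nodes Character labels (or indices) of nodes to profile;
#'   may be empty.
#' @param fine_tune Passed to [modularity_spectral()].
#' @return List with `global` (named numeric: `q`, `global_efficiency`,
#'   `global_flow`) and `nodes` (data frame: node, betweenness, flow,
#'   participation, local_efficiency).
#' @export
metric_bundle <- function(g, partition = NULL, target_nodes = character(),
                          fine_tune = TRUE) {
  stopifnot(inherits(g, "bin_graph"))
  if (is.null(partition))
    partition <- modularity_spectral(g, fine_tune = fine_tune)$membership
  ps <- shortest_paths(g)
  glob <- c(q = compute_q(g, partition),
            global_efficiency = global_efficiency(g, ps),
            global_flow = global_flow(g))
  nodes <- NULL
  if (length(target_nodes)) {
    idx <- vapply(target_nodes, function(t) resolve_node(g, t), 0L)
    nodes <- data.frame(
      node = g$node_labels[idx],
      betweenness = vapply(idx, function(i) betweenness(g, i, ps), 0),
      flow = vapply(idx, function(i) flow_coefficient(g, i), 0),
      participation = vapply(idx, function(i) participation(g, partition, i), 0),
      local_efficiency = vapply(idx, function(i) local_efficiency(g, i), 0),
      stringsAsFactors = FALSE)
    rownames(nodes) <- NULL
  }
  list(global = glob, nodes = nodes)
}

resolve_node <- function(g, i) {
  if (is.character(i)) {
    j <- match(i, g$node_labels)
    if (is.na(j)) stop("unknown node label: ", i, call. = FALSE)
    return(j)
  }
  i <- as.integer(i)
  if (i < 1L || i > nrow(g$adj)) stop("node index out of range", call. = FALSE)
  i
}
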