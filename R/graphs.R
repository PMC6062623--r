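# Density-thresholded binary graphs and geodesic substrate (breadth-first
# distances and shortest-path counts) for the metric layer.

#' Proportional (density) thresholding of a connectivity matrix
#'
#' Retains the `round(k * N * (N - 1) / 2)` strongest off-diagonal values
#' of a symmetric Fisher-z matrix as edges and binarises. By default values
#' are ranked signed descending (the strongest positive connections); an
#' absolute-value mode is available. Ties are broken deterministically by
#' lexicographic (row, column) order of the upper triangle.
#'
#' @param conn A `conn_matrix` (or plain symmetric matrix).
#' @param k Density in `(0, 1]`: fraction of possible edges retained.
#' @param mode `"signed"` (default) ranks raw values; `"abs"` ranks
#'   magnitudes.
#' @return Object of class `bin_graph`: list(`adj` 0/1 adjacency matrix,
#'   `density`, `node_labels`).
#' @export
threshold_proportional <- function(conn, k, mode = c("signed", "abs")) {
  mode <- match.arg(mode)
  z <- if (inherits(conn, "conn_matrix")) conn$z else as.matrix(conn)
  if (max(abs(z - t(z))) > 1e-8) stop("matrix must be symmetric", call. = FALSE)
  assert_scalar_num(k, "k", 1e-12, 1)
  n <- nrow(z)
  m_possible <- n * (n - 1) / 2
  n_edges <- round(k * m_possible)
  if (n_edges < 1L) stop("density k yields zero edges", call. = FALSE)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[ut]
  key <- if (mode == "abs") -abs(vals) else -vals
  ord <- order(key, ut[, 1], ut[, 2])
  keep <- ord[seq_len(n_edges)]
  adj <- matrix(0L, n, n)
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  labels <- rownames(z)
  if (is.null(labels)) labels <- sprintf("roi_%03d", seq_len(n))
  dimnames(adj) <- list(labels, labels)
  structure(list(adj = adj, density = k, node_labels = labels),
            class = "bin_graph")
}

#' Construct a binary graph from an adjacency matrix
#'
#' @param adj Symmetric 0/1 matrix with zero diagonal.
#' @param density Stated density; default the realised edge fraction.
#' @param node_labels Node labels.
#' @return A `bin_graph`.
#' @export
bin_graph <- function(adj, density = NULL, node_labels = rownames(adj)) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  stopifnot(n == ncol(adj))
  if (!all(adj %in% c(0, 1))) stop("adjacency must be 0/1", call. = FALSE)
  if (any(adj != t(adj))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(adj) != 0)) stop("diagonal must be zero", call. = FALSE)
  storage.mode(adj) <- "integer"
  if (is.null(density)) density <- sum(adj) / (n * (n - 1))
  if (is.null(node_labels)) node_labels <- sprintf("roi_%03d", seq_len(n))
  dimnames(adj) <- list(node_labels, node_labels)
  structure(list(adj = adj, density = density, node_labels = node_labels),
            class = "bin_graph")
}

#' Number of edges in a binary graph
#' @param g A `bin_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(g) sum(g$adj) / 2

#' Breadth-first distances and shortest-path counts
#'
#' For every ordered node pair computes the geodesic distance in hops
#' (`Inf` for disconnected pairs) and the exact number of distinct shortest
#' paths, via level-synchronous breadth-first search with the standard
#' path-counting recursion. Counts of paths through an intermediate node
#' are recovered where needed from `sigma[s, i] * sigma[i, t]` when
#' `dist[s, i] + dist[i, t] == dist[s, t]`.
#'
#' @param g A `bin_graph`.
#' @return Object of class `path_stats`: list(`dist`, `sigma`) of node x
#'   node matrices.
#' @export
shortest_paths <- function(g) {
  stopifnot(inherits(g, "bin_graph"))
  A <- g$adj
  n <- nrow(A)
  storage.mode(A) <- "double"
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sig <- numeric(n); sig[s] <- 1
    frontier <- s
    level <- 0
    while (length(frontier)) {
      level <- level + 1
      reach <- as.numeric(crossprod(A[frontier, , drop = FALSE],
                                    sig[frontier]))
      nxt <- which(reach > 0 & is.infinite(d))
      if (!length(nxt)) break
      d[nxt] <- level
      sig[nxt] <- reach[nxt]
      frontier <- nxt
    }
    D[s, ] <- d
    S[s, ] <- sig
  }
  diag(D) <- 0
  dimnames(D) <- dimnames(S) <- dimnames(g$adj)
  structure(list(dist = D, sigma = S), class = "path_stats")
}

#' @export
print.bin_graph <- function(x, ...) {
  cat(sprintf("<bin_graph> %d nodes, %d edges (density %.3g)\n",
              nrow(x$adj), n_edges(x), x$density))
  invisible(x)
}
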