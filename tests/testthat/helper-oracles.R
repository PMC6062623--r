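# Independent brute-force oracles for the graph metrics. These deliberately
# avoid the package's BFS/path-counting code path: distances come from
# Floyd-Warshall, geodesic counts from explicit path enumeration on the
# distance-certified DAG, and everything else from direct loops over the
# defining sums.

rand_graph <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a + t(a)
}

oracle_dist <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) {
    nd <- d[i, k] + d[k, ]
    d[i, ] <- pmin(d[i, ], nd)
  }
  d
}

# enumerate every geodesic from s to t as a node sequence (uses FW distances
# only to certify steps)
oracle_geodesics <- function(a, d, s, t) {
  if (!is.finite(d[s, t]) || s == t) return(list())
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) { paths[[length(paths) + 1L]] <<- path; return() }
    rem <- d[u, t]
    for (v in which(a[u, ] > 0))
      if (d[v, t] == rem - 1) walk(c(path, v))
  }
  walk(s)
  paths
}

oracle_betweenness <- function(a, i) {
  n <- nrow(a)
  d <- oracle_dist(a)
  total <- 0
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == i || t == i || !is.finite(d[s, t])) next
    paths <- oracle_geodesics(a, d, s, t)
    if (!length(paths)) next
    through <- sum(vapply(paths, function(p) i %in% p[-c(1, length(p))], TRUE))
    total <- total + through / length(paths)
  }
  total / ((n - 1) * (n - 2))
}

oracle_sigma <- function(a, s, t) {
  d <- oracle_dist(a)
  length(oracle_geodesics(a, d, s, t))
}

oracle_global_eff <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- oracle_dist(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_eff <- function(a, i) {
  nb <- which(a[i, ] > 0)
  if (length(nb) < 2) return(0)
  oracle_global_eff(a[nb, nb, drop = FALSE])
}

oracle_flow <- function(a, i) {
  nb <- which(a[i, ] > 0)
  dg <- length(nb)
  if (dg < 2) return(0)
  p0 <- 0
  for (h in nb) for (j in nb)
    if (h != j && a[h, j] == 0) p0 <- p0 + 1
  p0 / (dg * (dg - 1))
}

oracle_participation <- function(a, part, i) {
  nb <- which(a[i, ] > 0)
  if (!length(nb)) return(0)
  s <- 0
  for (m in unique(part)) s <- s + (sum(part[nb] == m) / length(nb))^2
  1 - s
}

oracle_q <- function(a, part) {
  deg <- rowSums(a)
  two_m <- sum(deg)
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (part[i] == part[j])
      q <- q + a[i, j] - deg[i] * deg[j] / two_m
  q / two_m
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, max_id) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (id in seq_len(max_id + 1L)) rec(c(prefix, id), max(max_id, id))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_q <- function(a) {
  best <- -Inf
  for (p in set_partitions(nrow(a))) best <- max(best, oracle_q(a, p))
  best
}

# stochastic block graph with planted partition
sbm_graph <- function(n, n_modules, p_in, p_out) {
  part <- rep(seq_len(n_modules), each = ceiling(n / n_modules),
              length.out = n)
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (part[i] == part[j]) p_in else p_out
    if (stats::runif(1) < p) { a[i, j] <- 1L; a[j, i] <- 1L }
  }
  list(adj = a, partition = part)
}
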