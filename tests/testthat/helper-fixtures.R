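# Small in-code fixtures shared across test files.

# fast reduced-scale cohort for pipeline tests
tiny_cohort <- function(n_subjects = 4, n_nodes = 24, n_modules = 3,
                        n_volumes = 200, seed = 101, states = NULL, ...) {
  design <- default_design(n_volumes = n_volumes, tr = 2)
  if (is.null(states)) states <- default_states()
  simulate_cohort(n_subjects, design, states, seed = seed,
                  n_nodes = n_nodes, n_modules = n_modules, ...)
}

# canonical small graphs
graph_star <- function(n = 6) {
  a <- matrix(0L, n, n)
  a[1, 2:n] <- 1L; a[2:n, 1] <- 1L
  bin_graph(a)
}

graph_complete <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L
  bin_graph(a)
}

graph_path3 <- function() {
  a <- matrix(0L, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1L
  bin_graph(a)
}

graph_two_triangles <- function() {
  a <- matrix(0L, 6, 6)
  for (tri in list(1:3, 4:6))
    for (i in tri) for (j in tri) if (i != j) a[i, j] <- 1L
  bin_graph(a)
}

graph_cycle <- function(n = 4) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    a[i, j] <- 1L; a[j, i] <- 1L
  }
  bin_graph(a)
}
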