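# Independent brute-force oracles used to validate the graph metrics, plus
# small fixture builders. Everything here is deliberately naive: exhaustive
# enumeration, no adjacency-power shortcuts.

# Enumerate all walks of length `l` from i to j by recursive extension.
oracle_count_walks <- function(A, i, j, l) {
  n <- nrow(A)
  extend <- function(v, depth) {
    if (depth == l) return(as.integer(v == j) * 1)
    sum(vapply(which(A[v, ] == 1), function(w) extend(w, depth + 1L), numeric(1)))
  }
  if (l == 0) return(as.numeric(i == j))
  sum(vapply(which(A[i, ] == 1), function(w) extend(w, 1L), numeric(1)))
}

# Enumerate all self-avoiding paths of length `l` from i to j.
oracle_count_simple_paths <- function(A, i, j, l) {
  count <- 0L
  recurse <- function(v, visited, depth) {
    if (depth == l) {
      if (v == j) count <<- count + 1L
      return(invisible(NULL))
    }
    for (w in which(A[v, ] == 1)) {
      if (!visited[w]) {
        visited2 <- visited
        visited2[w] <- TRUE
        recurse(w, visited2, depth + 1L)
      }
    }
  }
  visited <- logical(nrow(A))
  visited[i] <- TRUE
  recurse(i, visited, 0L)
  count
}

# All-pairs shortest path lengths by Floyd-Warshall (independent of igraph).
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

random_graph <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

path_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

complete_graph <- function(n) 1 - diag(n)

star_graph <- function(n_leaves) {
  A <- matrix(0, n_leaves + 1, n_leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1
  A
}

# Small synthetic cohort shared across analysis-level tests.
tiny_cohort_config <- function(seed = 11, ...) {
  cohort_config(n_nodes = 40, group_sizes = c(CN = 8, eMCI = 8, lMCI = 8),
                n_volumes = 80, n_communities = 5, seed = seed, ...)
}
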