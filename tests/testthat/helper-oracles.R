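# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph's BFS) so they can certify them.

# Exhaustive all-pairs shortest paths by repeated relaxation (Floyd-Warshall)
# on an adjacency matrix. O(n^3); for small graphs only.
fw_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      through_k <- D[i, k] + D[k, ]
      D[i, ] <- pmin(D[i, ], through_k)
    }
  }
  dimnames(D) <- dimnames(adj)
  D
}

# Brute-force closest-distance proximity from a full distance matrix, by a
# plain double loop over the formula (unreachable members dropped).
brute_closest_proximity <- function(D, S, T) {
  total <- 0; denom <- 0
  for (t in T) {
    m <- Inf
    for (s in S) m <- min(m, D[s, t])
    if (is.finite(m)) { total <- total + m; denom <- denom + 1 }
  }
  for (s in S) {
    m <- Inf
    for (t in T) m <- min(m, D[s, t])
    if (is.finite(m)) { total <- total + m; denom <- denom + 1 }
  }
  if (denom == 0) return(NA_real_)
  total / denom
}

# A labeled path graph A - B - C - ...
make_path <- function(labels) {
  g <- igraph::make_ring(length(labels), circular = FALSE)
  igraph::V(g)$name <- labels
  g
}

# Random connected-ish undirected graph for property tests.
random_graph <- function(n, p = 0.1, seed = 1) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
  })
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}

file_bytes <- function(path) readBin(path, "raw", file.size(path))

# Two output directories contain the same files with the same bytes.
expect_same_tree <- function(dir1, dir2) {
  f1 <- sort(list.files(dir1, recursive = TRUE))
  f2 <- sort(list.files(dir2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(file_bytes(file.path(dir1, f)),
                     file_bytes(file.path(dir2, f)),
                     label = paste("bytes of", f))
  }
}

# Adjusted Rand index between two labelings (closed form on the pair counts).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
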