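# Brute-force graph oracles, independent of the package implementation (and
# of igraph): Floyd-Warshall distances, triple-enumeration clustering,
# path-enumeration betweenness, exhaustive-partition modularity.

make_net <- function(A) {
  if (is.null(rownames(A)))
    dimnames(A) <- list(paste0("n", seq_len(nrow(A))),
                        paste0("n", seq_len(nrow(A))))
  structure(list(adjacency = A, density = sum(A) / (nrow(A) * (nrow(A) - 1)),
                 node_labels = rownames(A)),
            class = "binary_network")
}

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bf_path_length <- function(A) {
  D <- bf_distances(A)
  off <- D[row(D) != col(D)]
  if (any(!is.finite(off))) return(NA_real_)
  mean(off)
}

bf_efficiency <- function(A) {
  D <- bf_distances(A)
  inv <- 1 / D[row(D) != col(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

bf_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (v in 1:n) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) { ci[v] <- 0; next }
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      links <- links + A[nb[a], nb[b]]
    ci[v] <- links / (k * (k - 1) / 2)
  }
  list(per_node = ci, mean = mean(ci))
}

# shortest-path counts sigma[s, t] by dynamic programming over distances
bf_path_counts <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  for (s in 1:n) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(A[, t] == 1 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  sigma
}

bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  sigma <- bf_path_counts(A, D)
  B <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    for (v in 1:n) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        B[v] <- B[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  B / ((n - 1) * (n - 2) / 2)
}

modularity_of_partition <- function(A, membership) {
  m2 <- sum(A)                 # 2 * edge count
  if (m2 == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    e_cc <- sum(A[idx, idx, drop = FALSE]) / m2
    a_c <- sum(k[idx]) / m2
    q <- q + e_cc - a_c^2
  }
  q
}

# all set partitions of 1..n (restricted-growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxval) {
    i <- length(prefix) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(maxval + 1L)) rec(c(prefix, v), max(maxval, v))
  }
  rec(integer(0), 0L)
  out
}

bf_modularity_best <- function(A) {
  parts <- all_partitions(nrow(A))
  best <- -Inf
  for (p in parts) {
    q <- modularity_of_partition(A, p)
    if (q > best) best <- q
  }
  best
}

# ---- graph generators -------------------------------------------------------

adjacency_from_index <- function(n, index) {
  # index in 0:(2^(n(n-1)/2) - 1) selects an edge subset (labeled graph)
  m <- n * (n - 1) / 2
  bits <- as.integer(intToBits(index))[1:m]
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- bits
  A + t(A)
}

all_connected_graphs <- function(n) {
  m <- n * (n - 1) / 2
  out <- list()
  for (idx in 0:(2^m - 1)) {
    A <- adjacency_from_index(n, idx)
    if (all(is.finite(bf_distances(A)))) out[[length(out) + 1L]] <- A
  }
  out
}

random_connected_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  repeat {
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p_edge)
    A <- A + t(A)
    if (all(is.finite(bf_distances(A)))) return(A)
  }
}

ring_lattice <- function(n, k) {
  A <- matrix(0L, n, n)
  for (d in 1:(k / 2)) for (i in 1:n) {
    j <- ((i + d - 1) %% n) + 1
    A[i, j] <- A[j, i] <- 1L
  }
  A
}

er_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p_edge)
  A + t(A)
}
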