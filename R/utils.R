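#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Pipeline stages each draw randomness from their own stream so that adding
#' or reordering stages never perturbs another stage's draws. Sub-seeds are a
#' deterministic integer hash of the master seed, a stage name, and an index,
#' kept inside the 32-bit signed range.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. "permutation", "rewire").
#' @param index integer index within the stage (default 0).
#' @return a positive integer seed.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  s <- (abs(as.numeric(master)) * 48271 + h * 69621 + as.numeric(index) * 16807)
  as.integer(s %% 2147483587) + 1L
}

# Mean local clustering and per-node values from a 0/1 adjacency matrix.
# Pure matrix algebra; also the fast path used inside permutation loops.
.adj_clustering <- function(A) {
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A)          # 2 * triangles through each node
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, tri / denom, 0)
  list(per_node = ci, mean = mean(ci))
}

# Shortest-path distance matrix of a 0/1 adjacency matrix via igraph.
.adj_distances <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  igraph::distances(g, algorithm = "unweighted")
}

.upper_pairs <- function(n) {
  # all unordered pairs (i < j) in lexicographic order
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

.stop_class <- function(msg, class) {
  stop(structure(class = c(class, "scovnet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
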