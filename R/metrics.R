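# Global and nodal topological properties of binary networks. Graph
# primitives (shortest paths, betweenness, rewiring, greedy community
# merging) are delegated to igraph; the analysis-level definitions,
# normalizations and conventions live here.

.net_adj <- function(net) if (inherits(net, "binary_network")) net$adjacency else net

#' Nodal degree
#'
#' @param net a `binary_network` (or 0/1 adjacency matrix).
#' @return named integer vector of edge counts per node.
#' @export
net_degree <- function(net) {
  A <- .net_adj(net)
  rowSums(A)
}

#' Clustering coefficient (Watts-Strogatz local clustering)
#'
#' Per node, the fraction of the node's neighbor pairs that are themselves
#' connected (`triangles / (k(k-1)/2)`); nodes with degree < 2 contribute 0.
#' The network-level `C` is the mean over all nodes.
#'
#' @param net a `binary_network`.
#' @return list with `per_node` and `mean`.
#' @export
net_clustering <- function(net) {
  A <- .net_adj(net)
  out <- .adj_clustering(A)
  names(out$per_node) <- rownames(A)
  out
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered node pairs of a connected
#' graph. Disconnected input is refused: the density sweep's minimum-density
#' rule is what guarantees connectivity in the analyzed range, and a silent
#' convention here would hide its violation.
#'
#' @param net a `binary_network`.
#' @return the characteristic path length `L`.
#' @export
characteristic_path_length <- function(net) {
  A <- .net_adj(net)
  D <- .adj_distances(A)
  off <- D[row(D) != col(D)]
  if (any(!is.finite(off)))
    .stop_class("characteristic path length is undefined on a disconnected graph",
                "scovnet_disconnected_error")
  mean(off)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' disconnected pairs contributing 0 (the 1/Inf convention), so no
#' connectivity restriction applies.
#'
#' @param net a `binary_network`.
#' @return `E_global` in (0, 1].
#' @export
global_efficiency <- function(net) {
  A <- .net_adj(net)
  D <- .adj_distances(A)
  inv <- 1 / D[row(D) != col(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Normalized betweenness centrality
#'
#' Brandes betweenness with fractional credit across multiple shortest paths,
#' normalized by `(N-1)(N-2)/2` so a star center scores 1.
#'
#' @param net a `binary_network`.
#' @return named numeric vector in [0, 1].
#' @export
net_betweenness <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  b / ((n - 1) * (n - 2) / 2)
}

#' Degree-preserving rewiring (connected variant)
#'
#' Randomizes a network by double-edge swaps, preserving every node's degree
#' and introducing no self-loops or multi-edges. The swap schedule is applied
#' in full and connectivity re-checked; a run that fragments a connected
#' input is retried with a fresh sub-seed (up to `max_retries`).
#'
#' @param net a `binary_network`.
#' @param n_swaps number of attempted swaps (default `10 * E`).
#' @param seed integer seed.
#' @param require_connected retry until the rewired graph is connected
#'   (only enforced when the input itself is connected).
#' @param max_retries retry budget.
#' @return a rewired `binary_network` with the same degree sequence.
#' @export
rewire_degree_preserving <- function(net, n_swaps = NULL, seed = 1L,
                                     require_connected = TRUE,
                                     max_retries = 50L) {
  g <- as_igraph(net)
  if (igraph::ecount(g) < 2L)
    return(net)
  n_swaps <- n_swaps %||% (10L * igraph::ecount(g))
  want_conn <- require_connected && igraph::is_connected(g)
  for (attempt in seq_len(max_retries)) {
    set.seed(derive_seed(seed, "rewire", attempt - 1L))
    g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
    if (!want_conn || igraph::is_connected(g2)) {
      A <- as.matrix(igraph::as_adjacency_matrix(g2))
      storage.mode(A) <- "integer"
      dimnames(A) <- dimnames(.net_adj(net))
      out <- net
      if (inherits(net, "binary_network")) out$adjacency <- A else out <- A
      return(out)
    }
  }
  .stop_class("could not obtain a connected degree-preserving rewiring",
              "scovnet_degenerate_error")
}

#' Normalized small-world indices
#'
#' `gamma = C / <C_random>`, `lambda = L / <L_random>`, `sigma = gamma /
#' lambda`, where the random reference ensemble is `n_random` connected
#' degree-preserving rewirings of the input. `sigma > 1` is the conventional
#' small-world criterion.
#'
#' @param net a connected `binary_network`.
#' @param n_random number of reference graphs (default 20).
#' @param seed integer seed.
#' @return list with `gamma`, `lambda`, `sigma`, `C`, `L`, and the reference
#'   means `C_random`, `L_random`.
#' @export
normalized_small_world <- function(net, n_random = 20L, seed = 1L) {
  C <- net_clustering(net)$mean
  L <- characteristic_path_length(net)
  Cr <- Lr <- numeric(n_random)
  for (i in seq_len(n_random)) {
    rn <- rewire_degree_preserving(net, seed = derive_seed(seed, "swref", i))
    Cr[i] <- net_clustering(rn)$mean
    Lr[i] <- characteristic_path_length(rn)
  }
  if (mean(Cr) <= 0)
    .stop_class("random reference clustering is 0; graph too sparse for gamma",
                "scovnet_degenerate_error")
  gamma <- C / mean(Cr); lambda <- L / mean(Lr)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       C = C, L = L, C_random = mean(Cr), L_random = mean(Lr))
}

#' Optimal modular structure by restarted greedy agglomeration
#'
#' Maximizes Newman modularity `Q = sum_c (e_cc - a_c^2)` over `n_iter`
#' randomized restarts of greedy agglomerative merging (vertex order is
#' permuted per restart to randomize tie-breaking) and returns the best
#' partition found. Never returns below the single-community baseline
#' (`Q = 0`).
#'
#' @param net a `binary_network` with >= 1 edge.
#' @param n_iter number of randomized restarts (default 1000).
#' @param seed integer seed.
#' @return list with `Q`, `partition` (named integer membership), and
#'   `n_modules`.
#' @export
modularity_optimal <- function(net, n_iter = 1000L, seed = 1L) {
  g <- as_igraph(net)
  if (igraph::ecount(g) < 1L)
    .stop_class("modularity needs at least one edge", "scovnet_spec_error")
  n <- igraph::vcount(g)
  best_q <- -Inf; best_m <- NULL
  for (i in seq_len(n_iter)) {
    set.seed(derive_seed(seed, "modularity", i))
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_fast_greedy(gp)
    q <- igraph::modularity(cl)
    if (q > best_q) {
      best_q <- q
      # original vertex i sits at position perm[i] of the permuted graph
      best_m <- as.integer(igraph::membership(cl))[perm]
    }
  }
  if (best_q < 0) {                       # single community dominates
    best_q <- 0
    best_m <- rep(1L, n)
  }
  best_m <- as.integer(factor(best_m))
  names(best_m) <- igraph::V(g)$name
  list(Q = best_q, partition = best_m, n_modules = length(unique(best_m)))
}

#' Sample degrees from the exponentially truncated power law
#'
#' Discrete degrees with cumulative distribution `P(K >= k) = k^(a-1)
#' exp(-k/b)` (normalized at `k = 1`), sampled by exact inverse-CDF.
#'
#' @param n number of draws.
#' @param a exponent.
#' @param b cut-off degree (> 0).
#' @param k_max support upper bound.
#' @return integer vector of degrees.
#' @export
sample_truncated_power_law <- function(n, a, b, k_max = 1000L) {
  k <- seq_len(k_max)
  S <- k^(a - 1) * exp(-k / b)
  # For a > 1 the curve rises until k = b(a-1), so it cannot be a survival
  # function from k = 1. Construct the distribution whose survival equals
  # the curve exactly on k >= 2 and put the remaining mass at k = 1
  # (P(K >= 1) = 1 always); the fitted cumulative curve then matches the
  # model at every degree above the minimum.
  if (max(S) > 1) S <- S / max(S)
  pmf <- c(1 - S[2L], pmax(S[-1L] - c(S[-(1:2)], 0), 0))
  sample(k, n, replace = TRUE, prob = pmf)
}

#' Fit an exponentially truncated power law to a degree distribution
#'
#' Fits the empirical cumulative degree distribution `P(K >= k)` by nonlinear
#' least squares (Levenberg-Marquardt) to `k^(a-1) exp(-k/b)`, with start
#' values from the log-linear form `log P = (a-1) log k - k/b`. `R^2` is
#' computed on the cumulative curve.
#'
#' @param net a `binary_network`, or an integer vector of degrees.
#' @return a `degree_fit`: list with `a`, `b`, `r_squared`, and the fitted
#'   cumulative curve (`k`, `p_emp`, `p_fit`).
#' @export
fit_truncated_power_law <- function(net) {
  degrees <- if (is.numeric(net) && is.null(dim(net))) net else net_degree(net)
  degrees <- degrees[degrees >= 1]
  ks <- sort(unique(degrees))
  if (length(ks) < 5L)
    .stop_class("need at least 5 distinct degree values to fit", "scovnet_degenerate_error")
  p_emp <- vapply(ks, function(k) mean(degrees >= k), 0)
  # log-linear start values; guard b0 > 0
  lf <- stats::lm(log(p_emp) ~ log(ks) + ks)
  a0 <- 1 + coef(lf)[[2L]]
  b0 <- -1 / coef(lf)[[3L]]
  if (!is.finite(b0) || b0 <= 0) b0 <- max(ks) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(p_emp ~ ks^(a - 1) * exp(-ks / b),
                      start = list(a = a0, b = b0),
                      lower = c(a = -10, b = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) .stop_class(paste0(
      "truncated power-law fit did not converge: ", conditionMessage(e)),
      "scovnet_fit_error"))
  p_fit <- stats::predict(fit)
  r2 <- 1 - sum((p_emp - p_fit)^2) / sum((p_emp - mean(p_emp))^2)
  structure(list(a = coef(fit)[["a"]], b = coef(fit)[["b"]],
                 r_squared = r2, k = ks, p_emp = p_emp, p_fit = p_fit),
            class = "degree_fit")
}

#' Random-failure resilience curve
#'
#' For each node fraction, removes that share of nodes uniformly at random
#' and records the size of the largest connected component relative to the
#' original node count, averaged over `reps` repetitions.
#'
#' @param net a `binary_network`.
#' @param fractions removal fractions in [0, 1).
#' @param reps Monte-Carlo repetitions per fraction (default 100).
#' @param seed integer seed.
#' @return a `resilience_curve`: data frame with `fraction_removed`,
#'   `relative_lcc`, `reps` attribute.
#' @export
random_failure <- function(net, fractions = seq(0, 0.9, by = 0.05),
                           reps = 100L, seed = 1L) {
  stopifnot(all(fractions >= 0 & fractions < 1))
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  rel <- numeric(length(fractions))
  for (i in seq_along(fractions)) {
    n_remove <- floor(fractions[i] * n)
    if (n_remove == 0L) { rel[i] <- 1; next }
    set.seed(derive_seed(seed, "failure", i))
    sizes <- vapply(seq_len(reps), function(r) {
      keep <- sample.int(n, n - n_remove)
      sub <- igraph::induced_subgraph(g, keep)
      max(igraph::components(sub)$csize) / n
    }, 0)
    rel[i] <- mean(sizes)
  }
  structure(data.frame(fraction_removed = fractions, relative_lcc = rel),
            reps = reps, class = c("resilience_curve", "data.frame"))
}
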