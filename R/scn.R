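# Structural covariance network construction: group-level Pearson association
# matrix over covariate-adjusted volumes, binarized across a density sweep.

#' Group-level association matrix
#'
#' Pairwise Pearson correlations of adjusted regional volumes across the
#' participants of one group; the diagonal is set to 0.
#'
#' @param resid a `residual_table` from [residualize()].
#' @param group group label (must be present with >= 4 participants).
#' @return an `assoc_matrix`: list with `r` (symmetric ROI x ROI matrix),
#'   `group`, `n_participants`.
#' @export
association_matrix <- function(resid, group) {
  idx <- which(resid$participants$group == group)
  if (length(idx) < 4L)
    .stop_class(sprintf("group %s has %d participants; need >= 4", group,
                        length(idx)), "scovnet_spec_error")
  X <- resid$residuals[idx, , drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  if (any(sds < 1e-12))
    .stop_class(paste0("zero-variance ROI(s): ",
                       paste(colnames(X)[sds < 1e-12], collapse = ", ")),
                "scovnet_degenerate_error")
  r <- stats::cor(X)
  diag(r) <- 0
  structure(list(r = r, group = group, n_participants = length(idx)),
            class = "assoc_matrix")
}

# Upper-triangle pair ranking shared by all thresholding operations: pairs
# ordered by decreasing correlation (signed by default), ties broken by
# lexicographic (i, j) for reproducibility.
.ranked_pairs <- function(assoc, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  r <- assoc$r
  n <- nrow(r)
  pairs <- .upper_pairs(n)
  vals <- r[pairs]
  key <- if (rank_by == "absolute") abs(vals) else vals
  ord <- order(-key, pairs[, 1L], pairs[, 2L])
  list(pairs = pairs[ord, , drop = FALSE], n = n,
       n_pairs = nrow(pairs), labels = rownames(r))
}

.network_from_edges <- function(rp, k) {
  A <- matrix(0L, rp$n, rp$n, dimnames = list(rp$labels, rp$labels))
  e <- rp$pairs[seq_len(k), , drop = FALSE]
  A[e] <- 1L
  A[e[, c(2L, 1L), drop = FALSE]] <- 1L
  A
}

#' Binarize an association matrix at a target density
#'
#' The `floor(density * N(N-1)/2)` node pairs with the largest correlations
#' become edges (signed ranking by default — positive covariance first — with
#' `absolute` available); everything else is 0. Ties are broken by
#' lexicographic pair order, so the operation is reproducible and the edge
#' set at a lower density is always nested inside a higher one.
#'
#' @param assoc an [association_matrix()].
#' @param density target edge fraction in (0, 1].
#' @param rank_by `"signed"` (default) or `"absolute"` correlation ranking.
#' @return a `binary_network`: list with `adjacency` (0/1 matrix), `density`
#'   (achieved), `density_target`, `node_labels`, `group`.
#' @export
binarize_at_density <- function(assoc, density, rank_by = "signed") {
  if (!is.numeric(density) || density <= 0 || density > 1)
    .stop_class("density must be in (0, 1]", "scovnet_spec_error")
  rp <- .ranked_pairs(assoc, rank_by)
  k <- floor(density * rp$n_pairs + 1e-9)
  if (k < 1L)
    .stop_class("density too low: target edge count is 0", "scovnet_spec_error")
  A <- .network_from_edges(rp, k)
  structure(list(adjacency = A, density = k / rp$n_pairs,
                 density_target = density, node_labels = rp$labels,
                 group = assoc$group),
            class = "binary_network")
}

#' Convert a binary network to an igraph object
#'
#' @param net a `binary_network` or bare 0/1 adjacency matrix.
#' @return an undirected igraph graph with ROI names as vertex names.
#' @export
as_igraph <- function(net) {
  A <- if (inherits(net, "binary_network")) net$adjacency else net
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

.is_connected_adj <- function(A) {
  igraph::is_connected(igraph::graph_from_adjacency_matrix(
    A, mode = "undirected", diag = FALSE))
}

#' Minimum density at which the network is fully connected
#'
#' Smallest density on a grid of step `grid_step` whose thresholded graph has
#' a single connected component. Edge addition is monotone, so the minimal
#' edge count is found by binary search and then rounded up to the grid.
#'
#' @param assoc an [association_matrix()].
#' @param grid_step density grid step (default 0.01).
#' @param rank_by correlation ranking, as in [binarize_at_density()].
#' @return the minimum connected density (a multiple of `grid_step`).
#' @export
minimum_connected_density <- function(assoc, grid_step = 0.01,
                                      rank_by = "signed") {
  rp <- .ranked_pairs(assoc, rank_by)
  if (!.is_connected_adj(.network_from_edges(rp, rp$n_pairs)))
    .stop_class("graph is not connected even at density 1", "scovnet_degenerate_error")
  lo <- rp$n - 1L; hi <- rp$n_pairs     # spanning tree lower bound
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (.is_connected_adj(.network_from_edges(rp, mid))) hi <- mid else lo <- mid + 1L
  }
  k_min <- lo
  # smallest grid density d with floor(d * n_pairs) >= k_min
  d <- ceiling((k_min / rp$n_pairs) / grid_step) * grid_step
  while (floor(d * rp$n_pairs + 1e-9) < k_min) d <- d + grid_step
  min(d, 1)
}

#' Build the density sweep of binary networks
#'
#' Thresholds the association matrix at every density of the analysis grid
#' (default 0.17 to 0.45 in steps of 0.02 — 15 networks). Connectivity is
#' verified at each density; disconnected networks are kept but flagged, and
#' path-length-based metrics downstream refuse flagged networks.
#'
#' @param assoc an [association_matrix()].
#' @param d_min,d_max,step density grid.
#' @param rank_by correlation ranking, as in [binarize_at_density()].
#' @return a `density_sweep`: list with `densities`, `networks` (list of
#'   `binary_network`), `connected` (logical per density), `group`.
#' @export
build_sweep <- function(assoc, d_min = 0.17, d_max = 0.45, step = 0.02,
                        rank_by = "signed") {
  if (d_min > d_max) .stop_class("d_min must be <= d_max", "scovnet_spec_error")
  densities <- seq(d_min, d_max + 1e-9, by = step)
  densities <- round(densities[densities <= d_max + 1e-9], 10)
  rp <- .ranked_pairs(assoc, rank_by)
  nets <- vector("list", length(densities))
  connected <- logical(length(densities))
  for (i in seq_along(densities)) {
    k <- floor(densities[i] * rp$n_pairs + 1e-9)
    if (k < 1L) .stop_class("density too low: target edge count is 0",
                            "scovnet_spec_error")
    A <- .network_from_edges(rp, k)
    connected[i] <- .is_connected_adj(A)
    nets[[i]] <- structure(list(adjacency = A, density = k / rp$n_pairs,
                                density_target = densities[i],
                                node_labels = rp$labels, group = assoc$group,
                                connected = connected[i]),
                           class = "binary_network")
  }
  if (!all(connected))
    warning(sprintf("disconnected network(s) at density: %s (group %s)",
                    paste(densities[!connected], collapse = ", "),
                    assoc$group %||% "?"))
  structure(list(densities = densities, networks = nets,
                 connected = connected, group = assoc$group),
            class = "density_sweep")
}
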