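# Non-parametric group inference on network topology: permutation null over
# group relabelings, per-density p-values, and an across-density functional
# (area-between-curves) statistic, all sharing one relabeling schedule.

.GLOBAL_METRICS <- c("C", "L", "E_global", "gamma", "lambda", "sigma", "Q")
.NODAL_METRICS <- c("degree", "clustering", "betweenness")

# Compute the requested metric curves for one group's residual rows across a
# density sweep. Fast path used both for observed data and inside the
# permutation loop; the estimator settings (n_random reference graphs,
# modularity restarts) are identical for both so the permutation null is
# exchangeable with the observed statistic.
.sweep_metrics <- function(X, densities, metrics, nodal_metrics, seed,
                           n_random = 6L, restarts = 20L, rank_by = "signed",
                           rewire_mult = 10L) {
  p <- ncol(X)
  r <- stats::cor(X)
  diag(r) <- 0

  # compiled fast path: global metrics without modularity or nodal curves
  if (!length(nodal_metrics) &&
      all(metrics %in% c("C", "L", "E_global", "gamma", "lambda", "sigma"))) {
    rr <- if (rank_by == "absolute") abs(r) else r
    want_sw <- any(c("gamma", "lambda", "sigma") %in% metrics)
    set.seed(seed)
    res <- .cpp_sweep_global(rr, densities,
                             "L" %in% metrics || want_sw,
                             "E_global" %in% metrics, want_sw,
                             as.integer(n_random), as.integer(rewire_mult),
                             10L)
    global <- res$global[metrics, , drop = FALSE]
    colnames(global) <- densities
    return(list(global = global, nodal = stats::setNames(list(), character()),
                connected = as.logical(res$connected)))
  }
  rp <- .ranked_pairs(list(r = r), rank_by)
  nd <- length(densities)
  global <- matrix(NA_real_, length(metrics), nd,
                   dimnames = list(metrics, densities))
  nodal <- lapply(nodal_metrics, function(m)
    matrix(NA_real_, p, nd, dimnames = list(colnames(X), densities)))
  names(nodal) <- nodal_metrics
  connected <- logical(nd)
  need_sw <- any(c("gamma", "lambda", "sigma") %in% metrics)
  need_dist <- need_sw || any(c("L", "E_global") %in% metrics) ||
    "betweenness" %in% nodal_metrics

  A <- matrix(0L, p, p, dimnames = list(colnames(X), colnames(X)))
  k_prev <- 0L
  for (d in seq_len(nd)) {
    k <- floor(densities[d] * rp$n_pairs + 1e-9)
    if (k > k_prev) {
      e <- rp$pairs[(k_prev + 1L):k, , drop = FALSE]
      A[e] <- 1L
      A[e[, c(2L, 1L), drop = FALSE]] <- 1L
      k_prev <- k
    }
    g <- NULL
    if (need_dist || "Q" %in% metrics) {
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                               diag = FALSE)
    }
    D <- NULL
    if (need_dist) D <- igraph::distances(g, algorithm = "unweighted")
    off <- if (!is.null(D)) D[row(D) != col(D)] else NULL
    connected[d] <- if (!is.null(off)) all(is.finite(off)) else
      .is_connected_adj(A)

    cl <- NULL
    if (any(c("C", "gamma", "sigma") %in% metrics) ||
        "clustering" %in% nodal_metrics)
      cl <- .adj_clustering(A)

    for (m in metrics) {
      global[m, d] <- switch(m,
        C = cl$mean,
        L = if (connected[d]) mean(off) else NA_real_,
        E_global = { inv <- 1 / off; inv[!is.finite(inv)] <- 0; mean(inv) },
        Q = {
          best <- -Inf
          for (i in seq_len(restarts)) {
            set.seed(derive_seed(seed, "modq", d * 10000L + i))
            perm <- sample.int(p)
            q <- igraph::modularity(igraph::cluster_fast_greedy(
              igraph::permute(g, perm)))
            if (q > best) best <- q
          }
          max(best, 0)
        },
        gamma = , lambda = , sigma = NA_real_)   # filled below
    }
    if (need_sw && connected[d]) {
      Cr <- Lr <- numeric(0)
      for (i in seq_len(n_random)) {
        ok <- FALSE
        for (attempt in 1:10) {
          set.seed(derive_seed(seed, "permsw",
                               d * 100000L + i * 100L + attempt))
          g2 <- igraph::rewire(g, igraph::keeping_degseq(
            niter = rewire_mult * igraph::ecount(g)))
          if (igraph::is_connected(g2)) { ok <- TRUE; break }
        }
        if (ok) {
          Cr <- c(Cr, mean(igraph::transitivity(g2, type = "local",
                                                isolates = "zero")))
          Lr <- c(Lr, igraph::mean_distance(g2, directed = FALSE))
        }
      }
      if (length(Cr) && mean(Cr) > 0) {
        gam <- cl$mean / mean(Cr)
        lam <- mean(off) / mean(Lr)
        if ("gamma" %in% metrics) global["gamma", d] <- gam
        if ("lambda" %in% metrics) global["lambda", d] <- lam
        if ("sigma" %in% metrics) global["sigma", d] <- gam / lam
      }
    }
    for (m in nodal_metrics) {
      nodal[[m]][, d] <- switch(m,
        degree = rowSums(A),
        clustering = cl$per_node,
        betweenness = igraph::betweenness(g, directed = FALSE) /
          ((p - 1) * (p - 2) / 2))
    }
  }
  list(global = global, nodal = nodal, connected = connected)
}

#' Metric curves across the density sweep for one group
#'
#' Convenience wrapper assembling every global metric (and, optionally, the
#' nodal metrics) of one group's covariance network at each density of the
#' sweep.
#'
#' @param resid a `residual_table`.
#' @param group group label.
#' @param d_min,d_max,step density grid (defaults 0.17/0.45/0.02).
#' @param metrics global metrics to compute (subset of `C`, `L`, `E_global`,
#'   `gamma`, `lambda`, `sigma`, `Q`).
#' @param nodal_metrics nodal metrics (subset of `degree`, `clustering`,
#'   `betweenness`), or `NULL`.
#' @param n_random reference graphs for gamma/lambda/sigma (default 20).
#' @param modularity_restarts greedy restarts for Q (default 1000).
#' @param seed integer seed for the stochastic metrics.
#' @param rank_by correlation ranking for thresholding.
#' @return a `metric_curves` object: list with `densities`, `global` (metric
#'   x density matrix), `nodal` (list of node x density matrices),
#'   `connected`, `group`.
#' @export
metric_curves <- function(resid, group, d_min = 0.17, d_max = 0.45,
                          step = 0.02, metrics = .GLOBAL_METRICS,
                          nodal_metrics = .NODAL_METRICS, n_random = 20L,
                          modularity_restarts = 1000L, seed = 1L,
                          rank_by = "signed") {
  idx <- which(resid$participants$group == group)
  if (!length(idx))
    .stop_class(paste0("group not present: ", group), "scovnet_spec_error")
  densities <- round(seq(d_min, d_max + 1e-9, by = step), 10)
  out <- .sweep_metrics(resid$residuals[idx, , drop = FALSE], densities,
                        metrics, nodal_metrics %||% character(), seed,
                        n_random = n_random, restarts = modularity_restarts,
                        rank_by = rank_by)
  structure(c(list(densities = densities, group = group), out),
            class = "metric_curves")
}

#' Random group relabelings
#'
#' Each repetition is a uniformly random partition of the pooled participants
#' into the two original group sizes, reproducible from the seed.
#'
#' @param labels character vector of group labels (two distinct values).
#' @param n_perm number of repetitions.
#' @param seed integer seed.
#' @return an `n_perm x n` logical matrix; `TRUE` marks membership of the
#'   first (alphabetically) group in that repetition.
#' @export
permute_groups <- function(labels, n_perm = 1000L, seed = 1L) {
  gs <- sort(unique(labels))
  stopifnot(length(gs) == 2L)
  n <- length(labels)
  n1 <- sum(labels == gs[1L])
  if (n < 8L)
    warning("fewer than 8 participants pooled; permutation null is coarse")
  out <- matrix(FALSE, n_perm, n)
  for (i in seq_len(n_perm)) {
    set.seed(derive_seed(seed, "perm", i))
    out[i, sample.int(n, n1)] <- TRUE
  }
  out
}

.add_one_p <- function(obs, null) {
  null <- null[is.finite(null)]
  if (!length(null) || !is.finite(obs)) return(NA_real_)
  (1 + sum(abs(null) >= abs(obs))) / (length(null) + 1)
}

# FDA across-threshold statistic: signed area between curves. Densities
# missing in a replicate (fragmented graph) are dropped and the sum rescaled
# to the full grid length (complete-pairs convention).
.fda_stat <- function(diff_curve) {
  ok <- is.finite(diff_curve)
  if (!any(ok)) return(NA_real_)
  sum(diff_curve[ok]) * length(diff_curve) / sum(ok)
}

#' Permutation test of network topology between two groups
#'
#' Compares every requested metric curve between two groups across the
#' density sweep. For each of `n_perm` relabelings, participants' adjusted
#' volumes are reassigned to two random groups of the original sizes, both
#' group networks are rebuilt, and all metrics recomputed — one shared
#' relabeling schedule drives every metric. Per density, the two-tailed
#' p-value is the add-one percentile of the observed difference in the null
#' distribution; across densities, the functional (FDA) statistic is the
#' signed area between the two curves, tested by the same percentile rule.
#' Nodal metrics get a per-node FDA p-value with Benjamini-Hochberg FDR
#' across nodes.
#'
#' The result is orientation-canonical: swapping the order of `groups`
#' negates the observed differences and FDA statistics but leaves every
#' p-value identical.
#'
#' @param resid a `residual_table` (typically `scope = "pooled_pair"` over
#'   exactly these two groups).
#' @param groups the two group labels; differences are `groups[1] -
#'   groups[2]`.
#' @param metrics,nodal_metrics metric selections as in [metric_curves()].
#' @param d_min,d_max,step density grid.
#' @param n_perm permutation repetitions (default 1000).
#' @param n_random reference graphs per network for gamma/lambda/sigma
#'   inside the test (default 6; applied to observed and null networks alike
#'   so the statistic is exchangeable).
#' @param modularity_restarts greedy restarts for Q inside the test
#'   (default 20; same note).
#' @param rewire_mult swap attempts per reference rewiring, as a multiple of
#'   the edge count (default 3 inside the test; [normalized_small_world()]
#'   uses 10 for observed networks).
#' @param seed integer seed.
#' @param rank_by correlation ranking for thresholding.
#' @param fda_tail `"two"` (default) or `"one"` tailed FDA p-values.
#' @param fdr_q FDR level for nodal decisions.
#' @return an `scn_permutation` object; see Details in the package vignette.
#' @export
permutation_test <- function(resid, groups,
                             metrics = c("C", "L", "E_global", "sigma"),
                             nodal_metrics = NULL,
                             d_min = 0.17, d_max = 0.45, step = 0.02,
                             n_perm = 1000L, n_random = 6L,
                             modularity_restarts = 20L, rewire_mult = 3L,
                             seed = 1L,
                             rank_by = "signed", fda_tail = c("two", "one"),
                             fdr_q = 0.05) {
  fda_tail <- match.arg(fda_tail)
  stopifnot(length(groups) == 2L, all(metrics %in% .GLOBAL_METRICS))
  nodal_metrics <- nodal_metrics %||% character()
  parts <- resid$participants
  keep <- parts$group %in% groups
  labels <- parts$group[keep]
  X <- resid$residuals[keep, , drop = FALSE]
  cg <- sort(groups)                 # canonical orientation
  flip <- !identical(as.character(groups), cg)
  densities <- round(seq(d_min, d_max + 1e-9, by = step), 10)
  nd <- length(densities)
  n <- nrow(X)
  n1 <- sum(labels == cg[1L])

  eval_split <- function(rows1, sub_seed) {
    m1 <- .sweep_metrics(X[rows1, , drop = FALSE], densities, metrics,
                         nodal_metrics, derive_seed(sub_seed, "g1"),
                         n_random, modularity_restarts, rank_by, rewire_mult)
    m2 <- .sweep_metrics(X[!rows1, , drop = FALSE], densities, metrics,
                         nodal_metrics, derive_seed(sub_seed, "g2"),
                         n_random, modularity_restarts, rank_by, rewire_mult)
    list(m1 = m1, m2 = m2)
  }

  obs_rows <- labels == cg[1L]
  obs <- eval_split(obs_rows, derive_seed(seed, "observed"))
  obs_diff <- obs$m1$global - obs$m2$global
  obs_nodal_diff <- stats::setNames(
    lapply(nodal_metrics, function(m) obs$m1$nodal[[m]] - obs$m2$nodal[[m]]),
    nodal_metrics)

  schedule <- permute_groups(labels, n_perm = n_perm, seed = seed)
  null_diff <- array(NA_real_, c(n_perm, length(metrics), nd),
                     dimnames = list(NULL, metrics, densities))
  null_fda_nodal <- lapply(nodal_metrics, function(m)
    matrix(NA_real_, n_perm, ncol(X)))
  names(null_fda_nodal) <- nodal_metrics
  n_fragmented <- 0L
  for (i in seq_len(n_perm)) {
    pm <- eval_split(schedule[i, ], derive_seed(seed, "permrep", i))
    d <- pm$m1$global - pm$m2$global
    if (anyNA(d)) n_fragmented <- n_fragmented + 1L
    null_diff[i, , ] <- d
    for (m in nodal_metrics) {
      nd_diff <- pm$m1$nodal[[m]] - pm$m2$nodal[[m]]
      null_fda_nodal[[m]][i, ] <- apply(nd_diff, 1L, .fda_stat)
    }
  }

  per_metric <- lapply(metrics, function(m) {
    od <- obs_diff[m, ]
    nm <- null_diff[, m, , drop = FALSE][, 1L, , drop = TRUE]
    if (nd == 1L) nm <- matrix(nm, ncol = 1L)
    p_density <- vapply(seq_len(nd), function(d)
      .add_one_p(od[d], nm[, d]), 0)
    obs_fda <- .fda_stat(od)
    null_fda <- apply(nm, 1L, .fda_stat)
    fda_p <- if (fda_tail == "two") .add_one_p(obs_fda, null_fda) else {
      nf <- null_fda[is.finite(null_fda)]
      (1 + sum(nf >= obs_fda)) / (length(nf) + 1)
    }
    sgn <- if (flip) -1 else 1
    list(metric = m,
         observed_group1 = if (flip) obs$m2$global[m, ] else obs$m1$global[m, ],
         observed_group2 = if (flip) obs$m1$global[m, ] else obs$m2$global[m, ],
         observed_diff = sgn * od,
         null_diffs = sgn * nm,
         p_per_density = p_density,
         fda_statistic = sgn * obs_fda, fda_p = fda_p, n_perm = n_perm)
  })
  names(per_metric) <- metrics

  nodal <- NULL
  if (length(nodal_metrics)) {
    nodal <- lapply(nodal_metrics, function(m) {
      obs_fda_n <- apply(obs_nodal_diff[[m]], 1L, .fda_stat)
      p_n <- vapply(seq_along(obs_fda_n), function(j)
        .add_one_p(obs_fda_n[j], null_fda_nodal[[m]][, j]), 0)
      fdr <- fdr_bh(p_n, q = fdr_q)
      data.frame(roi = colnames(X),
                 fda_statistic = (if (flip) -1 else 1) * obs_fda_n,
                 fda_p = p_n, fdr_p = fdr$adjusted,
                 significant_raw = p_n < 0.05,
                 significant_fdr = fdr$reject, row.names = NULL)
    })
    names(nodal) <- nodal_metrics
  }

  structure(list(groups = groups, densities = densities,
                 metrics = per_metric, nodal = nodal,
                 n_perm = n_perm, seed = seed,
                 n_fragmented_replicates = n_fragmented,
                 fda_tail = fda_tail),
            class = "scn_permutation")
}

#' @export
print.scn_permutation <- function(x, ...) {
  cat(sprintf("<scn_permutation> %s vs %s, %d permutations, %d densities\n",
              x$groups[1], x$groups[2], x$n_perm, length(x$densities)))
  for (m in names(x$metrics))
    cat(sprintf("  %-9s FDA stat % .4f  p = %.4g\n", m,
                x$metrics[[m]]$fda_statistic, x$metrics[[m]]$fda_p))
  invisible(x)
}

#' Nodal FDA tests with FDR correction
#'
#' Tidy per-node results of an [permutation_test()] run that included nodal
#' metrics: per-node FDA p-values and Benjamini-Hochberg decisions per
#' metric, reporting both raw and corrected significance.
#'
#' @param perm an `scn_permutation` with nodal results.
#' @param q FDR level (default 0.05).
#' @return data frame with columns `metric`, `roi`, `fda_statistic`,
#'   `fda_p`, `fdr_p`, `significant_raw`, `significant_fdr`.
#' @export
nodal_tests <- function(perm, q = 0.05) {
  if (is.null(perm$nodal))
    .stop_class("permutation result has no nodal metrics", "scovnet_spec_error")
  out <- do.call(rbind, lapply(names(perm$nodal), function(m) {
    df <- perm$nodal[[m]]
    fdr <- fdr_bh(df$fda_p, q = q)
    df$fdr_p <- fdr$adjusted
    df$significant_fdr <- fdr$reject
    cbind(metric = m, df)
  }))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values (monotone non-decreasing in rank) and rejection
#' decisions at level `q`.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` and logical `reject`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(adjusted = numeric(0), reject = logical(0)))
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= q)
}
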