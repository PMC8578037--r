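# Orchestration: one configuration drives load -> residualize -> SCN sweep ->
# topology -> permutation inference -> clinical statistics -> result bundle.

#' Pipeline configuration
#'
#' Collects every analysis parameter with the study defaults: density grid
#' 0.17-0.45 in 0.02 steps, 1000 permutations, 20 random reference graphs
#' and 1000 modularity restarts on observed networks, FDR q = 0.05, and the
#' three pairwise comparisons cMDD vs HC, RD vs HC, cMDD vs RD. The
#' `*_perm` variants are the cheaper estimator settings used inside
#' permutation replicates (applied to the observed statistic of the test as
#' well, which keeps the null exchangeable). Every stage derives its own
#' sub-seed from `seed`.
#'
#' @param comparisons list of 2-vectors of group labels.
#' @param d_min,d_max,step density grid.
#' @param n_perm permutation repetitions.
#' @param n_random reference graphs for observed gamma/lambda/sigma.
#' @param n_random_perm reference graphs inside the permutation test.
#' @param modularity_restarts greedy restarts for observed Q.
#' @param modularity_restarts_perm restarts inside the permutation test.
#' @param resilience_reps,resilience_fractions random-failure settings.
#' @param degree_fit_density density at which the degree distribution is
#'   fitted (default `d_min`; the lowest analyzed density).
#' @param metrics,nodal_metrics metric selections.
#' @param fdr_q FDR level.
#' @param rank_by correlation ranking for thresholding.
#' @param seed master seed.
#' @param out_dir output directory or `NULL`.
#' @return a `run_config` list.
#' @export
run_config <- function(comparisons = list(c("cMDD", "HC"), c("RD", "HC"),
                                          c("cMDD", "RD")),
                       d_min = 0.17, d_max = 0.45, step = 0.02,
                       n_perm = 1000L, n_random = 20L, n_random_perm = 6L,
                       modularity_restarts = 1000L,
                       modularity_restarts_perm = 20L,
                       resilience_reps = 100L,
                       resilience_fractions = seq(0, 0.9, by = 0.05),
                       degree_fit_density = d_min,
                       metrics = c("C", "L", "E_global", "gamma", "lambda",
                                   "sigma", "Q"),
                       nodal_metrics = c("degree", "clustering",
                                         "betweenness"),
                       fdr_q = 0.05, rank_by = "signed", seed = 1L,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(d_min <= d_max, step > 0, n_perm > 0, n_random > 0,
            modularity_restarts > 0, fdr_q > 0)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' For each configured comparison: pooled-pair residualization, group
#' association matrices, density sweeps with minimum-connected-density
#' checks, observed metric curves (full-quality estimator settings),
#' truncated power-law degree fits, random-failure resilience, the
#' permutation/FDA test of all global metrics, and nodal FDA tests with FDR.
#' Alongside, the clinical arm: demographic tests, omnibus MANCOVA (when
#' estimable), per-ROI ANCOVA with post-hoc contrasts, and ROI-psychometric
#' correlations for the patient groups. All results, a Table-style summary,
#' and a manifest (config, seeds, versions, per-stage log) are returned and,
#' if `out_dir` is set, written to disk.
#'
#' @param config a [run_config()].
#' @param cohort an `scn_cohort`, or `NULL` to build one from `spec` /
#'   `volumes_path` + `participants_path`.
#' @param spec a [cohort_spec()] to simulate from (used when `cohort` is
#'   `NULL`).
#' @param volumes_path,participants_path input files (used when both
#'   `cohort` and `spec` are `NULL`).
#' @param catalog catalog for file loading (default [roi_catalog()]).
#' @return an `scn_bundle` list: `clinical`, `comparisons`, `summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL, spec = NULL,
                         volumes_path = NULL, participants_path = NULL,
                         catalog = NULL) {
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  if (is.null(cohort)) {
    if (!is.null(spec)) {
      cohort <- generate_cohort(spec, seed = derive_seed(config$seed, "cohort"))
      note("simulated cohort: %d participants x %d ROIs",
           nrow(cohort$volumes), ncol(cohort$volumes))
    } else {
      catalog <- catalog %||% roi_catalog()
      parts <- load_participants(participants_path)
      vt <- load_volume_table(volumes_path, catalog)
      keep <- parts$id %in% vt$ids
      cohort <- structure(list(participants = parts[keep, , drop = FALSE],
                               volumes = vt$volumes[match(parts$id[keep],
                                                          vt$ids), ,
                                                    drop = FALSE],
                               catalog = catalog), class = "scn_cohort")
      note("loaded cohort: %d participants x %d ROIs",
           nrow(cohort$volumes), ncol(cohort$volumes))
    }
  }

  clinical <- list()
  clinical$demographics <- demographic_tests(cohort$participants)
  note("demographic tests: %d variables", nrow(clinical$demographics))
  clinical$mancova <- tryCatch(scn_mancova(cohort), error = function(e) {
    note("MANCOVA skipped: %s", conditionMessage(e))
    NULL
  })
  clinical$roi_ancova <- per_roi_ancova(cohort, q = config$fdr_q)
  note("per-ROI ANCOVA: %d ROIs, %d FDR-significant at q = %g",
       nrow(clinical$roi_ancova),
       sum(clinical$roi_ancova$fdr_p <= config$fdr_q, na.rm = TRUE),
       config$fdr_q)
  clinical$correlations <- lapply(
    intersect(c("cMDD", "RD"), unique(cohort$participants$group)),
    function(g) roi_psychometric_correlations(cohort, g))
  names(clinical$correlations) <- intersect(
    c("cMDD", "RD"), unique(cohort$participants$group))

  comparisons <- list()
  for (ci in seq_along(config$comparisons)) {
    pair <- config$comparisons[[ci]]
    tag <- paste(pair, collapse = "_vs_")
    note("comparison %s", tag)
    resid <- residualize(cohort, scope = "pooled_pair", groups = pair)
    cmp <- list(groups = pair)
    for (g in pair) {
      assoc <- association_matrix(resid, g)
      cmp[[paste0("dmin_", g)]] <- minimum_connected_density(
        assoc, rank_by = config$rank_by)
      sweep <- build_sweep(assoc, config$d_min, config$d_max, config$step,
                           rank_by = config$rank_by)
      cmp[[paste0("curves_", g)]] <- metric_curves(
        resid, g, config$d_min, config$d_max, config$step,
        metrics = config$metrics, nodal_metrics = config$nodal_metrics,
        n_random = config$n_random,
        modularity_restarts = config$modularity_restarts,
        seed = derive_seed(config$seed, paste0("curves_", g), ci),
        rank_by = config$rank_by)
      net_fit <- binarize_at_density(assoc, config$degree_fit_density,
                                     rank_by = config$rank_by)
      cmp[[paste0("degree_fit_", g)]] <- tryCatch(
        fit_truncated_power_law(net_fit), error = function(e) {
          note("degree fit failed for %s: %s", g, conditionMessage(e))
          NULL
        })
      cmp[[paste0("resilience_", g)]] <- random_failure(
        net_fit, fractions = config$resilience_fractions,
        reps = config$resilience_reps,
        seed = derive_seed(config$seed, paste0("resilience_", g), ci))
      note("  group %s: D_min = %.2f, %d/%d densities connected", g,
           cmp[[paste0("dmin_", g)]], sum(sweep$connected),
           length(sweep$connected))
    }
    cmp$permutation <- permutation_test(
      resid, pair, metrics = config$metrics,
      nodal_metrics = config$nodal_metrics,
      d_min = config$d_min, d_max = config$d_max, step = config$step,
      n_perm = config$n_perm, n_random = config$n_random_perm,
      modularity_restarts = config$modularity_restarts_perm,
      seed = derive_seed(config$seed, "comparison", ci),
      rank_by = config$rank_by, fdr_q = config$fdr_q)
    note("  permutation test done (%d fragmented replicates)",
         cmp$permutation$n_fragmented_replicates)
    cmp$nodal <- nodal_tests(cmp$permutation, q = config$fdr_q)
    comparisons[[tag]] <- cmp
  }

  summary <- .bundle_summary(comparisons, config)
  manifest <- list(
    package = "scovnet",
    version = as.character(utils::packageVersion("scovnet")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    log = log,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  bundle <- structure(list(clinical = clinical, comparisons = comparisons,
                           summary = summary, manifest = manifest),
                      class = "scn_bundle")
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

# Comparison-table summary: per comparison, each global metric's across-
# density mean in both groups and the FDA p-value; degree-fit parameters
# appended per group.
.bundle_summary <- function(comparisons, config) {
  rows <- list()
  for (tag in names(comparisons)) {
    cmp <- comparisons[[tag]]
    for (m in names(cmp$permutation$metrics)) {
      pm <- cmp$permutation$metrics[[m]]
      g1c <- cmp[[paste0("curves_", cmp$groups[1])]]$global[m, ]
      g2c <- cmp[[paste0("curves_", cmp$groups[2])]]$global[m, ]
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = tag, metric = m,
        group1 = cmp$groups[1], mean_group1 = mean(g1c, na.rm = TRUE),
        group2 = cmp$groups[2], mean_group2 = mean(g2c, na.rm = TRUE),
        fda_p = pm$fda_p)
    }
    for (g in cmp$groups) {
      fit <- cmp[[paste0("degree_fit_", g)]]
      if (!is.null(fit))
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = tag, metric = "degree_fit",
          group1 = g, mean_group1 = fit$a,
          group2 = sprintf("b=%.2f", fit$b), mean_group2 = fit$r_squared,
          fda_p = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results(bundle$summary, file.path(dir, "summary.tsv"))
  write_results(bundle$clinical$demographics,
                file.path(dir, "demographics.tsv"))
  write_results(bundle$clinical$roi_ancova, file.path(dir, "roi_ancova.tsv"))
  if (!is.null(bundle$clinical$mancova))
    write_results(unclass(bundle$clinical$mancova),
                  file.path(dir, "mancova.json"))
  for (tag in names(bundle$comparisons)) {
    cmp <- bundle$comparisons[[tag]]
    sub <- file.path(dir, tag)
    dir.create(sub, showWarnings = FALSE)
    for (g in cmp$groups) {
      curves <- cmp[[paste0("curves_", g)]]
      df <- data.frame(density = curves$densities, t(curves$global),
                       check.names = FALSE)
      write_results(df, file.path(sub, paste0("global_curves_", g, ".tsv")))
      write_results(as.data.frame(cmp[[paste0("resilience_", g)]]),
                    file.path(sub, paste0("resilience_", g, ".tsv")))
      fit <- cmp[[paste0("degree_fit_", g)]]
      if (!is.null(fit))
        write_results(unclass(fit)[c("a", "b", "r_squared")],
                      file.path(sub, paste0("degree_fit_", g, ".json")))
    }
    perm <- cmp$permutation
    perm_doc <- list(groups = perm$groups, densities = perm$densities,
                     n_perm = perm$n_perm, seed = perm$seed,
                     fda_tail = perm$fda_tail,
                     n_fragmented_replicates = perm$n_fragmented_replicates,
                     metrics = lapply(perm$metrics, function(pm)
                       pm[setdiff(names(pm), "null_diffs")]))
    write_results(perm_doc, file.path(sub, "permutation.json"))
    write_results(cmp$nodal, file.path(sub, "nodal_tests.tsv"))
  }
  write_results(bundle$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @export
print.scn_bundle <- function(x, ...) {
  cat("<scn_bundle>\n")
  cat(sprintf("  comparisons: %s\n",
              paste(names(x$comparisons), collapse = ", ")))
  cat(sprintf("  summary: %d rows\n", nrow(x$summary)))
  invisible(x)
}
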