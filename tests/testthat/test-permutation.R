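tiny_resid <- function(seed, groups = c("cMDD", "HC")) {
  co <- generate_cohort(cohort_spec_tiny(seed = seed))
  residualize(co, "pooled_pair", groups = groups)
}

test_that("relabeling schedules preserve sizes and are uniform", {
  labels <- rep(c("cMDD", "HC"), c(25, 35))
  n1 <- sum(labels == sort(unique(labels))[1])   # first group alphabetically
  sched <- permute_groups(labels, n_perm = 1000, seed = 3)
  expect_equal(dim(sched), c(1000L, 60L))
  expect_true(all(rowSums(sched) == n1))
  expect_false(identical(sched[1, ], sched[2, ]))
  # each participant lands in group 1 with frequency ~ n1/60
  freq <- colMeans(sched)
  se <- sqrt((n1 / 60) * (1 - n1 / 60) / 1000)
  expect_true(all(abs(freq - n1 / 60) < 3.5 * se + 1e-9))
  expect_warning(permute_groups(rep(c("a", "b"), c(3, 3)), 10, 1), "coarse")
})

test_that("add-one percentile p-values behave at the null center and floor", {
  # observed 0 against a symmetric null: p = 1
  expect_equal(scovnet:::.add_one_p(0, c(-2, -1, 1, 2)), 1)
  # observed beyond all 999 nulls: p = 1/1000
  expect_equal(scovnet:::.add_one_p(10, rnorm(999)), 1 / 1000)
  # observed at the median magnitude of its own null: p ~ 0.5
  null <- seq(-1, 1, length.out = 201)
  expect_equal(scovnet:::.add_one_p(median(abs(null)), null), 0.5,
               tolerance = 0.02)
})

test_that("the FDA statistic is the (rescaled) signed area between curves", {
  expect_equal(scovnet:::.fda_stat(c(1, 2, -1)), 2)
  # missing densities use complete pairs, rescaled to the grid length
  expect_equal(scovnet:::.fda_stat(c(1, NA, 2)), 3 / 2 * 3)
  expect_true(is.na(scovnet:::.fda_stat(c(NA_real_, NA_real_))))
})

test_that("permutation test is exchangeable under group relabeling", {
  rt <- tiny_resid(21)
  p1 <- permutation_test(rt, c("cMDD", "HC"), metrics = c("C", "E_global"),
                         n_perm = 30, seed = 5)
  p2 <- permutation_test(rt, c("HC", "cMDD"), metrics = c("C", "E_global"),
                         n_perm = 30, seed = 5)
  for (m in c("C", "E_global")) {
    expect_equal(p1$metrics[[m]]$p_per_density, p2$metrics[[m]]$p_per_density)
    expect_equal(p1$metrics[[m]]$fda_p, p2$metrics[[m]]$fda_p)
    expect_equal(p1$metrics[[m]]$fda_statistic,
                 -p2$metrics[[m]]$fda_statistic)
    expect_equal(p1$metrics[[m]]$observed_diff,
                 -p2$metrics[[m]]$observed_diff)
  }
})

test_that("identical groups give p-values at the top of the scale", {
  co <- generate_cohort(cohort_spec_tiny(seed = 22))
  # duplicate HC under two labels: observed difference exactly zero
  keep <- co$participants$group == "HC"
  parts <- co$participants[keep, ]
  vols <- co$volumes[keep, ]
  parts2 <- parts
  parts2$id <- paste0(parts$id, "_b")
  parts2$group <- "cMDD"
  vols2 <- vols
  rownames(vols2) <- parts2$id
  co2 <- list(participants = as_participant_table(rbind(parts, parts2)),
              volumes = rbind(vols, vols2), catalog = co$catalog)
  rt <- residualize(co2, "pooled_pair", groups = c("cMDD", "HC"))
  pt <- permutation_test(rt, c("cMDD", "HC"), metrics = "C",
                         n_perm = 19, seed = 6)
  expect_equal(unname(pt$metrics$C$observed_diff),
               rep(0, 15), tolerance = 1e-12)
  expect_true(all(pt$metrics$C$p_per_density == 1))
})

test_that("duplicate data under two labels give identical curves", {
  rt <- tiny_resid(23)
  c1 <- metric_curves(rt, "cMDD", metrics = c("C", "L", "E_global"),
                      nodal_metrics = NULL, seed = 4)
  # same rows relabeled
  rt2 <- rt
  rt2$participants$group[rt2$participants$group == "cMDD"] <- "XX"
  c2 <- metric_curves(rt2, "XX", metrics = c("C", "L", "E_global"),
                      nodal_metrics = NULL, seed = 4)
  expect_equal(c1$global, c2$global)
})

test_that("curves have the advertised shape and planted effects dominate", {
  rt <- residualize(generate_cohort(cohort_spec_paperlike_tiny(seed = 24)),
                    "pooled_pair", groups = c("cMDD", "HC"))
  mc <- metric_curves(rt, "HC", metrics = c("C", "L", "E_global", "sigma"),
                      nodal_metrics = c("degree", "clustering", "betweenness"),
                      n_random = 5, seed = 7)
  expect_equal(dim(mc$global), c(4L, 15L))
  expect_equal(dim(mc$nodal$degree), c(20L, 15L))
  expect_true(all(is.finite(mc$global["C", ])))
  # control structure is more small-world than the patient structure,
  # density by density (strong planted effect at these sizes)
  mc2 <- metric_curves(rt, "cMDD", metrics = "sigma", nodal_metrics = NULL,
                       n_random = 5, seed = 8)
  expect_gt(mean(mc$global["sigma", ] - mc2$global["sigma", ], na.rm = TRUE),
            0)
})

test_that("compiled sweep path matches the igraph reference implementation", {
  rt <- tiny_resid(26)
  X <- rt$residuals[rt$participants$group == "HC", ]
  dens <- seq(0.17, 0.45, 0.04)
  mets <- c("C", "L", "E_global", "gamma", "lambda", "sigma")
  cpp <- scovnet:::.sweep_metrics(X, dens, mets, character(), 5,
                                  n_random = 12, rewire_mult = 10)
  # requesting a nodal metric forces the igraph path
  ref <- scovnet:::.sweep_metrics(X, dens, mets, "degree", 5,
                                  n_random = 12, rewire_mult = 10)
  # deterministic metrics agree exactly
  for (m in c("C", "L", "E_global"))
    expect_equal(cpp$global[m, ], ref$global[m, ], tolerance = 1e-12)
  # the rewired-reference normalizations are independent Monte-Carlo
  # estimates of the same quantity: agreement within a few percent
  ok <- is.finite(cpp$global["gamma", ]) & is.finite(ref$global["gamma", ])
  expect_true(any(ok))
  expect_lt(max(abs(cpp$global["gamma", ok] / ref$global["gamma", ok] - 1)),
            0.15)
  expect_lt(max(abs(cpp$global["lambda", ok] / ref$global["lambda", ok] - 1)),
            0.05)
})

test_that("nodal tests report raw and FDR decisions", {
  rt <- tiny_resid(25)
  pt <- permutation_test(rt, c("cMDD", "HC"), metrics = "C",
                         nodal_metrics = c("degree", "clustering"),
                         n_perm = 40, seed = 9)
  nt <- nodal_tests(pt, q = 0.05)
  expect_equal(sort(unique(nt$metric)), c("clustering", "degree"))
  expect_equal(nrow(nt), 40L)        # 20 ROIs x 2 metrics
  expect_true(all(nt$fdr_p >= nt$fda_p - 1e-12))
  expect_true(all(nt$fda_p > 0 & nt$fda_p <= 1))
})

test_that("BH step-up matches hand arithmetic", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.9), q = 0.05)
  expect_equal(out$adjusted, c(0.04, 0.04, 0.04, 0.9))
  expect_equal(out$reject, c(TRUE, TRUE, TRUE, FALSE))
  one <- fdr_bh(0.03, q = 0.05)
  expect_equal(one$adjusted, 0.03)
  expect_true(one$reject)
  expect_equal(fdr_bh(numeric(0))$adjusted, numeric(0))
  allsame <- fdr_bh(rep(0.2, 5), q = 0.05)
  expect_equal(allsame$adjusted, rep(0.2, 5))
  # a typical nodal scenario: 10 strong signals among 90 nulls
  mix <- fdr_bh(c(rep(0.001, 10), rep(1, 90)), q = 0.05)
  expect_equal(sum(mix$reject), 10L)
})
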