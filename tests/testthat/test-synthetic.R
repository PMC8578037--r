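test_that("generation is deterministic in the seed", {
  spec <- cohort_spec_tiny(seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$participants, b$participants)
  c2 <- generate_cohort(spec, seed = 12)
  expect_false(identical(a$volumes, c2$volumes))
})

test_that("null spec with zero loadings yields uncorrelated ROIs", {
  cat20 <- roi_catalog_tiny()
  p <- nrow(cat20)
  base <- rep(500, p)
  spec <- cohort_spec(
    cat20, n_per_group = c(cMDD = 50, RD = 50, HC = 50),
    age_mean = c(cMDD = 21, RD = 21, HC = 21),
    age_sd = c(cMDD = 3, RD = 3, HC = 3),
    base_means = base, beta_age = rep(0, p), beta_icv = rep(0, p),
    noise_sd = rep(1, p),
    loadings = list(cMDD = matrix(0, p, 1), RD = matrix(0, p, 1),
                    HC = matrix(0, p, 1)), seed = 21)
  co <- generate_cohort(spec)
  # at n = 50, sd(r) ~ 1/sqrt(49); |r| < 0.3 is a ~2.1-sigma bound, so a
  # small percentage of the 190 pairs may exceed it by chance
  offdiag <- unlist(lapply(c("cMDD", "RD", "HC"), function(g) {
    r <- cor(co$volumes[co$participants$group == g, ])
    abs(r[upper.tri(r)])
  }))
  expect_gt(mean(offdiag < 0.3), 0.96)
  expect_lt(mean(offdiag), 0.15)
})

test_that("a planted factor raises within-set correlations in one group only", {
  cat20 <- roi_catalog_tiny()
  p <- nrow(cat20)
  L <- matrix(0, p, 1)
  L[1:10, 1] <- 1
  spec <- cohort_spec(
    cat20, n_per_group = c(cMDD = 120, HC = 120),
    age_mean = c(cMDD = 21, HC = 21), age_sd = c(cMDD = 3, HC = 3),
    base_means = rep(500, p), beta_age = rep(0, p), beta_icv = rep(0, p),
    noise_sd = rep(1, p),
    loadings = list(cMDD = L, HC = matrix(0, p, 1)), seed = 31)
  co <- generate_cohort(spec)
  mean_block_r <- function(g) {
    r <- cor(co$volumes[co$participants$group == g, 1:10])
    mean(r[upper.tri(r)])
  }
  expect_gt(mean_block_r("cMDD"), mean_block_r("HC") + 0.2)
})

test_that("generated covariance converges to Lambda Lambda' + diag(noise^2)", {
  cat20 <- roi_catalog_tiny()
  p <- nrow(cat20)
  L <- scovnet:::.block_loadings(p, 4, within = 1.0, scale = rep(1, p))
  spec <- cohort_spec(
    cat20, n_per_group = c(HC = 2000),
    age_mean = c(HC = 21), age_sd = c(HC = 3),
    base_means = rep(500, p), beta_age = rep(0, p), beta_icv = rep(0, p),
    noise_sd = rep(1, p), loadings = list(HC = L), seed = 41)
  co <- generate_cohort(spec)
  S_emp <- cov(co$volumes)
  S_theory <- L %*% t(L) + diag(1, p)
  rel_frob <- norm(S_emp - S_theory, "F") / norm(S_theory, "F")
  expect_lt(rel_frob, 0.10)
})

test_that("residualization recovers and removes the planted covariate slopes", {
  cat20 <- roi_catalog_tiny()
  p <- nrow(cat20)
  beta_age <- rep(3.0, p)
  beta_icv <- rep(0.002, p)
  spec <- cohort_spec(
    cat20, n_per_group = c(HC = 500),
    age_mean = c(HC = 21), age_sd = c(HC = 4),
    base_means = rep(500, p), beta_age = beta_age, beta_icv = beta_icv,
    noise_sd = rep(1, p), loadings = list(HC = matrix(0, p, 1)), seed = 51)
  co <- generate_cohort(spec)
  rt <- residualize(co, "pooled_all")
  slopes <- rt$coefficients["age", ]
  expect_true(all(abs(slopes - 3.0) / 3.0 < 0.05))
  # and regressing out removes them: residual slope on age ~ 0
  for (j in c(1, 10)) {
    refit <- coef(lm(rt$residuals[, j] ~ rt$participants$age))[2]
    expect_lt(abs(refit), 1e-8)
  }
})

test_that("null_pair demands actually-null groups", {
  spec <- cohort_spec_null_tiny(seed = 61)
  co <- null_pair(spec, c("cMDD", "HC"))
  expect_setequal(unique(co$participants$group), c("cMDD", "HC"))
  expect_true(is_null_spec(spec, c("cMDD", "HC")))
  not_null <- cohort_spec_tiny(seed = 61)
  expect_error(null_pair(not_null, c("cMDD", "HC")), "not null")
  # degenerate size still runs
  small <- cohort_spec_null_tiny(seed = 62, n_per_group = c(cMDD = 3, HC = 3))
  co2 <- null_pair(small, c("cMDD", "HC"))
  expect_equal(nrow(co2$participants), 6L)
})

test_that("spec validation catches dimension and label errors", {
  cat20 <- roi_catalog_tiny()
  p <- nrow(cat20)
  expect_error(cohort_spec(
    cat20, n_per_group = c(HC = 10), age_mean = c(HC = 21),
    age_sd = c(HC = 3), base_means = rep(500, p), beta_age = rep(0, p),
    beta_icv = rep(0, p), noise_sd = rep(1, p),
    loadings = list(HC = matrix(0, p - 1, 1))), "rows")
  expect_error(cohort_spec(
    cat20, n_per_group = c(HC = 2), age_mean = c(HC = 21),
    age_sd = c(HC = 3), base_means = rep(500, p), beta_age = rep(0, p),
    beta_icv = rep(0, p), noise_sd = rep(1, p),
    loadings = list(HC = matrix(0, p, 1))), "more than 2")
  expect_error(cohort_spec(
    cat20, n_per_group = c(HC = 10), age_mean = c(HC = 21),
    age_sd = c(HC = 3), base_means = rep(500, p), beta_age = rep(0, p),
    beta_icv = rep(0, p), noise_sd = rep(1, p),
    loadings = list(HC = matrix(0, p, 1)),
    marker_effects = data.frame(roi = "NOPE", group = "HC", shift = 1)),
    "unknown ROI")
})

test_that("simulate_cohort writes files the loaders accept", {
  dir <- tempfile()
  spec <- cohort_spec_tiny(seed = 71)
  paths <- simulate_cohort(spec, dir)
  parts <- load_participants(paths$participants)
  vt <- load_volume_table(paths$volumes, spec$catalog)
  expect_equal(nrow(parts), 90L)
  expect_equal(dim(vt$volumes), c(90L, 20L))
  co <- generate_cohort(spec)
  expect_equal(vt$volumes, co$volumes, tolerance = 1e-9)
})
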