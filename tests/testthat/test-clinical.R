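clin_cohort <- function(seed) generate_cohort(cohort_spec_markers(seed))

test_that("MANCOVA: identical duplicated groups give lambda ~ 1, p ~ 1", {
  co <- generate_cohort(cohort_spec_tiny(seed = 31))
  keep <- co$participants$group == "HC"
  parts <- co$participants[keep, ]
  parts2 <- parts
  parts2$id <- paste0(parts$id, "_b")
  parts2$group <- "cMDD"
  vols <- co$volumes[keep, 1:5]   # few DVs so n > DV + covs + groups
  vols2 <- vols
  rownames(vols2) <- parts2$id
  co2 <- list(participants = as_participant_table(rbind(parts, parts2)),
              volumes = rbind(vols, vols2))
  m <- scn_mancova(co2)
  expect_gt(m$wilks_lambda, 0.97)
  expect_gt(m$p, 0.5)
})

test_that("MANCOVA Wilks lambda matches a from-scratch E/H eigendecomposition", {
  set.seed(32)
  n <- 60
  group <- rep(c("cMDD", "RD", "HC"), each = 20)
  age <- runif(n, 18, 40)
  icv <- runif(n, 1.3e6, 1.6e6)
  y1 <- 2 * age + 0.0005 * icv + rnorm(n, 0, 5) +
    ifelse(group == "cMDD", -4, 0)
  y2 <- -age + 0.0002 * icv + rnorm(n, 0, 5) + ifelse(group == "HC", 3, 0)
  Y <- cbind(y1, y2)
  parts <- as_participant_table(data.frame(
    id = sprintf("p%02d", 1:n), group = group,
    gender = rep(c("male", "female"), 30), age = age, icv = icv))
  rownames(Y) <- parts$id
  m <- scn_mancova(list(participants = parts, volumes = Y))

  # oracle: residualize Y and group dummies on [1, age, icv], then
  # lambda = det(E) / det(E + H)
  X0 <- cbind(1, age, icv)
  M0 <- diag(n) - X0 %*% solve(crossprod(X0)) %*% t(X0)
  G <- model.matrix(~ factor(group))[, -1]
  Yr <- M0 %*% Y
  Gr <- M0 %*% G
  H <- t(Yr) %*% Gr %*% solve(crossprod(Gr)) %*% t(Gr) %*% Yr
  E <- crossprod(Yr) - H
  lambda_oracle <- det(E) / det(E + H)
  expect_equal(m$wilks_lambda, lambda_oracle, tolerance = 1e-8)
  expect_equal(m$df_effect, 4)   # p * q = 2 DVs x 2 hypothesis df
  s <- sqrt((4 * 4 - 4) / (4 + 4 - 5))
  expect_equal(m$partial_eta_squared, 1 - lambda_oracle^(1 / s),
               tolerance = 1e-8)
})

test_that("MANCOVA refuses underdetermined designs with advice", {
  co <- generate_cohort(cohort_spec_tiny(seed = 33))  # n = 90, 20 DVs fine
  sub <- list(participants = co$participants[1:20, ],
              volumes = co$volumes[1:20, ])
  expect_error(scn_mancova(sub), "per-ROI ANCOVA")
})

test_that("per-ROI ANCOVA recovers trait and state marker signatures", {
  co <- clin_cohort(34)
  res <- per_roi_ancova(co)
  expect_equal(nrow(res), 20L)
  trait <- res[res$roi == "L_Pallidum", ]
  state <- res[res$roi == "R_Pallidum", ]
  # trait: both patient contrasts significant, patients similar
  expect_lt(trait$fdr_p, 0.05)
  expect_lt(trait$p_cMDD_HC, 0.05)
  expect_lt(trait$p_RD_HC, 0.05)
  expect_gt(trait$p_cMDD_RD, 0.05)
  # state (RD only): RD-HC significant, cMDD-HC not
  expect_lt(state$fdr_p, 0.05)
  expect_lt(state$p_RD_HC, 0.05)
  expect_gt(state$p_cMDD_HC, 0.05)
  # effect directions: decreased volumes in the affected groups
  expect_lt(trait$mean_cMDD, trait$mean_HC)
  expect_lt(state$mean_RD, state$mean_HC)
  # non-survivors carry no post-hoc p-values
  expect_true(all(is.na(res$p_cMDD_HC[res$fdr_p > 0.05])))
})

test_that("per-ROI ANCOVA stays quiet on null data", {
  spec <- cohort_spec_null_tiny(seed = 35,
                                n_per_group = c(cMDD = 60, RD = 60, HC = 60))
  hits <- sapply(1:10, function(i) {
    co <- generate_cohort(spec, seed = 100 + i)
    sum(per_roi_ancova(co)$fdr_p <= 0.05, na.rm = TRUE)
  })
  expect_lt(mean(hits > 0), 0.4)   # FDR: few datasets with any discovery
})

test_that("demographic battery computes the standard tests", {
  co <- clin_cohort(36)
  dt <- demographic_tests(co$participants)
  expect_true(all(c("gender", "age", "education", "rrs", "hamd17",
                    "illness_duration") %in% dt$variable))
  expect_equal(dt$test[dt$variable == "gender"], "chi-square")
  expect_equal(dt$df[dt$variable == "gender"], 2)
  # HAMD-17 separates patients from controls by construction
  expect_lt(dt$p[dt$variable == "hamd17"], 1e-6)

  # two identical groups: U = n1 n2 / 2 on average, H = 0 when all equal
  parts <- as_participant_table(data.frame(
    id = sprintf("p%02d", 1:40), group = rep(c("cMDD", "RD"), each = 20),
    gender = rep(c("male", "female"), 20), age = rep(21:40, 2),
    icv = rep(1.4e6, 40), hamd17 = rep(5, 40),
    illness_duration = rep(c(3, 7), 20)))
  dt2 <- demographic_tests(parts)
  kw <- dt2[dt2$variable == "hamd17", ]
  expect_equal(kw$statistic, 0, tolerance = 1e-12)
  mw <- dt2[dt2$variable == "illness_duration", ]
  expect_equal(mw$statistic, 20 * 20 / 2)
  expect_gt(mw$p, 0.9)
})

test_that("correlation methods follow the method map", {
  co <- clin_cohort(37)
  # exact linear: Pearson r = 1
  vols <- co$volumes
  vols[, "L_CA1"] <- 2 * co$participants$rrs + 1
  co_lin <- list(participants = co$participants, volumes = vols)
  res <- roi_psychometric_correlations(co_lin, "RD", rois = "L_CA1")
  pr <- res[res$field == "rrs", ]
  expect_equal(pr$estimate, 1, tolerance = 1e-9)
  # monotone nonlinear: Spearman 1, Pearson < 1
  vols[, "L_CA3"] <- exp(co$participants$hamd17 / 4 +
                           seq_len(nrow(vols)) * 1e-9)
  co_mono <- list(participants = co$participants, volumes = vols)
  res2 <- roi_psychometric_correlations(co_mono, "cMDD", rois = "L_CA3")
  # ties in the integer score keep rank correlation marginally below 1
  expect_gt(res2$estimate[res2$field == "hamd17"], 0.99)
  expect_lt(res2$estimate[res2$field == "rrs"],
            res2$estimate[res2$field == "hamd17"])
  # constant input named in the error
  vols[, "L_CA1"] <- 1
  co_flat <- list(participants = co$participants, volumes = vols)
  expect_error(roi_psychometric_correlations(co_flat, "RD", rois = "L_CA1"),
               "L_CA1")
})

test_that("correlation estimates have the expected sampling spread", {
  # bivariate normal with rho = 0.3 at the remitted-group size
  set.seed(38)
  cover <- replicate(60, {
    z <- matrix(rnorm(67 * 2), 67)
    x <- z[, 1]
    y <- 0.3 * z[, 1] + sqrt(1 - 0.09) * z[, 2]
    abs(cor(x, y) - 0.3) < 0.25
  })
  expect_gt(mean(cover), 0.9)
})
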