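# Volumetric and demographic statistics arm: omnibus MANCOVA, per-ROI ANCOVA
# with FDR and pairwise post-hoc contrasts, demographic group tests, and
# ROI-psychometric correlations.

.clin_frame <- function(cohort) {
  parts <- cohort$participants
  vols <- cohort$volumes[match(parts$id, rownames(cohort$volumes)), ,
                         drop = FALSE]
  list(parts = parts, vols = vols)
}

#' Omnibus MANCOVA on regional volumes
#'
#' Multivariate analysis of covariance of all ROI volumes on group, adjusting
#' for age and intracranial volume: Wilks' lambda for the group effect (SS of
#' group entered after the covariates), Rao's F approximation, and the
#' multivariate partial eta-squared `1 - lambda^(1/s)` (convention recorded
#' in the result). Requires more participants than dependent variables +
#' covariates + groups; for the 100-ROI catalog this means n > 103, so small
#' cohorts are refused with a clear message (the per-ROI ANCOVA arm carries
#' those).
#'
#' @param cohort an `scn_cohort` (or list with `participants`, `volumes`).
#' @param covariates covariate column names in the participant table.
#' @return a `mancova_result`: list with `wilks_lambda`, `f_statistic`, `p`,
#'   `partial_eta_squared`, `df_effect`, `df_error`, `n`, and
#'   `eta_convention`.
#' @export
scn_mancova <- function(cohort, covariates = c("age", "icv")) {
  cf <- .clin_frame(cohort)
  n <- nrow(cf$vols); p <- ncol(cf$vols)
  g <- length(unique(cf$parts$group))
  if (n <= p + length(covariates) + g)
    .stop_class(sprintf(
      "MANCOVA needs n > DVs + covariates + groups (%d); got n = %d. Reduce the DV set or rely on the per-ROI ANCOVA arm.",
      p + length(covariates) + g, n), "scovnet_spec_error")
  dat <- data.frame(cf$parts[covariates], group = factor(cf$parts$group))
  fit <- stats::manova(cf$vols ~ age + icv + group, data = dat)
  sm <- summary(fit, test = "Wilks")$stats
  row <- sm["group", ]
  lambda <- row[["Wilks"]]
  q <- g - 1                                    # hypothesis df
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  structure(list(wilks_lambda = lambda,
                 f_statistic = row[["approx F"]],
                 p = row[["Pr(>F)"]],
                 partial_eta_squared = 1 - lambda^(1 / s),
                 df_effect = row[["num Df"]], df_error = row[["den Df"]],
                 n = n, eta_convention = "1 - lambda^(1/s), s = sqrt((p^2 q^2 - 4)/(p^2 + q^2 - 5))"),
            class = "mancova_result")
}

#' @export
print.mancova_result <- function(x, ...) {
  cat(sprintf("MANCOVA (group | age, icv): Wilks lambda = %.3f, F(%g, %g) = %.2f, p = %.3g, partial eta^2 = %.3f\n",
              x$wilks_lambda, x$df_effect, x$df_error, x$f_statistic, x$p,
              x$partial_eta_squared))
  invisible(x)
}

# Pairwise covariate-adjusted contrast p-value from a fitted lm with a group
# factor: t-test on the difference of group coefficients.
.contrast_p <- function(fit, lev, a, b) {
  cf <- coef(fit); V <- stats::vcov(fit)
  nm <- function(l) paste0("group", l)
  w <- rep(0, length(cf)); names(w) <- names(cf)
  if (nm(a) %in% names(cf)) w[nm(a)] <- 1
  if (nm(b) %in% names(cf)) w[nm(b)] <- -1
  est <- sum(w * cf)
  se <- sqrt(drop(t(w) %*% V %*% w))
  tval <- est / se
  2 * stats::pt(-abs(tval), df = fit$df.residual)
}

#' Per-ROI ANCOVA with FDR and pairwise post-hoc contrasts
#'
#' For each ROI: ANCOVA F for the group effect adjusting for age and ICV,
#' Benjamini-Hochberg FDR across ROIs, and — for FDR-surviving ROIs —
#' unadjusted pairwise covariate-adjusted t contrasts (cMDD-HC, RD-HC,
#' cMDD-RD). Group means and SDs of the raw volumes are reported alongside.
#'
#' @param cohort an `scn_cohort`.
#' @param covariates covariate column names.
#' @param q FDR level across ROIs (default 0.05).
#' @return data frame, one row per ROI: per-group `mean_*`/`sd_*`, `f`,
#'   `p`, `fdr_p`, `partial_eta_squared`, `p_cMDD_HC`, `p_RD_HC`,
#'   `p_cMDD_RD` (NA unless the ROI survives FDR).
#' @export
per_roi_ancova <- function(cohort, covariates = c("age", "icv"), q = 0.05) {
  cf <- .clin_frame(cohort)
  groups <- c("cMDD", "RD", "HC")
  present <- intersect(groups, unique(cf$parts$group))
  dat <- data.frame(cf$parts[covariates],
                    group = factor(cf$parts$group, levels = present))
  rois <- colnames(cf$vols)
  rows <- lapply(rois, function(roi) {
    dat$y <- cf$vols[, roi]
    fit <- stats::lm(y ~ age + icv + group, data = dat)
    an <- stats::anova(fit)            # sequential: group after covariates
    fval <- an["group", "F value"]
    pval <- an["group", "Pr(>F)"]
    eta <- an["group", "Sum Sq"] /
      (an["group", "Sum Sq"] + an["Residuals", "Sum Sq"])
    ms <- tapply(dat$y, dat$group, mean)
    sds <- tapply(dat$y, dat$group, stats::sd)
    out <- data.frame(roi = roi, f = fval, p = pval,
                      partial_eta_squared = eta)
    for (g in present) {
      out[[paste0("mean_", g)]] <- ms[[g]]
      out[[paste0("sd_", g)]] <- sds[[g]]
    }
    attr(out, "fit") <- fit
    out
  })
  res <- do.call(rbind, lapply(rows, function(r) r))
  fdr <- fdr_bh(res$p, q = q)
  res$fdr_p <- fdr$adjusted
  res$p_cMDD_HC <- res$p_RD_HC <- res$p_cMDD_RD <- NA_real_
  for (i in which(fdr$reject)) {
    fit <- attr(rows[[i]], "fit")
    if (all(c("cMDD", "HC") %in% present))
      res$p_cMDD_HC[i] <- .contrast_p(fit, present, "cMDD", "HC")
    if (all(c("RD", "HC") %in% present))
      res$p_RD_HC[i] <- .contrast_p(fit, present, "RD", "HC")
    if (all(c("cMDD", "RD") %in% present))
      res$p_cMDD_RD[i] <- .contrast_p(fit, present, "cMDD", "RD")
  }
  rownames(res) <- NULL
  res
}

#' Demographic and clinical group tests
#'
#' The standard battery: Pearson chi-square (no continuity correction) on the
#' gender x group table; one-way ANOVA for age, education and RRS;
#' Kruskal-Wallis for HAMD-17; Mann-Whitney U for illness duration between
#' the two patient groups.
#'
#' @param participants a `participant_table`.
#' @return data frame with `variable`, `test`, `statistic`, `df`, `p`.
#' @export
demographic_tests <- function(participants) {
  out <- list()
  tab <- table(participants$gender, participants$group)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    .stop_class("contingency table has an empty row/column", "scovnet_degenerate_error")
  ct <- stats::chisq.test(tab, correct = FALSE)
  out$gender <- data.frame(variable = "gender", test = "chi-square",
                           statistic = unname(ct$statistic),
                           df = unname(ct$parameter), p = ct$p.value)
  grp <- factor(participants$group)
  for (v in c("age", "education", "rrs")) {
    if (all(is.na(participants[[v]]))) next
    an <- stats::anova(stats::aov(participants[[v]] ~ grp))
    out[[v]] <- data.frame(variable = v, test = "anova",
                           statistic = an[1, "F value"],
                           df = an[1, "Df"], p = an[1, "Pr(>F)"])
  }
  if (!all(is.na(participants$hamd17))) {
    if (stats::sd(participants$hamd17, na.rm = TRUE) < 1e-12) {
      # all scores tied: H = 0 by definition (kruskal.test returns NaN)
      out$hamd17 <- data.frame(variable = "hamd17", test = "kruskal-wallis",
                               statistic = 0, df = nlevels(grp) - 1, p = 1)
    } else {
      kw <- stats::kruskal.test(participants$hamd17, grp)
      out$hamd17 <- data.frame(variable = "hamd17", test = "kruskal-wallis",
                               statistic = unname(kw$statistic),
                               df = unname(kw$parameter), p = kw$p.value)
    }
  }
  pat <- participants[participants$group %in% c("cMDD", "RD"), ]
  if (length(unique(pat$group)) == 2L &&
      !all(is.na(pat$illness_duration))) {
    mw <- stats::wilcox.test(illness_duration ~ group, data = pat,
                             exact = FALSE)
    out$duration <- data.frame(variable = "illness_duration",
                               test = "mann-whitney",
                               statistic = unname(mw$statistic),
                               df = NA_real_, p = mw$p.value)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ROI-psychometric correlations
#'
#' Correlates regional volumes with clinical scores within a group: Pearson
#' for RRS and illness remission, Spearman for HAMD-17 and illness duration
#' (the default method map), two-tailed p-values, pairwise deletion of
#' missing clinical values.
#'
#' @param cohort an `scn_cohort` (raw volumes) or a `residual_table`
#'   substituted as `volumes`.
#' @param group group label to analyze.
#' @param rois ROI names (default: all).
#' @param methods named character vector mapping clinical fields to
#'   `"pearson"` or `"spearman"`.
#' @return data frame with `roi`, `field`, `method`, `n`, `estimate`, `p`.
#' @export
roi_psychometric_correlations <- function(cohort, group,
    rois = NULL,
    methods = c(rrs = "pearson", illness_remission = "pearson",
                hamd17 = "spearman", illness_duration = "spearman")) {
  cf <- .clin_frame(cohort)
  keep <- cf$parts$group == group
  parts <- cf$parts[keep, , drop = FALSE]
  vols <- cf$vols[keep, , drop = FALSE]
  rois <- rois %||% colnames(vols)
  rows <- list()
  for (field in names(methods)) {
    y <- parts[[field]]
    ok <- !is.na(y)
    if (sum(ok) < 4L) next
    if (stats::sd(y[ok]) < 1e-12)
      .stop_class(paste0("constant clinical variable: ", field),
                  "scovnet_degenerate_error")
    for (roi in rois) {
      x <- vols[ok, roi]
      if (stats::sd(x) < 1e-12)
        .stop_class(paste0("constant ROI volume: ", roi),
                    "scovnet_degenerate_error")
      ctest <- suppressWarnings(stats::cor.test(x, y[ok],
                                                method = methods[[field]],
                                                exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, field = field, method = methods[[field]], n = sum(ok),
        estimate = unname(ctest$estimate), p = ctest$p.value)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
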