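# Covariate adjustment: per-ROI ordinary least squares of volume on
# [1, age, ICV]; all covariance networks are built on the residuals.

#' Regress age and intracranial volume out of regional volumes
#'
#' Fits, for every ROI, `volume ~ 1 + age + icv` by OLS over the chosen
#' fitting sample and returns the residuals. Covariates are mean-centered
#' before fitting (conditioning only; residuals are unaffected). For
#' `pooled_pair`, one regression is fitted over the two groups entering a
#' comparison — the default for permutation inference, since the adjustment
#' is then held fixed across relabelings and exchangeability under the null
#' is preserved. `per_group` and `pooled_all` are available for sensitivity
#' analysis.
#'
#' @param cohort an `scn_cohort`, or a list with `participants` (containing
#'   `id`, `group`, `age`, `icv`) and `volumes` (matrix, rownames = ids).
#' @param scope fitting sample: `"pooled_pair"` (requires `groups`),
#'   `"per_group"`, or `"pooled_all"`.
#' @param groups for `pooled_pair`, the two group labels to keep.
#' @return a `residual_table`: list with `residuals` (participants x ROI),
#'   `participants`, `coefficients` (3 x ROI: intercept, slope_age,
#'   slope_icv, on the centered scale), and `scope`.
#' @export
residualize <- function(cohort, scope = c("pooled_pair", "per_group",
                                          "pooled_all"), groups = NULL) {
  scope <- match.arg(scope)
  parts <- cohort$participants
  vols <- cohort$volumes
  vols <- vols[match(parts$id, rownames(vols)), , drop = FALSE]
  if (scope == "pooled_pair") {
    if (is.null(groups) || length(groups) != 2L)
      .stop_class("pooled_pair scope needs exactly two group labels",
                  "scovnet_spec_error")
    keep <- parts$group %in% groups
    parts <- parts[keep, , drop = FALSE]
    vols <- vols[keep, , drop = FALSE]
  }
  fit_one <- function(idx) {
    if (length(idx) < 4L)
      .stop_class("need at least 4 participants per fitting sample",
                  "scovnet_fit_error")
    age <- parts$age[idx] - mean(parts$age[idx])
    icv <- parts$icv[idx] - mean(parts$icv[idx])
    X <- cbind(intercept = 1, age = age, icv = icv)
    qx <- qr(X)
    if (qx$rank < 3L) {
      culprit <- c("age", "icv")[c(stats::sd(age), stats::sd(icv)) < 1e-12]
      .stop_class(paste0("rank-deficient covariate design",
                         if (length(culprit)) paste0(" (constant: ",
                           paste(culprit, collapse = ", "), ")")),
                  "scovnet_fit_error")
    }
    fit <- stats::lm.fit(X, vols[idx, , drop = FALSE])
    res <- as.matrix(fit$residuals)
    cf <- as.matrix(fit$coefficients)
    rownames(cf) <- c("intercept", "age", "icv")
    colnames(cf) <- colnames(vols)
    list(res = res, coef = cf)
  }
  if (scope == "per_group") {
    res <- vols * NA_real_
    coefs <- list()
    for (g in unique(parts$group)) {
      idx <- which(parts$group == g)
      f <- fit_one(idx)
      res[idx, ] <- f$res
      coefs[[g]] <- f$coef
    }
  } else {
    f <- fit_one(seq_len(nrow(parts)))
    res <- f$res
    coefs <- f$coef
  }
  dimnames(res) <- dimnames(vols)
  structure(list(residuals = res, participants = parts,
                 coefficients = coefs, scope = scope),
            class = "residual_table")
}

#' @export
print.residual_table <- function(x, ...) {
  cat(sprintf("<residual_table> %d participants x %d ROIs (scope: %s)\n",
              nrow(x$residuals), ncol(x$residuals), x$scope))
  invisible(x)
}
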