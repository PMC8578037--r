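# Synthetic cohort generator. Regional volumes follow the generative model the
# covariance analysis assumes:
#
#   vol[p, i] = base_mean[i] + marker_shift(group_p, i)
#               + beta_age[i] * (age_p - age_ref)
#               + beta_icv[i] * (icv_p - icv_ref)
#               + (Lambda_g f_p)[i] + eps[p, i]
#
# with factors f_p ~ N(0, diag(factor_sd^2)) and noise eps ~ N(0, noise_sd^2)
# independent. Group differences in SCN topology are planted through the
# group-specific loading matrices Lambda_g; volumetric marker effects are
# additive mean shifts that leave the covariance untouched, so the two arms of
# the analysis can be exercised independently.

#' Construct a synthetic cohort specification
#'
#' @param catalog an [roi_catalog()] (any size; `strict = FALSE` catalogs
#'   are accepted).
#' @param n_per_group named integer vector, e.g. `c(cMDD = 131, RD = 67,
#'   HC = 235)`; every count must exceed 2.
#' @param age_mean,age_sd named numeric vectors per group (years).
#' @param icv_mean,icv_sd intracranial volume distribution (mm^3).
#' @param base_means per-ROI mean volumes (mm^3), catalog order.
#' @param beta_age,beta_icv per-ROI covariate slopes (mm^3 per year, mm^3 per
#'   mm^3).
#' @param noise_sd per-ROI residual standard deviation (mm^3), all positive.
#' @param loadings named list, one `n_roi x n_factors` matrix per group.
#' @param factor_sd named list of per-factor standard deviations (default 1).
#' @param marker_effects data frame with columns `roi`, `group`, `shift`
#'   (mm^3), or `NULL`.
#' @param seed default integer seed used by [generate_cohort()].
#' @return a validated `cohort_spec`.
#' @export
cohort_spec <- function(catalog, n_per_group, age_mean, age_sd,
                        icv_mean = 1.45e6, icv_sd = 1.4e5,
                        base_means, beta_age, beta_icv, noise_sd,
                        loadings, factor_sd = NULL,
                        marker_effects = NULL, seed = 1L) {
  p <- nrow(catalog)
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups)))
    .stop_class("n_per_group must be a named vector", "scovnet_spec_error")
  if (any(n_per_group <= 2))
    .stop_class("every group needs more than 2 participants", "scovnet_spec_error")
  for (v in list(base_means, beta_age, beta_icv, noise_sd))
    if (length(v) != p)
      .stop_class("per-ROI vectors must match the catalog length", "scovnet_spec_error")
  if (any(noise_sd <= 0))
    .stop_class("noise_sd must be positive", "scovnet_spec_error")
  if (!all(groups %in% names(loadings)))
    .stop_class("loadings must name every group", "scovnet_spec_error")
  for (g in groups) {
    if (nrow(loadings[[g]]) != p)
      .stop_class(sprintf(
        "loading matrix for group %s has %d rows; catalog has %d ROIs",
        g, nrow(loadings[[g]]), p), "scovnet_spec_error")
  }
  if (is.null(factor_sd))
    factor_sd <- lapply(loadings, function(L) rep(1, ncol(L)))
  if (!is.null(marker_effects)) {
    stopifnot(all(c("roi", "group", "shift") %in% names(marker_effects)))
    bad <- setdiff(marker_effects$roi, catalog$roi_name)
    if (length(bad))
      .stop_class(paste0("marker_effects reference unknown ROI(s): ",
                         paste(bad, collapse = ", ")), "scovnet_spec_error")
  }
  structure(list(catalog = catalog, n_per_group = n_per_group,
                 age_mean = age_mean, age_sd = age_sd,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 base_means = base_means, beta_age = beta_age,
                 beta_icv = beta_icv, noise_sd = noise_sd,
                 loadings = loadings, factor_sd = factor_sd,
                 marker_effects = marker_effects, seed = seed),
            class = "cohort_spec")
}

#' Is a spec null (exchangeable) across the given groups?
#'
#' A spec is null for a set of groups when those groups share an identical
#' factor model and carry no marker effects, i.e. their volumes are drawn
#' from the same generative law.
#'
#' @param spec a `cohort_spec`.
#' @param groups group labels to compare (default: all).
#' @return `TRUE`/`FALSE`.
#' @export
is_null_spec <- function(spec, groups = names(spec$n_per_group)) {
  ref <- spec$loadings[[groups[1L]]]
  same <- all(vapply(groups[-1L], function(g)
    isTRUE(all.equal(spec$loadings[[g]], ref)) &&
      isTRUE(all.equal(spec$factor_sd[[g]], spec$factor_sd[[groups[1L]]])),
    TRUE))
  no_markers <- is.null(spec$marker_effects) ||
    !any(spec$marker_effects$group %in% groups &
           abs(spec$marker_effects$shift) > 0)
  same && no_markers
}

.rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) x[x < lower] <- stats::rnorm(sum(x < lower), mean, sd)
  x
}

.rlnorm_match <- function(n, mean, sd) {
  # lognormal with the requested arithmetic mean and sd (skewed durations)
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic cohort
#'
#' Draws demographics and regional volumes under `spec`'s generative model;
#' fully reproducible from the seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (default `spec$seed`).
#' @return an `scn_cohort`: list with `participants` (a `participant_table`),
#'   `volumes` (participants x ROI matrix, mm^3), and `catalog`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  set.seed(seed)
  p <- nrow(spec$catalog)
  groups <- names(spec$n_per_group)
  clin <- .clinical_profiles()
  parts <- list(); vols <- list()
  for (g in groups) {
    n <- spec$n_per_group[[g]]
    age <- .rnorm_trunc(n, spec$age_mean[[g]], spec$age_sd[[g]], 18)
    icv <- .rnorm_trunc(n, spec$icv_mean, spec$icv_sd, 1e5)
    prof <- clin[[g]] %||% clin[["HC"]]
    gender <- ifelse(stats::runif(n) < prof$p_female, "female", "male")
    education <- round(.rnorm_trunc(n, prof$edu[1], prof$edu[2], 9), 1)
    hamd <- pmax(0L, round(stats::rnorm(n, prof$hamd[1], prof$hamd[2])))
    rrs <- pmax(22L, round(stats::rnorm(n, prof$rrs[1], prof$rrs[2])))
    dur <- if (is.null(prof$duration)) rep(NA_real_, n) else
      round(.rlnorm_match(n, prof$duration[1], prof$duration[2]), 1)
    remis <- if (is.null(prof$remission)) rep(NA_real_, n) else
      round(.rlnorm_match(n, prof$remission[1], prof$remission[2]), 1)

    L <- spec$loadings[[g]]
    fsd <- spec$factor_sd[[g]]
    f <- matrix(stats::rnorm(n * ncol(L)), n) %*% diag(fsd, ncol(L))
    eps <- matrix(stats::rnorm(n * p), n) %*% diag(spec$noise_sd, p)
    shift <- rep(0, p)
    if (!is.null(spec$marker_effects)) {
      me <- spec$marker_effects[spec$marker_effects$group == g, , drop = FALSE]
      if (nrow(me))
        shift[match(me$roi, spec$catalog$roi_name)] <- me$shift
    }
    v <- matrix(rep(spec$base_means + shift, each = n), n) +
      outer(age - spec$age_mean[[g]], spec$beta_age) +
      outer(icv - spec$icv_mean, spec$beta_icv) +
      f %*% t(L) + eps
    v <- pmax(v, 1)          # volumes are physical; tail draws below 1 mm^3
    colnames(v) <- spec$catalog$roi_name
    ids <- sprintf("%s_%03d", g, seq_len(n))
    rownames(v) <- ids
    parts[[g]] <- data.frame(id = ids, group = g, gender = gender,
                             age = age, education = education, icv = icv,
                             hamd17 = hamd, rrs = rrs,
                             illness_duration = dur,
                             illness_remission = remis,
                             stringsAsFactors = FALSE)
    vols[[g]] <- v
  }
  participants <- as_participant_table(do.call(rbind, parts))
  rownames(participants) <- NULL
  structure(list(participants = participants,
                 volumes = do.call(rbind, vols),
                 catalog = spec$catalog),
            class = "scn_cohort")
}

# Clinical score profiles per group: mean/sd of the standard instruments
# (HAMD-17 depression severity, RRS rumination), education in years, illness
# duration/remission in months, and the female fraction.
.clinical_profiles <- function() list(
  cMDD = list(p_female = 72 / 131, edu = c(14.00, 2.22), hamd = c(22.45, 4.88),
              rrs = c(58.29, 11.14), duration = c(9.46, 12.13),
              remission = NULL),
  RD = list(p_female = 38 / 67, edu = c(14.52, 2.22), hamd = c(3.72, 2.93),
            rrs = c(44.84, 10.19), duration = c(13.77, 8.98),
            remission = c(5.56, 3.63)),
  HC = list(p_female = 122 / 235, edu = c(14.25, 0.82), hamd = c(2.12, 2.31),
            rrs = c(43.95, 8.76), duration = NULL, remission = NULL))

#' Generate a matched null pair of groups
#'
#' Both groups are drawn from the identical generative law, so any downstream
#' two-group test is exercised under its null hypothesis (used for type-I
#' error calibration of the permutation inference).
#'
#' @param spec a [cohort_spec()] that is null for `groups` (see
#'   [is_null_spec()]).
#' @param groups the two group labels.
#' @param seed integer seed.
#' @return an `scn_cohort` restricted to the two groups.
#' @export
null_pair <- function(spec, groups, seed = spec$seed) {
  stopifnot(length(groups) == 2L)
  if (!is_null_spec(spec, groups))
    .stop_class("spec is not null for the requested groups", "scovnet_spec_error")
  sub <- spec
  sub$n_per_group <- spec$n_per_group[groups]
  sub$age_mean <- spec$age_mean[groups]
  sub$age_sd <- spec$age_sd[groups]
  generate_cohort(sub, seed = seed)
}

# ---- loading-matrix builders ------------------------------------------------

# Block factors: n_blocks factors, each loading `within` on its own block.
# `global` adds one factor loading on every ROI (across-block shortcuts);
# `chain` adds bridge factors tying the tail of block b to the head of block
# b+1 (local-only coupling -> lattice-like long-path topology).
.block_loadings <- function(n_roi, n_blocks, within, global = 0, chain = 0,
                            scale = rep(1, n_roi)) {
  block <- sort(rep(seq_len(n_blocks), length.out = n_roi))
  L <- matrix(0, n_roi, n_blocks)
  for (b in seq_len(n_blocks)) L[block == b, b] <- within
  if (global > 0) L <- cbind(L, rep(global, n_roi))
  if (chain > 0 && n_blocks > 1) {
    for (b in seq_len(n_blocks - 1L)) {
      idx_a <- which(block == b)
      idx_b <- which(block == b + 1L)
      half_a <- idx_a[idx_a > stats::quantile(idx_a, 0.5)]
      half_b <- idx_b[idx_b <= stats::quantile(idx_b, 0.5)]
      col <- rep(0, n_roi)
      col[c(half_a, half_b)] <- chain
      L <- cbind(L, col)
    }
  }
  L * scale
}

# Banded ring of small modules: block factors (loading w0) plus, for each
# band distance d, factors coupling block b to block b+d around the ring
# (loading wb[d]). Covariance decays with ring distance, so the thresholded
# network is an elongated module-ring: long characteristic path, high
# normalized path length, reduced small-worldness.
.band_loadings <- function(n_roi, n_blocks, w0, wb, scale = rep(1, n_roi)) {
  blk <- sort(rep(seq_len(n_blocks), length.out = n_roi))
  L <- matrix(0, n_roi, 0)
  for (b in seq_len(n_blocks)) {
    col <- rep(0, n_roi); col[blk == b] <- w0
    L <- cbind(L, col)
  }
  for (d in seq_along(wb)) {
    if (wb[d] <= 0) next
    for (b in seq_len(n_blocks)) {
      col <- rep(0, n_roi)
      col[blk == b | blk == ((b + d - 1L) %% n_blocks) + 1L] <- wb[d]
      L <- cbind(L, col)
    }
  }
  L * scale
}

# Smooth distance-decay ring: one factor per ROI with a Gaussian loading
# profile of width tau over ring distance (truncated at 2.5 tau). The
# induced covariance decays smoothly with ring distance, so nearly every
# pair carries planted signal and the thresholded network is a thick ring
# band at every analyzed density: long characteristic paths, high normalized
# path length, reduced small-worldness.
.gauss_ring_loadings <- function(n_roi, tau, w, scale = rep(1, n_roi)) {
  L <- matrix(0, n_roi, n_roi)
  for (j in seq_len(n_roi)) {
    d <- pmin(abs(seq_len(n_roi) - j), n_roi - abs(seq_len(n_roi) - j))
    prof <- exp(-d^2 / (2 * tau^2))
    prof[d > 2.5 * tau] <- 0
    L[, j] <- w * prof
  }
  L * scale
}

# Long-range shortcut factors: each row of `pairs` is a 2-ROI factor with
# loading w, planting a strong distant correlation (small-world shortcuts).
.shortcut_loadings <- function(n_roi, pairs, w, scale = rep(1, n_roi)) {
  L <- matrix(0, n_roi, nrow(pairs))
  for (j in seq_len(nrow(pairs))) L[pairs[j, ], j] <- w
  L * scale
}

# Deterministic spread of k long-range pairs between the two halves of the
# catalog (the multiplier 7 is coprime with 50, so targets never repeat).
.shortcut_pairs <- function(n_roi, k) {
  half <- n_roi %/% 2L
  i <- seq_len(k)
  cbind(i, half + ((7L * i) %% half) + 1L)
}

.default_base_means <- function(catalog) {
  base <- c(basal_ganglia = 2500, amygdala = 200, hippocampus = 300,
            thalamus = 400)
  b <- base[catalog$structure_group]
  # deterministic per-ROI spread so ROIs are distinguishable
  b * (0.6 + 0.8 * (seq_len(nrow(catalog)) %% 7) / 7)
}

#' Shipped cohort specifications
#'
#' `cohort_spec_paperlike()` emulates the reference study design: three
#' groups of 131/67/235 over the full 100-ROI catalog and Table-like
#' volumetric marker shifts (bilateral pallidum, PuA/VLa/VLp thalamic
#' nuclei). Covariance structure differs by group: controls (HC) combine
#' five strongly clustered modules with 30 long-range shortcut correlations
#' — a small-world covariance geometry (short paths, high sigma); currently
#' depressed patients (cMDD) carry a smooth distance-decay ring whose
#' covariance falls off with ring distance — an elongated geometry whose
#' thresholded networks have longer characteristic paths and higher
#' normalized path length, hence reduced small-worldness; remitted patients
#' (RD) are the decay ring plus a reduced shortcut set (intermediate).
#' `cohort_spec_tiny()` is a scaled version on the 20-ROI catalog with
#' 30/30/30 participants for fast tests; `cohort_spec_paperlike_tiny()`
#' keeps the 20-ROI catalog but the study's group sizes.
#' `cohort_spec_null_tiny()` uses one shared factor model for all groups and
#' no marker effects (type-I-error calibration).
#' `cohort_spec_markers()` plants pure mean-shift markers (no covariance
#' differences) at the study's group sizes on the 20-ROI catalog: a trait
#' marker (-0.5 SD in both patient groups, left pallidum) and a state marker
#' (-0.6 SD in RD only, right pallidum).
#'
#' @param seed default seed carried by the spec.
#' @return a [cohort_spec()].
#' @export
cohort_spec_paperlike <- function(seed = 1L) {
  cat100 <- roi_catalog()
  p <- nrow(cat100)
  base <- .default_base_means(cat100)
  s <- 0.10 * base                       # per-ROI signal/noise scale
  sc_pairs <- .shortcut_pairs(p, 30)
  load_hc <- cbind(.block_loadings(p, 5, within = 1.1, scale = s),
                   .shortcut_loadings(p, sc_pairs, 1.3, scale = s))
  load_cmdd <- .gauss_ring_loadings(p, tau = 8, w = 0.35, scale = s)
  load_rd <- cbind(.gauss_ring_loadings(p, tau = 8, w = 0.35, scale = s),
                   .shortcut_loadings(p, sc_pairs[1:12, , drop = FALSE],
                                      1.0, scale = s))
  me <- data.frame(
    roi = c("L_Pallidum", "L_Pallidum", "L_PuA", "L_PuA",
            "R_Pallidum", "R_VLa", "R_VLp"),
    group = c("cMDD", "RD", "cMDD", "RD", "RD", "RD", "RD"),
    shift = c(-126, -164, -3.9, -4.3, -133, -11, -10))
  cohort_spec(cat100,
              n_per_group = c(cMDD = 131, RD = 67, HC = 235),
              age_mean = c(cMDD = 21.77, RD = 21.70, HC = 21.35),
              age_sd = c(cMDD = 4.01, RD = 3.77, HC = 2.91),
              base_means = base, beta_age = -0.004 * base,
              beta_icv = base / 1.45e6, noise_sd = s,
              loadings = list(cMDD = load_cmdd, RD = load_rd, HC = load_hc),
              marker_effects = me, seed = seed)
}

#' @rdname cohort_spec_paperlike
#' @export
cohort_spec_tiny <- function(seed = 1L) {
  cat20 <- roi_catalog_tiny()
  p <- nrow(cat20)
  base <- .default_base_means(cat20)
  s <- 0.10 * base
  cohort_spec(cat20,
              n_per_group = c(cMDD = 30, RD = 30, HC = 30),
              age_mean = c(cMDD = 21.77, RD = 21.70, HC = 21.35),
              age_sd = c(cMDD = 4.01, RD = 3.77, HC = 2.91),
              base_means = base, beta_age = -0.004 * base,
              beta_icv = base / 1.45e6, noise_sd = s,
              loadings = list(
                cMDD = .gauss_ring_loadings(p, tau = 2, w = 0.55, scale = s),
                RD = cbind(.gauss_ring_loadings(p, tau = 2, w = 0.55,
                                                scale = s),
                           .shortcut_loadings(p, .shortcut_pairs(p, 3), 1.0,
                                              scale = s)),
                HC = cbind(.block_loadings(p, 4, within = 1.1, scale = s),
                           .shortcut_loadings(p, .shortcut_pairs(p, 5), 1.3,
                                              scale = s))),
              seed = seed)
}

#' @rdname cohort_spec_paperlike
#' @export
cohort_spec_paperlike_tiny <- function(seed = 1L) {
  spec <- cohort_spec_tiny(seed)
  spec$n_per_group <- c(cMDD = 131, RD = 67, HC = 235)
  spec
}

#' @rdname cohort_spec_paperlike
#' @param n_per_group group sizes for the null pair (calibration default
#'   40/40).
#' @export
cohort_spec_null_tiny <- function(seed = 1L,
                                  n_per_group = c(cMDD = 40, HC = 40)) {
  cat20 <- roi_catalog_tiny()
  p <- nrow(cat20)
  base <- .default_base_means(cat20)
  s <- 0.10 * base
  shared <- .block_loadings(p, 4, within = 1.0, global = 0.45, scale = s)
  loads <- stats::setNames(rep(list(shared), length(n_per_group)),
                           names(n_per_group))
  cohort_spec(cat20, n_per_group = n_per_group,
              age_mean = stats::setNames(rep(21.5, length(n_per_group)),
                                         names(n_per_group)),
              age_sd = stats::setNames(rep(3.5, length(n_per_group)),
                                       names(n_per_group)),
              base_means = base, beta_age = -0.004 * base,
              beta_icv = base / 1.45e6, noise_sd = s,
              loadings = loads, seed = seed)
}

#' @rdname cohort_spec_paperlike
#' @export
cohort_spec_markers <- function(seed = 1L) {
  cat20 <- roi_catalog_tiny()
  p <- nrow(cat20)
  base <- .default_base_means(cat20)
  s <- 0.10 * base
  zero <- stats::setNames(rep(list(matrix(0, p, 1)), 3), c("cMDD", "RD", "HC"))
  trait_roi <- "L_Pallidum"; state_roi <- "R_Pallidum"
  sd_trait <- s[match(trait_roi, cat20$roi_name)]
  sd_state <- s[match(state_roi, cat20$roi_name)]
  me <- data.frame(
    roi = c(trait_roi, trait_roi, state_roi),
    group = c("cMDD", "RD", "RD"),
    shift = c(-0.5 * sd_trait, -0.5 * sd_trait, -0.6 * sd_state))
  cohort_spec(cat20,
              n_per_group = c(cMDD = 131, RD = 67, HC = 235),
              age_mean = c(cMDD = 21.77, RD = 21.70, HC = 21.35),
              age_sd = c(cMDD = 4.01, RD = 3.77, HC = 2.91),
              base_means = base, beta_age = -0.004 * base,
              beta_icv = base / 1.45e6, noise_sd = s,
              loadings = zero, marker_effects = me, seed = seed)
}

#' Read / write a cohort specification as YAML
#'
#' Loading matrices are stored row-wise; the catalog travels inside the file,
#' so a spec file is self-contained.
#'
#' @param spec a [cohort_spec()].
#' @param path YAML file path.
#' @return `write_cohort_spec()` returns the path invisibly;
#'   `read_cohort_spec()` returns a validated `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  doc <- list(
    catalog = lapply(seq_len(nrow(spec$catalog)), function(i)
      as.list(spec$catalog[i, ])),
    n_per_group = as.list(spec$n_per_group),
    age_mean = as.list(spec$age_mean), age_sd = as.list(spec$age_sd),
    icv_mean = spec$icv_mean, icv_sd = spec$icv_sd,
    base_means = spec$base_means, beta_age = spec$beta_age,
    beta_icv = spec$beta_icv, noise_sd = spec$noise_sd,
    loadings = lapply(spec$loadings, function(L)
      lapply(seq_len(nrow(L)), function(i) unname(L[i, ]))),
    factor_sd = lapply(spec$factor_sd, as.numeric),
    marker_effects = if (is.null(spec$marker_effects)) NULL else
      lapply(seq_len(nrow(spec$marker_effects)), function(i)
        as.list(spec$marker_effects[i, ])),
    seed = spec$seed)
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  catalog <- do.call(rbind, lapply(doc$catalog, as.data.frame))
  catalog <- structure(catalog, class = c("roi_catalog", "data.frame"))
  validate_roi_catalog(catalog, strict = nrow(catalog) == 100L)
  loadings <- lapply(doc$loadings, function(rows)
    do.call(rbind, lapply(rows, as.numeric)))
  me <- if (is.null(doc$marker_effects)) NULL else
    do.call(rbind, lapply(doc$marker_effects, as.data.frame))
  cohort_spec(catalog,
              n_per_group = unlist(doc$n_per_group),
              age_mean = unlist(doc$age_mean), age_sd = unlist(doc$age_sd),
              icv_mean = doc$icv_mean, icv_sd = doc$icv_sd,
              base_means = as.numeric(doc$base_means),
              beta_age = as.numeric(doc$beta_age),
              beta_icv = as.numeric(doc$beta_icv),
              noise_sd = as.numeric(doc$noise_sd),
              loadings = loadings,
              factor_sd = lapply(doc$factor_sd, as.numeric),
              marker_effects = me, seed = doc$seed)
}

#' Write a simulated cohort to disk
#'
#' Writes `participants.tsv` and `volumes.tsv` (consumable by
#' [load_participants()] / [load_volume_table()]) into `dir`.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisible named list of the written paths.
#' @export
simulate_cohort <- function(spec, dir, seed = spec$seed) {
  cohort <- generate_cohort(spec, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pp <- file.path(dir, "participants.tsv")
  vp <- file.path(dir, "volumes.tsv")
  write_participants(cohort$participants, pp)
  df <- data.frame(id = rownames(cohort$volumes), cohort$volumes,
                   check.names = FALSE)
  utils::write.table(df, vp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(participants = pp, volumes = vp))
}
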