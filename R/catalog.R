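#' The subcortical ROI catalog
#'
#' The analysis operates on a fixed catalog of 100 subcortical gray-matter
#' regions: per hemisphere, 4 basal-ganglia structures (caudate, putamen,
#' accumbens, pallidum), 9 amygdaloid subnuclei, 12 hippocampal subfield rows
#' and 25 thalamic nuclei, following the FreeSurfer 7 subfield atlases. The
#' catalog ships as an editable TSV (`inst/extdata/roi_catalog.tsv`); the
#' per-structure counts are enforced on load so a locally edited name list
#' keeps the topology of the analysis intact.
#'
#' @param path path to a catalog TSV with columns `roi_name`, `hemisphere`
#'   (`L`/`R`) and `structure_group`; defaults to the shipped catalog.
#' @param strict enforce the 4/9/12/25-per-hemisphere, 100-total cardinality
#'   (default `TRUE`). Reduced catalogs (e.g. for fast simulation) set this
#'   to `FALSE`.
#' @return a `roi_catalog` data frame with columns `roi_name`, `hemisphere`,
#'   `structure_group`.
#' @examples
#' cat100 <- roi_catalog()
#' nrow(cat100)            # 100
#' table(cat100$structure_group)
#' @export
roi_catalog <- function(path = system.file("extdata", "roi_catalog.tsv",
                                           package = "scovnet"),
                        strict = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("roi_name", "hemisphere", "structure_group")
  if (!all(need %in% names(df)))
    .stop_class(paste0("catalog file must have columns: ",
                       paste(need, collapse = ", ")), "scovnet_schema_error")
  df <- df[, need]
  validate_roi_catalog(df, strict = strict)
  structure(df, class = c("roi_catalog", "data.frame"))
}

#' Validate an ROI catalog
#'
#' @param catalog a data frame as returned by [roi_catalog()].
#' @param strict enforce the full 100-ROI cardinality.
#' @return the catalog, invisibly; errors describe any violation.
#' @export
validate_roi_catalog <- function(catalog, strict = TRUE) {
  if (anyDuplicated(catalog$roi_name))
    .stop_class("duplicate ROI names in catalog", "scovnet_schema_error")
  if (!all(catalog$hemisphere %in% c("L", "R")))
    .stop_class("hemisphere must be 'L' or 'R'", "scovnet_schema_error")
  groups <- c("basal_ganglia", "amygdala", "hippocampus", "thalamus")
  if (!all(catalog$structure_group %in% groups))
    .stop_class(paste0("structure_group must be one of: ",
                       paste(groups, collapse = ", ")), "scovnet_schema_error")
  if (strict) {
    expected <- c(basal_ganglia = 4L, amygdala = 9L, hippocampus = 12L,
                  thalamus = 25L)
    for (h in c("L", "R")) {
      tab <- table(catalog$structure_group[catalog$hemisphere == h])
      for (g in names(expected)) {
        n <- if (g %in% names(tab)) tab[[g]] else 0L
        if (n != expected[[g]])
          .stop_class(sprintf(
            "hemisphere %s has %d %s ROIs, expected %d", h, n, g,
            expected[[g]]), "scovnet_schema_error")
      }
    }
    if (nrow(catalog) != 100L)
      .stop_class("catalog must have exactly 100 entries", "scovnet_schema_error")
  }
  invisible(catalog)
}

#' A reduced 20-ROI catalog for fast simulation and tests
#'
#' Takes, per hemisphere, 2 basal-ganglia, 2 amygdaloid, 3 hippocampal and
#' 3 thalamic regions from the full catalog (the pallidum and PuA — the
#' catalog's marker regions — are always included). Cardinality checks are
#' relaxed.
#'
#' @return a `roi_catalog` data frame with 20 rows.
#' @export
roi_catalog_tiny <- function() {
  full <- roi_catalog()
  keep <- c("Caudate", "Pallidum",                       # basal ganglia
            "Lateral_nucleus", "Basal_nucleus",          # amygdala
            "Subiculum", "CA1", "CA3",                   # hippocampus
            "VLa", "VLp", "PuA")                         # thalamus
  sel <- full[sub("^[LR]_", "", full$roi_name) %in% keep, ]
  rownames(sel) <- NULL
  validate_roi_catalog(sel, strict = FALSE)
  structure(sel, class = c("roi_catalog", "data.frame"))
}
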