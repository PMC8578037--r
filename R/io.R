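# Tabular input/output: participant tables, wide ROI-volume tables in the
# asegstats2table dialect, adjacency matrices, networks, and result documents.

.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.norm_colname <- function(x) {
  x <- tolower(gsub("[-. ()]+", "_", x))
  x <- sub("^left_", "l_", x)
  x <- sub("^right_", "r_", x)
  sub("_+$", "", x)
}

#' Load a participant table
#'
#' Reads a comma- or tab-delimited participant table with required columns
#' `id`, `group`, `gender`, `age`, `icv` and optional clinical columns
#' `education`, `hamd17`, `rrs`, `illness_duration`, `illness_remission`.
#' Optional columns that are absent stay absent (reported `NA`), never zero.
#'
#' @param path file path.
#' @return a `participant_table` data frame, one row per participant.
#' @export
load_participants <- function(path) {
  df <- .read_delim_auto(path)
  names(df) <- .norm_colname(names(df))
  as_participant_table(df)
}

#' Coerce and validate a participant data frame
#'
#' @param df data frame with at least `id`, `group`, `gender`, `age`, `icv`.
#' @return a validated `participant_table`.
#' @export
as_participant_table <- function(df) {
  required <- c("id", "group", "gender", "age", "icv")
  missing <- setdiff(required, names(df))
  if (length(missing))
    .stop_class(paste0("participant table missing column(s): ",
                       paste(missing, collapse = ", ")), "scovnet_schema_error")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    .stop_class("duplicate participant IDs", "scovnet_integrity_error")
  bad <- setdiff(unique(df$group), c("cMDD", "RD", "HC"))
  if (length(bad))
    .stop_class(paste0("unknown group label(s): ", paste(bad, collapse = ", "),
                       " (expected cMDD, RD, HC)"), "scovnet_validation_error")
  if (!all(df$gender %in% c("male", "female")))
    .stop_class("gender must be 'male' or 'female'", "scovnet_validation_error")
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    .stop_class("age must be positive", "scovnet_validation_error")
  if (any(!is.finite(df$icv)) || any(df$icv <= 0))
    .stop_class("icv must be positive", "scovnet_validation_error")
  optional <- c("education", "hamd17", "rrs", "illness_duration",
                "illness_remission")
  for (col in optional) if (!col %in% names(df)) df[[col]] <- NA_real_
  if (any(df$hamd17 < 0, na.rm = TRUE))
    .stop_class("hamd17 must be non-negative", "scovnet_validation_error")
  structure(df, class = c("participant_table", "data.frame"))
}

#' Load a wide ROI-volume table
#'
#' Reads an asegstats2table-style wide table (rows = participants, one ID
#' column plus one column per catalog ROI, volumes in mm^3). Columns are
#' matched to the catalog case-insensitively after punctuation folding and an
#' alias map for FreeSurfer spellings, then reordered to catalog order. Rows
#' with any missing or non-positive volume are dropped with a report
#' (correlation matrices need complete columns); catalog ROIs without a
#' matching column are a schema error that names them.
#'
#' @param path file path (TSV or CSV with a header row).
#' @param catalog an [roi_catalog()].
#' @param aliases named character vector or YAML file path mapping input
#'   column spellings to catalog names; defaults to the shipped FreeSurfer
#'   alias map.
#' @param id_col name of the ID column; by default the first column whose
#'   normalized name is `id`, `subject`, or `measure_volume`, else column 1.
#' @return an `roi_volume_table`: list with `ids` (character), `volumes`
#'   (numeric matrix, rownames = ids, colnames = catalog order), `catalog`,
#'   and `dropped` (data frame reporting removed rows).
#' @export
load_volume_table <- function(path, catalog,
                              aliases = system.file("extdata",
                                "freesurfer_aliases.yaml", package = "scovnet"),
                              id_col = NULL) {
  df <- .read_delim_auto(path)
  if (is.character(aliases) && length(aliases) == 1L && file.exists(aliases))
    aliases <- unlist(yaml::read_yaml(aliases))
  aliases <- aliases %||% character()

  raw_names <- names(df)
  mapped <- raw_names
  hit <- match(raw_names, names(aliases))
  mapped[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  norm <- .norm_colname(mapped)
  cat_norm <- .norm_colname(catalog$roi_name)

  if (is.null(id_col)) {
    cand <- which(norm %in% c("id", "subject", "measure_volume"))
    id_idx <- if (length(cand)) cand[1L] else 1L
  } else {
    id_idx <- match(.norm_colname(id_col), norm)
    if (is.na(id_idx))
      .stop_class(paste0("ID column not found: ", id_col), "scovnet_schema_error")
  }
  ids <- as.character(df[[id_idx]])
  if (anyDuplicated(ids))
    .stop_class("duplicate participant IDs in volume table",
                "scovnet_integrity_error")

  pos <- match(cat_norm, norm)
  if (anyNA(pos))
    .stop_class(paste0("volume table is missing catalog ROI column(s): ",
                       paste(catalog$roi_name[is.na(pos)], collapse = ", ")),
                "scovnet_schema_error")
  vol <- df[, pos, drop = FALSE]
  for (j in seq_along(vol)) {
    v <- vol[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "")
      if (length(bad))
        .stop_class(sprintf("non-numeric volume at row %d, column '%s'",
                            bad[1L], catalog$roi_name[j]),
                    "scovnet_parse_error")
      v <- vn
    }
    vol[[j]] <- v
  }
  vol <- as.matrix(vol)
  dimnames(vol) <- list(ids, catalog$roi_name)

  incomplete <- !stats::complete.cases(vol) | apply(vol, 1L, function(r)
    any(r <= 0, na.rm = TRUE))
  dropped <- data.frame(id = ids[incomplete],
                        n_missing = rowSums(is.na(vol[incomplete, , drop = FALSE])))
  if (any(incomplete)) {
    warning(sprintf("dropped %d participant(s) with missing/non-positive volumes: %s",
                    sum(incomplete), paste(dropped$id, collapse = ", ")))
    vol <- vol[!incomplete, , drop = FALSE]
    ids <- ids[!incomplete]
  }
  structure(list(ids = ids, volumes = vol, catalog = catalog,
                 dropped = dropped),
            class = "roi_volume_table")
}

#' @export
print.roi_volume_table <- function(x, ...) {
  cat(sprintf("<roi_volume_table> %d participants x %d ROIs\n",
              nrow(x$volumes), ncol(x$volumes)))
  invisible(x)
}

#' Write a participant table or ROI-volume table as TSV
#'
#' `write_participants()` and `write_volume_table()` round-trip with
#' [load_participants()] / [load_volume_table()].
#'
#' @param x object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
write_volume_table <- function(x, path) {
  df <- data.frame(id = x$ids, x$volumes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a binary adjacency matrix as TSV
#'
#' @param net a `binary_network` (or bare 0/1 matrix with dimnames).
#' @param path file path.
#' @return the path (write) or the 0/1 matrix with dimnames (read).
#' @export
write_adjacency <- function(net, path) {
  A <- if (inherits(net, "binary_network")) net$adjacency else net
  df <- data.frame(roi = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(A) <- "integer"
  rownames(A) <- df[[1L]]
  A
}

#' Export a network as GraphML and edge list
#'
#' Node labels are the ROI names; the edge list has columns `from`, `to`.
#'
#' @param net a `binary_network`.
#' @param graphml_path,edgelist_path output paths (`NULL` to skip either).
#' @return invisible list of written paths.
#' @export
write_network <- function(net, graphml_path = NULL, edgelist_path = NULL) {
  g <- as_igraph(net)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edgelist_path)) {
    el <- igraph::as_edgelist(g, names = TRUE)
    utils::write.table(data.frame(from = el[, 1], to = el[, 2]),
                       edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(graphml = graphml_path, edgelist = edgelist_path))
}

#' Write pipeline results
#'
#' Tabular results (metric curves, comparison tables) are written as TSV;
#' structured results (permutation results, run bundles) as JSON. Dispatches
#' on class.
#'
#' @param results a result object produced by the pipeline.
#' @param path output file path (`.tsv` or `.json` decides the format for
#'   data frames; lists always go to JSON).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.data.frame(results) && !grepl("[.]json$", path)) {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(.jsonable(results), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}

# strip heavyweight members (igraph handles, matrices kept as-is serialize fine)
.jsonable <- function(x) {
  if (inherits(x, "igraph")) return(NULL)
  if (is.list(x)) {
    x <- x[!vapply(x, inherits, TRUE, what = "igraph")]
    lapply(x, .jsonable)
  } else x
}
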