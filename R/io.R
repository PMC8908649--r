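# Plain-text interchange: subjects table CSV, per-subject time-series
# CSV, connectivity matrices, edge lists with JSON sidecars.

subjects_schema <- c("subject_id", "pvh", "dwmh", "fazekas_total", "group",
                     "wmh_volume_ml", "age", "sex", "education_years",
                     "moca", "mmse", "timeseries_file")

#' Write a cohort to a directory
#'
#' Emits one `<subject_id>_timeseries.csv` per subject (T rows x N
#' labeled columns) plus `subjects.csv` and `node_labels.txt`; the file
#' set round-trips losslessly through [read_subjects()].
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param directory output directory (created if absent).
#' @return Invisibly, the path to the subjects table.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "cohort")) stop_wmhnet("expected a cohort")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop_wmhnet("cannot create directory: ", directory)
  writeLines(cohort$node_labels, file.path(directory, "node_labels.txt"))
  tab <- cohort$subjects
  tsf <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    id <- tab$subject_id[i]
    tsf[i] <- paste0(id, "_timeseries.csv")
    m <- cohort$timeseries[[id]]
    colnames(m) <- cohort$node_labels
    write.csv(as.data.frame(m), file.path(directory, tsf[i]),
              row.names = FALSE, quote = FALSE)
  }
  tab$timeseries_file <- tsf
  if (nrow(tab) == 0) tab <- empty_subjects_table()
  path <- file.path(directory, "subjects.csv")
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

empty_subjects_table <- function() {
  out <- as.data.frame(setNames(rep(list(character(0)),
                                    length(subjects_schema)),
                                subjects_schema))
  out
}

#' Read a subjects table
#'
#' Validates the declared CSV schema (all columns present, numeric cells
#' numeric, grades in range, group consistent with the Fazekas total)
#' and reports violations with row and column.
#'
#' @param path path to `subjects.csv`.
#' @return Validated data frame.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop_wmhnet("subjects table not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(subjects_schema, names(tab))
  if (length(missing))
    stop_wmhnet("subjects table missing column(s): ",
                paste(missing, collapse = ", "))
  num_cols <- c("pvh", "dwmh", "fazekas_total", "wmh_volume_ml", "age",
                "education_years", "moca", "mmse")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    bad <- which(is.na(v) & nzchar(tab[[cl]]))
    if (length(bad))
      stop_wmhnet(sprintf("non-numeric value in column '%s', row %d: '%s'",
                          cl, bad[1], tab[[cl]][bad[1]]))
    tab[[cl]] <- v
  }
  for (i in seq_len(nrow(tab))) {
    fz <- fazekas_group(tab$pvh[i], tab$dwmh[i])
    if (fz$fazekas_total != tab$fazekas_total[i] ||
        !identical(fz$group, tab$group[i]))
      stop_wmhnet(sprintf(
        "row %d: group/total inconsistent with Fazekas grades", i))
  }
  tab
}

#' Read one ROI time-series file
#'
#' @param path CSV/TSV with T rows and N labeled columns.
#' @param node_labels expected column labels (order checked), or `NULL`.
#' @param tr_seconds repetition time to attach.
#' @return A [roi_timeseries()].
#' @export
read_timeseries <- function(path, node_labels = NULL, tr_seconds = 2) {
  if (!file.exists(path)) stop_wmhnet("time-series file not found: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop_wmhnet("non-numeric cells in time series: ", path)
  if (!is.null(node_labels)) {
    if (ncol(m) != length(node_labels))
      stop_wmhnet(sprintf(
        "%s has %d columns but %d node labels were declared",
        path, ncol(m), length(node_labels)))
    if (!identical(colnames(m), node_labels))
      stop_wmhnet("column labels do not match the node-label file: ", path)
  }
  roi_timeseries(m, tr_seconds, colnames(m))
}

#' Read a whole cohort back from disk
#'
#' @param directory directory written by [write_cohort()].
#' @param tr_seconds repetition time to attach to the series.
#' @return A `cohort` (without simulation parameters).
#' @export
read_cohort <- function(directory, tr_seconds = 2) {
  tab <- read_subjects(file.path(directory, "subjects.csv"))
  lab_path <- file.path(directory, "node_labels.txt")
  labels <- if (file.exists(lab_path)) readLines(lab_path) else NULL
  series <- lapply(seq_len(nrow(tab)), function(i) {
    read_timeseries(file.path(directory, tab$timeseries_file[i]),
                    labels, tr_seconds)$data
  })
  names(series) <- tab$subject_id
  structure(list(subjects = tab, timeseries = series,
                 node_labels = labels, params = NULL),
            class = "cohort")
}

#' Write a connectivity matrix as labeled CSV
#' @param c a `connectivity_matrix`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_connectivity <- function(c, path) {
  if (!inherits(c, "connectivity_matrix"))
    stop_wmhnet("expected a connectivity_matrix")
  df <- as.data.frame(c$values)
  write.csv(cbind(node = c$node_labels, df), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write a thresholded network as edge list plus JSON sidecar
#'
#' Edge list TSV (`node_i`, `node_j`, `weight`) and a `.json` sidecar
#' recording sparsity, edge count, connectedness and the edge-retention
#' convention.
#'
#' @param net a `binary_network` or `weighted_network`.
#' @param path output TSV path (sidecar gets the same stem).
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  w <- if (inherits(net, "weighted_network")) net$weights else
    adjacency_of(net)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(node_i = net$node_labels[idx[, 1]],
                   node_j = net$node_labels[idx[, 2]],
                   weight = w[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(sparsity = net$sparsity, n_edges = nrow(df),
               connected = if (!is.null(net$connected)) net$connected else NA,
               edge_rule = if (!is.null(net$keep)) net$keep else "positive",
               weighted = inherits(net, "weighted_network"))
  jsonlite::write_json(meta, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
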