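# Delimited-text I/O for surface feature tables, parcellations, matrices,
# graphs, and JSON reports. All formats are UTF-8, "." decimal, header row
# mandatory; TSV by default with comma-delimited files accepted on read.

#' Canonical surface feature column names
#'
#' The six vertex-wise morphometric measures exported per vertex of the pial
#' surface: cortical thickness (mm), surface area (mm^2), gray matter volume
#' (mm^3), sulcal depth, metric distortion, and mean curvature (the last
#' three dimensionless).
#'
#' @return Character vector of the six feature column names.
#' @export
surface_features <- function() {
  c("thickness", "area", "volume", "sulc", "metric_distortion", "curvature")
}

# Guess the delimiter of a delimited text file from its header line.
.detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a vertex-wise surface feature table
#'
#' Reads a delimited text file (TSV or CSV, header mandatory) with one row
#' per surface vertex, holding a `vertex_id` column, a `region_label` atlas
#' label column, and one numeric column per morphometric feature. Row order
#' is preserved; downstream network construction is invariant to it.
#'
#' @param path Path to the delimited file.
#' @param feature_names Character vector of feature columns to retain
#'   (default [surface_features()]).
#' @return A `vertex_table` data.frame with columns `vertex_id`,
#'   `region_label`, and the requested features.
#' @export
read_vertex_features <- function(path, feature_names = surface_features()) {
  sep <- .detect_sep(path)
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  required <- c("vertex_id", "region_label", feature_names)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("column not found: ", paste(missing, collapse = ", "), call. = FALSE)
  out <- df[, required, drop = FALSE]
  out$vertex_id <- suppressWarnings(as.integer(out$vertex_id))
  if (anyNA(out$vertex_id)) stop("non-integer vertex_id", call. = FALSE)
  if (anyDuplicated(out$vertex_id))
    stop("duplicate vertex_id within subject", call. = FALSE)
  for (f in feature_names) {
    v <- suppressWarnings(as.numeric(out[[f]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric or missing value in column '%s' at row %d",
                   f, bad[1L]), call. = FALSE)
    out[[f]] <- v
  }
  rownames(out) <- NULL
  structure(out, class = c("vertex_table", "data.frame"))
}

#' Write a vertex feature table
#'
#' @param table A `vertex_table` (or compatible data.frame).
#' @param path Output path; tab-delimited with header.
#' @return Invisibly, `path`.
#' @export
write_vertex_features <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cortical parcellation lookup
#'
#' Parses a delimited file with columns `region_label`, `hemisphere` (L/R),
#' `index` (0-based, contiguous), and optionally `region_name`, into a
#' bijective label/index map.
#'
#' @param path Path to the parcellation file.
#' @return A `parcellation` data.frame ordered by index, with attribute
#'   `V` (number of regions).
#' @export
read_parcellation <- function(path) {
  sep <- .detect_sep(path)
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  required <- c("region_label", "hemisphere", "index")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("column not found: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!"region_name" %in% names(df)) df$region_name <- df$region_label
  if (anyDuplicated(df$region_label))
    stop("duplicate region_label in parcellation", call. = FALSE)
  if (anyDuplicated(df$index))
    stop("duplicate index in parcellation", call. = FALSE)
  V <- nrow(df)
  if (!setequal(df$index, 0:(V - 1L)))
    stop("parcellation indices must be contiguous 0..V-1", call. = FALSE)
  if (!all(df$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  df <- df[order(df$index), c("region_label", "hemisphere", "index",
                              "region_name")]
  rownames(df) <- NULL
  structure(df, class = c("parcellation", "data.frame"), V = V)
}

#' Default 68-region Desikan-Killiany parcellation
#'
#' The gyral-based cortical atlas with 34 regions per hemisphere bundled
#' with the package.
#'
#' @return A `parcellation` with 68 regions.
#' @export
dk_parcellation <- function() {
  read_parcellation(system.file("extdata", "desikan_killiany_68.tsv",
                                package = "morphnet", mustWork = TRUE))
}

#' Write / read a labelled square matrix
#'
#' Tab-delimited with region labels as both the first row and the first
#' column; round trips are exact to 1e-12.
#'
#' @param matrix Square numeric matrix.
#' @param labels Character vector of region labels, one per row/column.
#' @param path File path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   list with elements `matrix` (with dimnames set) and `labels`.
#' @export
write_matrix <- function(matrix, labels, path) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("matrix must be square", call. = FALSE)
  if (length(labels) != nrow(matrix))
    stop("labels length must equal matrix dimension", call. = FALSE)
  dimnames(matrix) <- list(labels, labels)
  lines <- c(paste(c("region", labels), collapse = "\t"),
             vapply(seq_len(nrow(matrix)), function(i) {
               paste(c(labels[i], formatC(matrix[i, ], format = "g",
                                          digits = 17)), collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(m) != ncol(m)) stop("matrix file not square", call. = FALSE)
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, labels)
  list(matrix = m, labels = labels)
}

#' Write / read a thresholded graph as an edge list
#'
#' Tab-delimited columns `region_a region_b weight present`, one row per
#' unordered region pair (i < j in atlas order).
#'
#' @param adjacency 0/1 symmetric adjacency matrix with dimnames.
#' @param weights Symmetric weight matrix aligned with `adjacency`.
#' @param path File path.
#' @return `write_graph_edges` returns `path` invisibly; `read_graph_edges`
#'   a data.frame of the four columns.
#' @export
write_graph_edges <- function(adjacency, weights, path) {
  labels <- rownames(adjacency)
  idx <- which(upper.tri(adjacency), arr.ind = TRUE)
  df <- data.frame(region_a = labels[idx[, 1L]],
                   region_b = labels[idx[, 2L]],
                   weight = weights[idx],
                   present = as.integer(adjacency[idx] != 0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_edges
#' @export
read_graph_edges <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a JSON analysis report
#'
#' @param report A named list.
#' @param path File path.
#' @return `write_report` returns `path` invisibly; `read_report` the list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
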