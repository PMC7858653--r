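#' Read an ASV count table from TSV
#'
#' Accepts either orientation (ASV rows x sample columns — the common
#' amplicon export, and the dialect written by [write_fixture()] — or samples
#' x ASVs). When `metadata` is supplied the orientation is auto-detected by
#' matching ids against `metadata$sample_id`; otherwise `orientation`
#' decides. Non-integer or negative entries and duplicate ids are hard
#' errors.
#'
#' @param path TSV file; first column holds row ids.
#' @param metadata optional metadata data.frame for orientation detection.
#' @param taxonomy optional named lineage vector to attach.
#' @param orientation `"auto"`, `"asv_rows"` or `"sample_rows"`.
#' @return a [asv_table()].
#' @export
read_counts <- function(path, metadata = NULL, taxonomy = NULL,
                        orientation = c("auto", "asv_rows", "sample_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric entries in count table: ", path)
  if (any(mat != round(mat))) stop("non-integer counts in ", path)
  rownames(mat) <- ids
  if (orientation == "auto") {
    orientation <- "asv_rows"
    if (!is.null(metadata)) {
      md <- validate_metadata(metadata)
      row_hits <- mean(ids %in% md$sample_id)
      col_hits <- mean(colnames(mat) %in% md$sample_id)
      orientation <- if (row_hits > col_hits) "sample_rows" else "asv_rows"
    }
  }
  if (orientation == "asv_rows") mat <- t(mat)
  asv_table(mat, taxonomy)
}

#' Read a host-parameter table from CSV
#'
#' @param path CSV with a `sample_id` column and one numeric column per
#'   parameter; empty cells become `NA` (parameter not measured).
#' @return numeric matrix, samples x parameters.
#' @export
read_host <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("host table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in host table")
  mat <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric host parameter values in ", path)
  rownames(mat) <- df$sample_id
  mat
}

#' Read sample metadata from CSV
#'
#' @param path CSV with columns sample_id, experiment, group, cohort,
#'   timepoint.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  validate_metadata(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}

#' Read an ASV taxonomy map from TSV
#'
#' @param path two-column TSV (`asv_id`, `lineage`).
#' @return named character vector of lineages.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a planted ground truth from JSON
#'
#' @param path `truth.json` written by [write_fixture()].
#' @return list with `shifted_asv_ids`, `bottleneck_ids`, `planted_edges`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$shifted_asv_ids <- unlist(x$shifted_asv_ids)
  x
}

#' Write / read the audit-complete edge table
#'
#' @param edges edge data.frame from [correlate_features()].
#' @param path TSV destination.
#' @return `write_edges`: invisibly, `path`; `read_edges`: the data.frame.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write the network as GraphML (Cytoscape-compatible)
#'
#' @param network igraph graph from [build_network()].
#' @param path destination `.graphml`.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
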