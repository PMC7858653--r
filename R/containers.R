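#' ASV count table
#'
#' Bundles an integer abundance matrix (samples in rows, amplicon sequence
#' variants in columns) with an optional taxonomy lineage per ASV. This is the
#' raw object consumed by the preprocessing stage.
#'
#' @param counts integer matrix, samples x ASVs, with unique row and column
#'   names and no negative entries.
#' @param taxonomy optional named character vector mapping ASV ids to
#'   semicolon-delimited lineage strings (`"k__...;p__...;..."`). ASVs absent
#'   from the map are treated as unclassified.
#' @return an object of class `tk_asv`.
#' @export
asv_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty count table")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have sample (row) and ASV (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids")
  if (any(is.na(counts))) stop("NA counts are not allowed")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts)))
    stop("counts must be integers (found non-integer entries)")
  storage.mode(counts) <- "double" # exact for counts < 2^53
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("taxonomy must be named by ASV id")
    taxonomy <- taxonomy[intersect(names(taxonomy), colnames(counts))]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "tk_asv")
}

#' @export
print.tk_asv <- function(x, ...) {
  cat(sprintf("<tk_asv> %d samples x %d ASVs, total count %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.tk_asv <- function(x) dim(x$counts)

#' Feature table of normalized values
#'
#' Real-valued matrix (samples x features) carrying, per column, the feature
#' kind (`"microbe"` or `"host"`), plus provenance flags recording which
#' normalization steps have been applied.
#'
#' @param values numeric matrix, samples x features, dimnames required.
#' @param kind character vector (length = number of features, or length 1,
#'   recycled) of `"microbe"` / `"host"` labels.
#' @param provenance character vector of processing flags already applied.
#' @return an object of class `tk_features`.
#' @export
feature_table <- function(values, kind = "microbe", provenance = character()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature matrix must have sample and feature names")
  kind <- rep_len(as.character(kind), ncol(values))
  if (!all(kind %in% c("microbe", "host")))
    stop("feature kind must be 'microbe' or 'host'")
  structure(list(values = values, kind = kind,
                 provenance = unique(as.character(provenance))),
            class = "tk_features")
}

#' @export
print.tk_features <- function(x, ...) {
  cat(sprintf("<tk_features> %d samples x %d features (%d microbe, %d host)\n",
              nrow(x$values), ncol(x$values),
              sum(x$kind == "microbe"), sum(x$kind == "host")))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.tk_features <- function(x) dim(x$values)

add_provenance <- function(ft, flag) {
  ft$provenance <- unique(c(ft$provenance, flag))
  ft
}

#' Combine microbe and host feature tables
#'
#' Joins two feature tables on shared samples (intersection, in the order of
#' the first table).
#'
#' @param microbes,hosts `tk_features` objects.
#' @return a single `tk_features` with both feature sets.
#' @export
bind_features <- function(microbes, hosts) {
  shared <- intersect(rownames(microbes$values), rownames(hosts$values))
  if (length(shared) == 0L) stop("no shared samples between the two tables")
  feature_table(cbind(microbes$values[shared, , drop = FALSE],
                      hosts$values[shared, , drop = FALSE]),
                kind = c(microbes$kind, hosts$kind),
                provenance = union(microbes$provenance, hosts$provenance))
}

#' Validate a sample-metadata table
#'
#' Checks the metadata contract used throughout the pipeline: one row per
#' sample with experiment, group (control/treatment), birth-cohort and
#' timepoint labels.
#'
#' @param metadata a data.frame.
#' @param samples optional character vector of sample ids that must all be
#'   present in the metadata.
#' @return the validated data.frame (invisibly usable), with character columns.
#' @export
validate_metadata <- function(metadata, samples = NULL) {
  required <- c("sample_id", "experiment", "group", "cohort", "timepoint")
  missing <- setdiff(required, names(metadata))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  for (col in required) metadata[[col]] <- as.character(metadata[[col]])
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  if (!is.null(samples)) {
    orphans <- setdiff(samples, metadata$sample_id)
    if (length(orphans))
      stop("samples absent from metadata: ", paste(orphans, collapse = ", "))
  }
  metadata
}
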