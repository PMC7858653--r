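#' Remove ASV singletons
#'
#' Drops ASVs whose total count across all samples (pooling every experiment)
#' equals exactly 1. All-zero ASVs are retained here; they fall out later at
#' the cumulative-abundance filter.
#'
#' @param x a [asv_table()] object.
#' @return a `tk_asv` without singleton ASVs.
#' @export
drop_singletons <- function(x) {
  stopifnot(inherits(x, "tk_asv"))
  totals <- colSums(x$counts)
  keep <- totals != 1
  asv_table(x$counts[, keep, drop = FALSE], x$taxonomy)
}

#' Keep the most abundant ASVs by cumulative share
#'
#' ASVs are ranked by their grand total across all samples in every
#' experiment; the minimal prefix whose cumulative share of the grand total
#' reaches `threshold` is retained (the ASV that crosses the threshold is
#' included). With `threshold = 1` every ASV with a nonzero total is kept.
#'
#' @param x a `tk_asv`.
#' @param threshold fraction in (0, 1]; default 0.995.
#' @return a `tk_asv` restricted to the retained ASVs (original column order).
#' @export
filter_cumulative_abundance <- function(x, threshold = 0.995) {
  stopifnot(inherits(x, "tk_asv"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a single number in (0, 1]")
  totals <- colSums(x$counts)
  grand <- sum(totals)
  if (grand <= 0) stop("count table has zero grand total")
  ord <- order(-totals, colnames(x$counts)) # deterministic tie-break
  share <- cumsum(totals[ord]) / grand
  n_keep <- which(share >= threshold - 1e-12)[1L]
  keep_ids <- colnames(x$counts)[sort(ord[seq_len(n_keep)])]
  asv_table(x$counts[, keep_ids, drop = FALSE], x$taxonomy)
}

#' Relativize counts per million
#'
#' Converts each sample's counts to relative abundance on a counts-per-million
#' scale: `count / sample_total * 1e6`.
#'
#' @param x a `tk_asv`; every sample must have a positive total.
#' @return a `tk_features` of microbe features with provenance `relativized`.
#' @export
relativize_per_million <- function(x) {
  stopifnot(inherits(x, "tk_asv"))
  totals <- rowSums(x$counts)
  if (any(totals <= 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(x$counts)[totals <= 0], collapse = ", "))
  feature_table(x$counts / totals * 1e6, kind = "microbe",
                provenance = "relativized")
}

# Replace one sample's values by the reference distribution at matching ranks;
# tied entries receive the mean of the reference values over the tied ranks.
qn_map_to_reference <- function(v, ref) {
  o <- order(v)
  vs <- v[o]
  block <- cumsum(c(TRUE, vs[-1L] != vs[-length(vs)]))
  out <- stats::ave(ref, block)
  res <- numeric(length(v))
  res[o] <- out
  res
}

#' Quantile normalize microbe features per experiment
#'
#' Within each experiment separately, every sample's value vector is replaced
#' by the cross-sample mean of order statistics at the matching rank, so that
#' all samples of an experiment share one value distribution. Ties receive the
#' mean of the reference values over the tied ranks. An experiment with a
#' single sample is left unchanged with a warning.
#'
#' @param ft a `tk_features` (typically relativized microbe abundances).
#' @param metadata sample metadata (see [validate_metadata()]).
#' @return a `tk_features` with provenance `quantile_normalized`.
#' @export
quantile_normalize <- function(ft, metadata) {
  stopifnot(inherits(ft, "tk_features"))
  metadata <- validate_metadata(metadata, samples = rownames(ft$values))
  exp_of <- metadata$experiment[match(rownames(ft$values), metadata$sample_id)]
  vals <- ft$values
  for (ex in unique(exp_of)) {
    rows <- which(exp_of == ex)
    if (length(rows) < 2L) {
      warning("experiment '", ex,
              "' has a single sample; quantile normalization is the identity")
      next
    }
    sub <- vals[rows, , drop = FALSE]
    sorted <- apply(sub, 1L, sort)        # features x samples, each col sorted
    if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = 1L)
    ref <- rowMeans(sorted)               # mean k-th order statistic
    vals[rows, ] <- t(apply(sub, 1L, qn_map_to_reference, ref = ref))
  }
  out <- feature_table(vals, kind = ft$kind, provenance = ft$provenance)
  add_provenance(out, "quantile_normalized")
}

#' Log2 transform with pseudocount
#'
#' @param ft a `tk_features` with non-negative values.
#' @param pseudocount added before taking log2; default 1, which maps zeros to
#'   zero and is negligible on the counts-per-million scale.
#' @return a `tk_features` with provenance `log_transformed`.
#' @export
log2_transform <- function(ft, pseudocount = 1) {
  stopifnot(inherits(ft, "tk_features"))
  if (any(ft$values < 0)) stop("negative values cannot be log-transformed")
  out <- feature_table(log2(ft$values + pseudocount),
                       kind = ft$kind, provenance = ft$provenance)
  add_provenance(out, "log_transformed")
}

#' Normalize host parameters by birth cohort, then across experiments
#'
#' Stage 1 removes litter/cohort effects: each value is divided by the cohort
#' mean (or median, see `center`) of that parameter. A cohort with fewer than
#' two measured samples falls back, with a warning, to the overall mean of the
#' parameter. Stage 2 harmonizes the two experiments: every parameter measured
#' in more than one experiment is z-scored per experiment; parameters present
#' in a single experiment skip stage 2 and are flagged in the
#' `single_experiment` attribute of the result.
#'
#' @param host numeric matrix (samples x parameters) with dimnames; `NA`
#'   marks parameters not measured for a sample.
#' @param metadata sample metadata with cohort and experiment labels.
#' @param center `"mean"` (default) or `"median"` cohort statistic.
#' @return a `tk_features` of host features with provenance
#'   `cohort_normalized` (and `experiment_standardized` when stage 2 ran).
#' @export
normalize_host_by_cohort <- function(host, metadata, center = c("mean", "median")) {
  center <- match.arg(center)
  host <- as.matrix(host)
  if (is.null(rownames(host)) || is.null(colnames(host)))
    stop("host matrix must have sample and parameter names")
  metadata <- validate_metadata(metadata, samples = rownames(host))
  idx <- match(rownames(host), metadata$sample_id)
  cohort <- metadata$cohort[idx]
  experiment <- metadata$experiment[idx]
  cfun <- if (center == "mean") mean else stats::median
  out <- host

  for (p in colnames(host)) {
    v <- host[, p]
    overall <- cfun(v[!is.na(v)])
    for (co in unique(cohort)) {
      rows <- which(cohort == co & !is.na(v))
      if (!length(rows)) next
      if (length(rows) < 2L) {
        warning("cohort '", co, "' has < 2 samples for '", p,
                "'; normalizing by the overall ", center)
        ctr <- overall
      } else {
        ctr <- cfun(v[rows])
      }
      if (!is.finite(ctr) || ctr == 0)
        stop("cohort ", center, " of zero for parameter '", p,
             "' in cohort '", co, "'")
      out[rows, p] <- v[rows] / ctr
    }
  }

  # stage 2: cross-experiment standardization for shared parameters
  measured_in <- apply(out, 2L, function(v)
    length(unique(experiment[!is.na(v)])))
  shared <- colnames(out)[measured_in > 1L]
  single <- colnames(out)[measured_in <= 1L]
  for (p in shared) {
    for (ex in unique(experiment)) {
      rows <- which(experiment == ex & !is.na(out[, p]))
      if (length(rows) < 2L) next
      mu <- mean(out[rows, p]); sdv <- stats::sd(out[rows, p])
      out[rows, p] <- if (sdv > 0) (out[rows, p] - mu) / sdv else 0
    }
  }

  ft <- feature_table(out, kind = "host", provenance = "cohort_normalized")
  if (length(shared)) ft <- add_provenance(ft, "experiment_standardized")
  attr(ft, "single_experiment") <- single
  ft
}

#' Full microbe preprocessing chain
#'
#' Applies the fixed normalization order: singleton removal, cumulative
#' abundance filter, relativization per million, per-experiment quantile
#' normalization, log2 transform. The order is recorded in the provenance
#' flags of the result.
#'
#' @param x a `tk_asv`.
#' @param metadata sample metadata.
#' @param threshold cumulative-abundance fraction, default 0.995.
#' @param pseudocount log2 pseudocount, default 1.
#' @return a `tk_features` of normalized microbe abundances. The relativized
#'   (pre-quantile-normalization) table is kept in attribute `relativized`
#'   for abundance summaries.
#' @export
preprocess_microbes <- function(x, metadata, threshold = 0.995, pseudocount = 1) {
  x <- drop_singletons(x)
  x <- filter_cumulative_abundance(x, threshold)
  rel <- relativize_per_million(x)
  qn <- quantile_normalize(rel, metadata)
  out <- log2_transform(qn, pseudocount)
  attr(out, "relativized") <- rel
  attr(out, "pseudocount") <- pseudocount
  out
}

lineage_phylum <- function(lineage) {
  if (is.na(lineage) || !nzchar(trimws(lineage))) return("Unclassified")
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1L]])
  p <- grep("^p__", parts, value = TRUE)
  if (length(p)) {
    name <- sub("^p__", "", p[1L])
    return(if (nzchar(name)) name else "Unclassified")
  }
  # tolerate bare "Kingdom;Phylum;..." lineages without rank prefixes
  if (length(parts) >= 2L && nzchar(parts[2L])) return(parts[2L])
  "Unclassified"
}

#' Aggregate ASV counts to phylum level
#'
#' Sums, per sample, the counts of all ASVs sharing a phylum; ASVs with empty
#' or missing lineages are pooled into `"Unclassified"`.
#'
#' @param x a `tk_asv` with taxonomy.
#' @return numeric matrix, samples x phyla.
#' @export
aggregate_phylum <- function(x) {
  stopifnot(inherits(x, "tk_asv"))
  if (is.null(x$taxonomy)) stop("count table carries no taxonomy")
  lin <- x$taxonomy[colnames(x$counts)]
  lin[is.na(lin)] <- ""
  phyla <- vapply(lin, lineage_phylum, character(1L), USE.NAMES = FALSE)
  out <- t(rowsum(t(x$counts), group = phyla))
  out[, order(colnames(out)), drop = FALSE]
}

#' Bacteroidetes : Firmicutes ratio per sample
#'
#' Computes, for every sample, the ratio of Bacteroidetes to Firmicutes
#' counts from a phylum table. Samples with zero Firmicutes are returned as
#' `NA` (undefined), never infinity. The common misspelling "Bacteriodetes"
#' is accepted in the column names.
#'
#' @param phyla samples x phyla matrix, as from [aggregate_phylum()].
#' @return named numeric vector of per-sample ratios (`NA` = undefined).
#' @export
bacteroidetes_firmicutes_ratio <- function(phyla) {
  phyla <- as.matrix(phyla)
  bact <- intersect(c("Bacteroidetes", "Bacteriodetes", "Bacteroidota"),
                    colnames(phyla))
  if (!length(bact)) stop("no Bacteroidetes column in phylum table")
  if (!"Firmicutes" %in% colnames(phyla))
    stop("no Firmicutes column in phylum table")
  b <- rowSums(phyla[, bact, drop = FALSE])
  f <- phyla[, "Firmicutes"]
  ratio <- ifelse(f > 0, b / f, NA_real_)
  names(ratio) <- rownames(phyla)
  ratio
}
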