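#' Pipeline configuration
#'
#' All stage parameters of the end-to-end run, with defaults equal to the
#' published analysis settings: 99.5% cumulative-abundance threshold, log2
#' pseudocount 1, microbe-host individual-p prefilter 0.6, FDR tiers
#' 0.05 / 0.15 / 0.10 (microbe-microbe / microbe-host / host-host), and a
#' 10,000-graph null ensemble. The serialized configuration plus the input
#' files reproduce a run bit-exactly.
#'
#' @param threshold cumulative-abundance fraction.
#' @param pseudocount log2 pseudocount.
#' @param p_prefilter individual p screen for microbe-host edges.
#' @param fdr_thresholds named per-class FDR cuts.
#' @param fdr_method `"BH"` or `"BY"`.
#' @param rescue character vector of edge ids exempt from the prefilter.
#' @param cohort_center `"mean"` or `"median"` for host cohort normalization.
#' @param n_null null-ensemble size.
#' @param null_mode `"all"` or `"top"` (see [build_null_ensemble()]).
#' @param top_k candidates reported per node type.
#' @param seed master seed; per-stage seeds are derived from it and logged.
#' @return a list of class `tk_pipeline_config`.
#' @export
pipeline_config <- function(threshold = 0.995, pseudocount = 1,
                            p_prefilter = 0.6,
                            fdr_thresholds = c("microbe-microbe" = 0.05,
                                               "microbe-host" = 0.15,
                                               "host-host" = 0.10),
                            fdr_method = "BH", rescue = character(),
                            cohort_center = "mean",
                            n_null = 10000, null_mode = "all",
                            top_k = 3L, seed = 1L) {
  structure(list(threshold = threshold, pseudocount = pseudocount,
                 p_prefilter = p_prefilter, fdr_thresholds = fdr_thresholds,
                 fdr_method = fdr_method, rescue = rescue,
                 cohort_center = cohort_center, n_null = as.integer(n_null),
                 null_mode = null_mode, top_k = as.integer(top_k),
                 seed = as.integer(seed)),
            class = "tk_pipeline_config")
}

#' Run the full transkingdom pipeline
#'
#' Chains preprocessing, per-group correlation with the filter cascade,
#' network assembly, topology scoring and the random-network null:
#' preprocess -> correlate -> network -> topology -> null. Inputs may be
#' in-memory objects ([asv_table()], matrix, data.frame) or file paths in the
#' dialects of the `read_*` functions. When `out_dir` is given, all artifacts
#' plus a manifest (config, seeds, input checksums, filter-stage counts) are
#' written there.
#'
#' @param counts `tk_asv` or path to counts TSV.
#' @param host samples x parameters matrix or path to host CSV.
#' @param metadata data.frame or path to metadata CSV.
#' @param taxonomy optional named lineage vector or path to taxonomy TSV.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class `tk_run`: `features`, `fold_changes`, `edges`,
#'   `network`, `scores`, `candidates`, `null`, `tails`, `report`.
#' @export
run_pipeline <- function(counts, host, metadata, taxonomy = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "tk_pipeline_config"))
  input_paths <- character()
  if (is.character(metadata)) {
    input_paths["metadata"] <- metadata; metadata <- read_metadata(metadata)
  }
  metadata <- validate_metadata(metadata)
  if (is.character(taxonomy)) {
    input_paths["taxonomy"] <- taxonomy; taxonomy <- read_taxonomy(taxonomy)
  }
  if (is.character(counts)) {
    input_paths["counts"] <- counts
    counts <- read_counts(counts, metadata = metadata, taxonomy = taxonomy)
  } else if (!is.null(taxonomy) && is.null(counts$taxonomy)) {
    counts <- asv_table(counts$counts, taxonomy)
  }
  if (is.character(host)) {
    input_paths["host"] <- host; host <- read_host(host)
  }
  stopifnot(inherits(counts, "tk_asv"))

  # --- preprocess -----------------------------------------------------------
  microbes <- preprocess_microbes(counts, metadata,
                                  threshold = config$threshold,
                                  pseudocount = config$pseudocount)
  hosts_stage1 <- suppressWarnings(
    normalize_host_by_cohort(host, metadata, center = config$cohort_center))
  features <- bind_features(microbes, hosts_stage1)

  # fold changes on positive ratio scales: back-transformed normalized
  # abundances for microbes, stage-1 cohort-normalized values for hosts
  rel <- attr(microbes, "relativized")
  back <- pmax(2^microbes$values - config$pseudocount, 0)
  host_stage1_raw <- cohort_stage1_values(host, metadata, config$cohort_center)
  shared <- rownames(features$values)
  fc_input <- cbind(back[shared, , drop = FALSE],
                    host_stage1_raw[shared, , drop = FALSE])
  fold_changes <- fold_change_records(fc_input, metadata)

  # --- correlate ------------------------------------------------------------
  edges <- correlate_features(features, metadata, fold_changes,
                              p_prefilter = config$p_prefilter,
                              rescue = config$rescue,
                              fdr_thresholds = config$fdr_thresholds,
                              fdr_method = config$fdr_method)

  # --- network + topology ---------------------------------------------------
  network <- build_network(edges, fold_changes,
                           kind = stats::setNames(features$kind,
                                                  colnames(features$values)),
                           abundance = rel$values)
  scores <- topology_scores(network)
  candidates <- rank_candidates(scores, top_k = config$top_k)

  # --- null calibration -----------------------------------------------------
  n_nodes <- igraph::vcount(network)
  n_a <- sum(igraph::V(network)$type == "microbe")
  n_b <- n_nodes - n_a
  null <- NULL; tails <- NULL
  if (config$n_null >= 1L && n_nodes >= 2L && n_a >= 1L && n_b >= 1L &&
      igraph::ecount(network) >= 1L) {
    null <- build_null_ensemble(n = n_nodes, m = igraph::ecount(network),
                                n_a = n_a, n_b = n_b,
                                n_networks = config$n_null,
                                seed = stage_seed(config$seed, "null"),
                                mode = config$null_mode)
    tp <- tail_probability(null, candidates$degree, candidates$bibc_normalized)
    tails <- cbind(candidates,
                   tail_probability = as.numeric(tp),
                   censored = attr(tp, "censored"))
  }

  report <- pipeline_report(edges, network, scores)
  run <- structure(list(config = config, features = features,
                        fold_changes = fold_changes, edges = edges,
                        network = network, scores = scores,
                        candidates = candidates, null = null, tails = tails,
                        report = report),
                   class = "tk_run")
  if (!is.null(out_dir)) write_run(run, out_dir, input_paths)
  run
}

# stage-1-only cohort normalization (no cross-experiment z-scoring), used for
# host fold changes where a ratio scale is required
cohort_stage1_values <- function(host, metadata, center = "mean") {
  host <- as.matrix(host)
  metadata <- validate_metadata(metadata, samples = rownames(host))
  cohort <- metadata$cohort[match(rownames(host), metadata$sample_id)]
  cfun <- if (center == "mean") mean else stats::median
  out <- host
  for (p in colnames(host)) {
    v <- host[, p]
    overall <- cfun(v[!is.na(v)])
    for (co in unique(cohort)) {
      rows <- which(cohort == co & !is.na(v))
      if (!length(rows)) next
      ctr <- if (length(rows) < 2L) overall else cfun(v[rows])
      out[rows, p] <- v[rows] / ctr
    }
  }
  out
}

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11, null = 101)
  # double arithmetic, reduced mod 2^31 - 1, so large master seeds never
  # overflow R's 32-bit integers
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

pipeline_report <- function(edges, network, scores) {
  sgn <- edges$sign_consistent
  cas <- sgn & edges$causality_ok
  fcc <- cas & edges$fc_consistent
  pre <- fcc & edges$prefilter_ok
  list(n_candidate_edges = nrow(edges),
       n_after_sign = sum(sgn, na.rm = TRUE),
       n_after_causality = sum(cas, na.rm = TRUE),
       n_after_fold_change = sum(fcc, na.rm = TRUE),
       n_after_prefilter = sum(pre, na.rm = TRUE),
       n_kept = sum(edges$kept, na.rm = TRUE),
       n_rescued_kept = sum(edges$kept & edges$rescued, na.rm = TRUE),
       n_nodes = igraph::vcount(network),
       n_edges = igraph::ecount(network),
       n_positive_edges = if (igraph::ecount(network))
         sum(igraph::E(network)$average_rho > 0) else 0L,
       n_negative_edges = if (igraph::ecount(network))
         sum(igraph::E(network)$average_rho < 0) else 0L)
}

#' @export
print.tk_run <- function(x, ...) {
  r <- x$report
  cat("<tk_run> transkingdom pipeline result\n")
  cat(sprintf("  edges: %d candidates -> %d sign -> %d causality -> %d fold-change -> %d prefilter -> %d kept (%d rescued)\n",
              r$n_candidate_edges, r$n_after_sign, r$n_after_causality,
              r$n_after_fold_change, r$n_after_prefilter, r$n_kept,
              r$n_rescued_kept))
  cat(sprintf("  network: %d nodes, %d edges (%d positive / %d negative)\n",
              r$n_nodes, r$n_edges, r$n_positive_edges, r$n_negative_edges))
  if (!is.null(x$tails)) {
    cat("  top candidates:\n")
    print(x$tails[, c("node", "type", "degree", "bibc_normalized",
                      "tail_probability")], row.names = FALSE)
  }
  invisible(x)
}

write_run <- function(run, out_dir, input_paths = character()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  ft <- run$features
  utils::write.table(
    data.frame(sample_id = rownames(ft$values), ft$values,
               check.names = FALSE),
    file.path(out_dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_edges(run$edges, file.path(out_dir, "edges.tsv"))
  if (igraph::vcount(run$network) > 0)
    write_graphml(run$network, file.path(out_dir, "network.graphml"))
  utils::write.table(run$scores, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  checksums <- if (length(input_paths))
    as.list(tools::md5sum(unlist(input_paths))) else NULL
  manifest <- list(package_version = as.character(utils::packageVersion("tknet")),
                   config = unclass(run$config),
                   input_checksums = checksums,
                   report = run$report)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(run$null)) {
    null_summary <- list(n_networks = run$null$n_networks, n = run$null$n,
                         m = run$null$m, n_a = run$null$n_a, n_b = run$null$n_b,
                         mode = run$null$mode,
                         queries = run$tails)
    jsonlite::write_json(null_summary, file.path(out_dir, "null_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
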