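#' Partition samples into experiment-by-group analysis groups
#'
#' Builds the four (by default) analysis groups — control and treatment of
#' each experiment — over which per-pair Spearman correlations are computed.
#'
#' @param metadata sample metadata (see [validate_metadata()]).
#' @param samples optional character vector restricting the partition to these
#'   sample ids.
#' @param min_n minimum samples per group (Spearman p needs degrees of
#'   freedom); default 4.
#' @return named list of character vectors of sample ids, names
#'   `"<experiment>:<group>"`.
#' @export
make_partition <- function(metadata, samples = NULL, min_n = 4L) {
  metadata <- validate_metadata(metadata)
  if (!is.null(samples))
    metadata <- metadata[metadata$sample_id %in% samples, , drop = FALSE]
  key <- paste(metadata$experiment, metadata$group, sep = ":")
  part <- split(metadata$sample_id, key)
  small <- names(part)[lengths(part) < min_n]
  if (length(small))
    stop("group(s) with fewer than ", min_n, " samples: ",
         paste(small, collapse = ", "))
  part[order(names(part))]
}

# two-sided p-value for a Spearman rho via the t approximation on n-2 df
spearman_p <- function(rho, n) {
  r <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  p
}

#' Per-group Spearman correlations for all feature pairs
#'
#' Computes, within each analysis group, the Spearman rank correlation (ties
#' by average ranks) and its two-sided p-value from the t approximation on
#' n - 2 degrees of freedom, for every unordered feature pair. Features that
#' are constant within a group yield `NA` for that group; downstream filters
#' exclude such edges.
#'
#' @param features a `tk_features` with both microbe and host columns.
#' @param partition list of sample-id groups from [make_partition()].
#' @return list with elements `rho` and `p` (each a named list of
#'   features x features matrices, one per group), `n` (samples per group),
#'   and `kind` (feature kind vector).
#' @export
spearman_by_group <- function(features, partition) {
  stopifnot(inherits(features, "tk_features"))
  vals <- features$values
  rho <- p <- stats::setNames(vector("list", length(partition)), names(partition))
  n <- stats::setNames(integer(length(partition)), names(partition))
  for (g in names(partition)) {
    rows <- partition[[g]]
    if (length(rows) < 4L) stop("group '", g, "' has fewer than 4 samples")
    sub <- vals[rows, , drop = FALSE]
    constant <- apply(sub, 2L, function(v) length(unique(v)) == 1L)
    r <- suppressWarnings(stats::cor(sub, method = "spearman"))
    r[constant, ] <- NA_real_
    r[, constant] <- NA_real_
    rho[[g]] <- r
    p[[g]] <- spearman_p(r, length(rows))
    n[g] <- length(rows)
  }
  list(rho = rho, p = p, n = n, kind = features$kind)
}

#' Per-node fold-change records across experiments
#'
#' For every feature, computes the per-experiment median fold change
#' (treatment median / control median) on a positive ratio scale, its
#' direction, whether the direction is consistent across experiments, and the
#' average median fold change used as a node attribute.
#'
#' A zero or undefined control median, or an exact fold change of 1 (no
#' direction), makes the record inconsistent: edges touching such nodes are
#' removed by the fold-change-consistency filter.
#'
#' @param values numeric matrix (samples x features) on a positive ratio
#'   scale — e.g. back-transformed normalized abundances for microbes and
#'   cohort-normalized (stage 1) values for host parameters.
#' @param metadata sample metadata.
#' @param control_label,treatment_label group labels; defaults `"control"`,
#'   `"treatment"`.
#' @return data.frame with one row per feature: `feature`,
#'   `fc_<experiment>` columns, `direction` (+1 / -1 / NA), `consistent`,
#'   `average_median_fold_change`.
#' @export
fold_change_records <- function(values, metadata,
                                control_label = "control",
                                treatment_label = "treatment") {
  values <- as.matrix(values)
  metadata <- validate_metadata(metadata, samples = rownames(values))
  idx <- match(rownames(values), metadata$sample_id)
  experiment <- metadata$experiment[idx]
  group <- metadata$group[idx]
  exps <- sort(unique(experiment))

  fc <- matrix(NA_real_, nrow = ncol(values), ncol = length(exps),
               dimnames = list(colnames(values), exps))
  for (ex in exps) {
    ctl <- which(experiment == ex & group == control_label)
    trt <- which(experiment == ex & group == treatment_label)
    if (!length(ctl) || !length(trt)) next
    med_c <- apply(values[ctl, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    med_t <- apply(values[trt, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    ratio <- ifelse(is.finite(med_c) & med_c > 0 & is.finite(med_t),
                    med_t / med_c, NA_real_)
    fc[, ex] <- ratio
  }

  sign_fc <- sign(log(fc))           # +1 above 1, -1 below 1, 0 at exactly 1
  consistent <- apply(sign_fc, 1L, function(s)
    all(is.finite(s)) && all(s != 0) && length(unique(s)) == 1L)
  direction <- ifelse(consistent, sign_fc[, 1L], NA_real_)

  out <- data.frame(feature = rownames(fc),
                    consistent = unname(consistent),
                    direction = unname(direction),
                    average_median_fold_change = unname(rowMeans(fc)),
                    stringsAsFactors = FALSE)
  colnames(fc) <- paste0("fc_", colnames(fc))
  cbind(out, as.data.frame(fc, optional = TRUE), row.names = NULL)
}

#' Sign-consistency of per-group correlations
#'
#' @param rhos numeric matrix (edges x groups) or vector of per-group rhos.
#' @return logical: TRUE iff all rhos strictly share one sign. A zero or
#'   missing rho has no sign and fails.
#' @export
sign_consistency_filter <- function(rhos) {
  if (is.null(dim(rhos))) rhos <- matrix(rhos, nrow = 1L)
  apply(rhos, 1L, function(r)
    all(is.finite(r)) && (all(r > 0) || all(r < 0)))
}

#' Fold-change-consistency of an edge's endpoints
#'
#' @param consistent_a,consistent_b logical vectors: endpoint fold-change
#'   records' `consistent` flags.
#' @return logical: TRUE iff both endpoints changed in a consistent direction
#'   across experiments.
#' @export
fold_change_consistency_filter <- function(consistent_a, consistent_b) {
  as.logical(consistent_a) & as.logical(consistent_b) &
    !is.na(consistent_a) & !is.na(consistent_b)
}

#' Causality (sign-coherence) filter
#'
#' Retains an edge only when the sign of its average correlation equals the
#' product of its two endpoints' treatment fold-change directions:
#' `sign(rho) = sign(delta_A) * sign(delta_B)`. Edges violating this
#' coherence are treated as noise-driven.
#'
#' @param average_rho numeric vector of edge average correlations.
#' @param direction_a,direction_b endpoint directions (+1 / -1, `NA`
#'   undefined).
#' @return logical vector; undefined directions or zero correlations fail.
#' @export
causality_filter <- function(average_rho, direction_a, direction_b) {
  ok <- is.finite(average_rho) & average_rho != 0 &
    is.finite(direction_a) & is.finite(direction_b)
  ok & (sign(average_rho) == direction_a * direction_b)
}

#' Fixed-effect meta-analysis of correlations on Fisher's Z scale
#'
#' Pools per-group Spearman correlations with inverse-variance (fixed-effect)
#' weighting of the Fisher transforms: `z_i = atanh(rho_i)` with weight
#' `n_i - 3`; the pooled estimate is `zbar = sum(w z) / sum(w)` with standard
#' error `1/sqrt(sum(w))`, and the two-sided p-value comes from the normal
#' tail of `zbar / SE`.
#'
#' @param rhos numeric vector (one edge) or matrix (edges x groups) of
#'   correlations; values with `|rho| = 1` are clamped to `1 - 1e-7` with a
#'   warning.
#' @param ns group sizes (vector, recycled across edges); every `n` must
#'   exceed 3.
#' @return list with `meta_z` (the pooled z statistic `zbar/SE`), `meta_p`
#'   (two-sided normal p), and `pooled_r` (back-transformed pooled
#'   correlation).
#' @export
fisher_z_meta <- function(rhos, ns) {
  if (is.null(dim(rhos))) rhos <- matrix(rhos, nrow = 1L)
  if (is.null(dim(ns)))
    ns <- matrix(rep(as.numeric(ns), length.out = ncol(rhos)),
                 nrow = nrow(rhos), ncol = ncol(rhos), byrow = TRUE)
  if (any(ns <= 3)) stop("every group must have n > 3")
  if (any(abs(rhos) >= 1, na.rm = TRUE)) {
    warning("|rho| = 1 clamped to 1 - 1e-7 for Fisher transformation")
    rhos <- pmin(pmax(rhos, -(1 - 1e-7)), 1 - 1e-7)
  }
  z <- atanh(rhos)
  w <- ns - 3
  sw <- rowSums(w)
  zbar <- rowSums(w * z) / sw
  se <- 1 / sqrt(sw)
  stat <- zbar / se
  list(meta_z = as.numeric(stat),
       meta_p = as.numeric(2 * stats::pnorm(-abs(stat))),
       pooled_r = as.numeric(tanh(zbar)))
}

#' Individual p-value prefilter with rescue list
#'
#' Applies, to microbe-host edges only, the screen requiring every per-group
#' correlation p-value to fall below `p_cut`; edges named in `rescue` are
#' retained regardless and flagged `rescued`. Microbe-microbe and host-host
#' edges pass untouched.
#'
#' @param edges edge data.frame (see [correlate_features()]) holding
#'   `class` and per-group `p.` columns.
#' @param p_cut default 0.6.
#' @param rescue character vector of edge ids (`"a<==>b"`, either endpoint
#'   order) exempt from the prefilter.
#' @return the data.frame with logical columns `prefilter_ok` and `rescued`
#'   filled in.
#' @export
apply_prefilter <- function(edges, p_cut = 0.6, rescue = character()) {
  pcols <- grep("^p\\.", names(edges), value = TRUE)
  pm <- as.matrix(edges[, pcols, drop = FALSE])
  all_below <- apply(pm, 1L, function(p) all(is.finite(p)) && all(p < p_cut))
  id_fwd <- paste0(edges$node_a, "<==>", edges$node_b)
  id_rev <- paste0(edges$node_b, "<==>", edges$node_a)
  edges$rescued <- (id_fwd %in% rescue) | (id_rev %in% rescue)
  edges$prefilter_ok <- ifelse(edges$class == "microbe-host",
                               all_below | edges$rescued, TRUE)
  edges
}

#' Class-specific FDR adjustment and edge gating
#'
#' Benjamini-Hochberg adjustment of the meta-analysis p-values, computed
#' independently within each edge class (microbe-microbe, microbe-host,
#' host-host) over the edges that survived all earlier filters, then gated at
#' class-specific thresholds. Rescued edges enter the adjustment set but are
#' kept even when their FDR misses the threshold.
#'
#' @param edges edge data.frame with filter flags and `meta_p`.
#' @param thresholds named numeric: FDR cut per class; defaults
#'   `c("microbe-microbe" = 0.05, "microbe-host" = 0.15, "host-host" = 0.10)`.
#' @param method `stats::p.adjust` method; `"BH"` (default) or `"BY"`.
#' @return the data.frame with `fdr`, `kept` and `removal_reason` filled in.
#' @export
fdr_by_class <- function(edges,
                         thresholds = c("microbe-microbe" = 0.05,
                                        "microbe-host" = 0.15,
                                        "host-host" = 0.10),
                         method = c("BH", "BY")) {
  method <- match.arg(method)
  eligible <- edges$sign_consistent & edges$causality_ok &
    edges$fc_consistent & edges$prefilter_ok & is.finite(edges$meta_p)
  edges$fdr <- NA_real_
  for (cl in unique(edges$class)) {
    rows <- which(eligible & edges$class == cl)
    if (!length(rows)) next
    edges$fdr[rows] <- stats::p.adjust(edges$meta_p[rows], method = method)
  }
  thr <- thresholds[edges$class]
  edges$kept <- eligible & (edges$rescued |
                              (!is.na(edges$fdr) & edges$fdr < thr))
  edges$removal_reason <- edge_removal_reason(edges)
  edges
}

# first failing predicate in the documented order
edge_removal_reason <- function(edges) {
  reason <- rep("", nrow(edges))
  bad_rho <- !apply(as.matrix(edges[, grep("^rho\\.", names(edges)),
                                    drop = FALSE]), 1L,
                    function(r) all(is.finite(r)))
  reason[!edges$kept] <- "fdr"
  reason[!edges$kept & !edges$prefilter_ok] <- "prefilter"
  reason[!edges$kept & !edges$fc_consistent] <- "fold_change"
  reason[!edges$kept & !edges$causality_ok & edges$sign_consistent] <- "causality"
  reason[!edges$kept & !edges$sign_consistent] <- "sign"
  reason[!edges$kept & bad_rho] <- "constant_feature"
  reason
}

#' Candidate edges with per-group evidence, filters, meta-analysis and FDR
#'
#' Runs the full edge-selection cascade: per-group Spearman correlations for
#' every feature pair, sign-consistency, causality and fold-change-consistency
#' screens, the microbe-host individual-p prefilter with optional rescue
#' edges, the fixed-effect Fisher-Z meta-analysis, and class-specific BH-FDR
#' gating. The returned table is audit-complete: removed edges stay in it
#' with their first failing filter recorded.
#'
#' @param features combined `tk_features` (microbes + hosts).
#' @param metadata sample metadata.
#' @param fold_changes data.frame from [fold_change_records()].
#' @param p_prefilter individual-p screen for microbe-host edges; default 0.6.
#' @param rescue character vector of edge ids exempt from the prefilter.
#' @param fdr_thresholds named per-class FDR cuts (see [fdr_by_class()]).
#' @param fdr_method `"BH"` (default) or `"BY"`.
#' @return data.frame with one row per unordered feature pair.
#' @export
correlate_features <- function(features, metadata, fold_changes,
                               p_prefilter = 0.6, rescue = character(),
                               fdr_thresholds = c("microbe-microbe" = 0.05,
                                                  "microbe-host" = 0.15,
                                                  "host-host" = 0.10),
                               fdr_method = "BH") {
  partition <- make_partition(metadata, samples = rownames(features$values))
  sp <- spearman_by_group(features, partition)

  feats <- colnames(features$values)
  kind <- features$kind
  pair <- which(upper.tri(matrix(0, length(feats), length(feats))), arr.ind = TRUE)
  ia <- pair[, 1L]; ib <- pair[, 2L]
  class_of <- function(ka, kb) ifelse(ka == kb,
                                      paste0(ka, "-", kb),
                                      "microbe-host")
  edges <- data.frame(node_a = feats[ia], node_b = feats[ib],
                      class = class_of(kind[ia], kind[ib]),
                      stringsAsFactors = FALSE)

  for (g in names(partition)) {
    edges[[paste0("rho.", g)]] <- sp$rho[[g]][cbind(ia, ib)]
    edges[[paste0("p.", g)]] <- sp$p[[g]][cbind(ia, ib)]
    edges[[paste0("n.", g)]] <- sp$n[[g]]
  }

  rmat <- as.matrix(edges[, paste0("rho.", names(partition)), drop = FALSE])
  edges$average_rho <- rowMeans(rmat)
  edges$sign_consistent <- sign_consistency_filter(rmat)

  fcidx_a <- match(edges$node_a, fold_changes$feature)
  fcidx_b <- match(edges$node_b, fold_changes$feature)
  if (anyNA(fcidx_a) || anyNA(fcidx_b))
    stop("feature(s) without a fold-change record")
  edges$fc_consistent <- fold_change_consistency_filter(
    fold_changes$consistent[fcidx_a], fold_changes$consistent[fcidx_b])
  edges$causality_ok <- causality_filter(edges$average_rho,
                                         fold_changes$direction[fcidx_a],
                                         fold_changes$direction[fcidx_b])

  edges <- apply_prefilter(edges, p_cut = p_prefilter, rescue = rescue)

  ok <- apply(rmat, 1L, function(r) all(is.finite(r)))
  edges$meta_z <- edges$meta_p <- NA_real_
  if (any(ok)) {
    meta <- fisher_z_meta(rmat[ok, , drop = FALSE], sp$n)
    edges$meta_z[ok] <- meta$meta_z
    edges$meta_p[ok] <- meta$meta_p
  }

  fdr_by_class(edges, thresholds = fdr_thresholds, method = fdr_method)
}
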