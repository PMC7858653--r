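#' Assemble kept edges into the transkingdom network
#'
#' Builds an undirected simple graph from the kept rows of an edge table.
#' Nodes are exactly the endpoints of kept edges (isolated features are not
#' nodes). Node attributes: `type` (microbe/host), `average_median_fold_change`
#' and, for microbes, `average_abundance` (mean relativized abundance across
#' all samples of both experiments). Edge attributes: `average_rho` and its
#' `sign`.
#'
#' @param edges edge data.frame from [correlate_features()] (or a subset);
#'   only rows with `kept == TRUE` are used.
#' @param fold_changes data.frame from [fold_change_records()].
#' @param kind named character vector of feature kinds (or a `tk_features`
#'   whose kinds are used).
#' @param abundance optional samples x microbes matrix of relativized
#'   abundances used for the `average_abundance` node attribute.
#' @return an [igraph::graph] object (possibly empty).
#' @export
build_network <- function(edges, fold_changes, kind, abundance = NULL) {
  kept <- edges[isTRUE_vec(edges$kept), , drop = FALSE]
  if (inherits(kind, "tk_features"))
    kind <- stats::setNames(kind$kind, colnames(kind$values))
  if (nrow(kept) == 0L)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  if (anyDuplicated(t(apply(kept[, c("node_a", "node_b")], 1L, sort))))
    stop("duplicate edges in kept set")
  if (any(kept$node_a == kept$node_b)) stop("self-edges are not allowed")

  nodes <- sort(unique(c(kept$node_a, kept$node_b)))
  fcidx <- match(nodes, fold_changes$feature)
  if (anyNA(fcidx)) stop("edge endpoint(s) without a fold-change record: ",
                         paste(nodes[is.na(fcidx)], collapse = ", "))
  vdf <- data.frame(name = nodes,
                    type = unname(kind[nodes]),
                    average_median_fold_change =
                      fold_changes$average_median_fold_change[fcidx],
                    stringsAsFactors = FALSE)
  if (!is.null(abundance)) {
    ab <- colMeans(abundance)
    vdf$average_abundance <- ifelse(nodes %in% names(ab),
                                    unname(ab[nodes]), NA_real_)
  }
  edf <- data.frame(from = kept$node_a, to = kept$node_b,
                    average_rho = kept$average_rho,
                    sign = ifelse(kept$average_rho >= 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  comp <- igraph::components(g)
  igraph::V(g)$component <- comp$membership
  g
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Node degree
#'
#' Incident-edge count per node (the number of nodes a node interacts with in
#' a simple graph).
#'
#' @param network an igraph graph.
#' @return named integer vector.
#' @export
node_degree <- function(network) {
  igraph::degree(network)
}

#' Bipartite betweenness centrality (BiBC)
#'
#' For two disjoint node sets A and B, BiBC of a node v is the sum over
#' unordered pairs (s in A, t in B), with s != v != t, of the fraction of
#' shortest s-t paths that pass through v. Nodes on no cross-group shortest
#' path (including every degree-1 node outside A-B interiors) score 0;
#' disconnected pairs contribute 0. Edges are treated as unweighted: the
#' statistic counts paths, correlation magnitude stays an attribute.
#'
#' @param network an igraph graph.
#' @param set_a,set_b character vectors of vertex names (or numeric vertex
#'   ids) for the two groups; by default disjointness is required.
#' @param normalize if TRUE, divide by `|A| * |B|` (see [normalize_bibc()]).
#' @param check_disjoint set FALSE to allow overlapping sets, in which case
#'   pairs inside the overlap are counted once per ordered direction (so
#'   `set_a = set_b =` all vertices gives twice the classical betweenness).
#' @return named numeric vector over all vertices.
#' @export
bibc <- function(network, set_a = NULL, set_b = NULL, normalize = FALSE,
                 check_disjoint = TRUE) {
  n <- igraph::vcount(network)
  nm <- igraph::V(network)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  if (is.null(set_a) || is.null(set_b)) {
    type <- igraph::V(network)$type
    if (is.null(type))
      stop("set_a/set_b not given and the graph has no 'type' attribute")
    set_a <- nm[type == "microbe"]
    set_b <- nm[type == "host"]
  }
  a_idx <- resolve_vertices(set_a, nm)
  b_idx <- resolve_vertices(set_b, nm)
  if (check_disjoint && length(intersect(a_idx, b_idx)))
    stop("set_a and set_b must be disjoint")
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  el <- igraph::as_edgelist(network, names = FALSE)
  storage.mode(el) <- "integer"
  is_b <- rep(FALSE, n); is_b[b_idx] <- TRUE
  raw <- bibc_accumulate(n, el - 1L, as.integer(a_idx - 1L), is_b)
  names(raw) <- nm
  if (normalize) raw <- normalize_bibc(raw, length(a_idx), length(b_idx))
  raw
}

resolve_vertices <- function(set, nm) {
  if (is.character(set)) {
    idx <- match(set, nm)
    if (anyNA(idx)) stop("unknown vertex name(s): ",
                         paste(set[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(set)
}

#' Normalize BiBC by group sizes
#'
#' Divides raw BiBC by `n_A * n_B`, the number of cross-group pairs, mapping
#' scores into \[0, 1\].
#'
#' @param scores raw BiBC values.
#' @param n_a,n_b sizes of the two groups (both positive).
#' @return normalized scores.
#' @export
normalize_bibc <- function(scores, n_a, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("both groups must be non-empty")
  scores / (n_a * n_b)
}

#' Degree and normalized BiBC for every node
#'
#' @param network an igraph graph whose vertices carry a `type` attribute
#'   (microbe/host), as from [build_network()].
#' @return data.frame: `node`, `type`, `degree`, `bibc_raw`,
#'   `bibc_normalized`, sorted by the ranking order of [rank_candidates()].
#' @export
topology_scores <- function(network) {
  if (igraph::vcount(network) == 0L)
    return(data.frame(node = character(), type = character(),
                      degree = integer(), bibc_raw = numeric(),
                      bibc_normalized = numeric(), stringsAsFactors = FALSE))
  type <- igraph::V(network)$type
  nm <- igraph::V(network)$name
  n_a <- sum(type == "microbe"); n_b <- sum(type == "host")
  raw <- bibc(network)
  norm <- if (n_a > 0 && n_b > 0) normalize_bibc(raw, n_a, n_b) else raw * 0
  out <- data.frame(node = nm, type = type,
                    degree = as.integer(igraph::degree(network)),
                    bibc_raw = as.numeric(raw),
                    bibc_normalized = as.numeric(norm),
                    stringsAsFactors = FALSE)
  out[order(-out$bibc_normalized, -out$degree, out$node), , drop = FALSE]
}

#' Rank bottleneck candidates
#'
#' Sorts nodes by (normalized BiBC desc, degree desc, node id asc) — a
#' deterministic lexicographic order — and returns the top `top_k` of each
#' node type.
#'
#' @param scores data.frame from [topology_scores()].
#' @param top_k how many per type; larger than the node count returns all.
#' @param type optional: restrict to `"microbe"` or `"host"`.
#' @return data.frame of the ranked candidates with a `rank` column
#'   (per type).
#' @export
rank_candidates <- function(scores, top_k = 3L, type = NULL) {
  if (nrow(scores) == 0L) return(cbind(scores, rank = integer()))
  scores <- scores[order(-scores$bibc_normalized, -scores$degree, scores$node),
                   , drop = FALSE]
  pieces <- lapply(split(scores, scores$type), function(d) {
    d$rank <- seq_len(nrow(d))
    utils::head(d, top_k)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (!is.null(type)) out <- out[out$type == type, , drop = FALSE]
  out[order(out$type, out$rank), , drop = FALSE]
}
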