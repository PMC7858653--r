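# Independent oracles used across test files. These deliberately take the
# slow, literal route so they share no code path with the implementation.

# Brute-force BiBC: enumerate every shortest path between every (A, B) pair
# with igraph and count interior-node fractions explicitly.
bibc_oracle <- function(g, set_a, set_b) {
  nm <- igraph::V(g)$name
  res <- stats::setNames(numeric(length(nm)), nm)
  for (s in set_a) for (t in set_b) {
    if (s == t) next
    paths <- suppressWarnings(
      igraph::all_shortest_paths(g, from = s, to = t)$res)
    if (!length(paths)) next
    interior <- unlist(lapply(paths, function(p) {
      v <- names(p)
      v[!(v %in% c(s, t))]
    }))
    if (length(interior)) {
      tab <- table(interior)
      res[names(tab)] <- res[names(tab)] + as.numeric(tab) / length(paths)
    }
  }
  res
}

# Benjamini-Hochberg step-up written straight from the definition:
# adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cur <- 1
  for (i in m:1) {
    cur <- min(cur, p[o[i]] * m / i)
    adj[o[i]] <- cur
  }
  pmin(adj, 1)
}

# Tiny count-table builder for preprocessing tests.
toy_asv <- function(counts, taxonomy = NULL, samples = NULL, asvs = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- samples %||% sprintf("s%d", seq_len(nrow(counts)))
  colnames(counts) <- asvs %||% sprintf("a%d", seq_len(ncol(counts)))
  if (!is.null(taxonomy)) names(taxonomy) <- colnames(counts)
  asv_table(counts, taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-experiment metadata for a block of samples, groups in halves.
toy_metadata <- function(samples, experiment = "exp1",
                         group = NULL, cohort = NULL) {
  n <- length(samples)
  data.frame(sample_id = samples,
             experiment = rep_len(experiment, n),
             group = group %||% rep(c("control", "treatment"), each = n / 2),
             cohort = cohort %||% rep_len(c("c1", "c2"), n),
             timepoint = "wk12",
             stringsAsFactors = FALSE)
}
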