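#' Sample an Erdos-Renyi G(n, m) random graph
#'
#' Draws a simple undirected graph with exactly `n` nodes and exactly `m`
#' distinct edges chosen uniformly without replacement, deterministically for
#' a given seed.
#'
#' @param n node count.
#' @param m edge count, `0 <= m <= n(n-1)/2`.
#' @param seed optional integer; when given, sampling is reproducible and the
#'   caller's RNG state is left untouched.
#' @return an igraph graph.
#' @export
sample_gnm <- function(n, m, seed = NULL) {
  if (m < 0 || m > n * (n - 1) / 2)
    stop("m must lie in [0, n(n-1)/2]")
  with_seed_(seed, igraph::sample_gnm(n, m, directed = FALSE, loops = FALSE))
}

# evaluate expr under a temporary RNG seed (restores .Random.seed after)
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Null ensemble of size-matched random graphs
#'
#' Samples `n_networks` G(n, m) graphs, assigns each a uniformly random
#' disjoint bipartition of sizes (`n_a`, `n_b`) — the real microbe/host
#' labels carry no meaning in an unlabeled random graph — computes every
#' node's degree and normalized BiBC, pools the samples, and bins them into a
#' 2D probability-density histogram (degree at integer bins, BiBC in
#' `bibc_bins` equal-width bins spanning 0 to 1.05 x the observed maximum).
#'
#' @param n,m node and edge counts of the real network.
#' @param n_a,n_b partition sizes, `n_a + n_b = n`.
#' @param n_networks ensemble size; default 10000.
#' @param seed integer seed for reproducibility.
#' @param mode `"all"` pools every node of every graph (default; richer and
#'   more conservative for extreme queries); `"top"` pools only each
#'   network's highest-(BiBC, degree) node.
#' @param bibc_bins number of BiBC histogram bins; default 50.
#' @return an object of class `tk_null`: a list with the pooled `degree` and
#'   `bibc` samples, histogram `breaks_degree` / `breaks_bibc` / `density`,
#'   and the ensemble metadata.
#' @export
build_null_ensemble <- function(n, m, n_a, n_b, n_networks = 10000,
                                seed = NULL, mode = c("all", "top"),
                                bibc_bins = 50L) {
  mode <- match.arg(mode)
  if (n_networks < 1L) stop("n_networks must be positive")
  if (n_a + n_b != n) stop("n_a + n_b must equal n")
  if (n_a <= 0 || n_b <= 0) stop("both partition sizes must be positive")
  res <- with_seed_(seed, {
    deg_pool <- bibc_pool <- vector("list", n_networks)
    for (i in seq_len(n_networks)) {
      g <- igraph::sample_gnm(n, m, directed = FALSE, loops = FALSE)
      stopifnot(igraph::ecount(g) == m, igraph::vcount(g) == n)
      a_idx <- sample.int(n, n_a)
      b_idx <- setdiff(seq_len(n), a_idx)
      deg <- as.numeric(igraph::degree(g))
      el <- igraph::as_edgelist(g, names = FALSE)
      storage.mode(el) <- "integer"
      is_b <- rep(FALSE, n); is_b[b_idx] <- TRUE
      bb <- bibc_accumulate(n, el - 1L, as.integer(a_idx - 1L), is_b) /
        (n_a * n_b)
      if (mode == "top") {
        j <- order(-bb, -deg)[1L]
        deg_pool[[i]] <- deg[j]; bibc_pool[[i]] <- bb[j]
      } else {
        deg_pool[[i]] <- deg; bibc_pool[[i]] <- bb
      }
    }
    list(degree = unlist(deg_pool), bibc = unlist(bibc_pool))
  })

  max_d <- max(res$degree)
  breaks_degree <- seq(-0.5, max_d + 0.5, by = 1)
  max_b <- max(res$bibc)
  upper <- if (max_b > 0) max_b * 1.05 else 1e-6
  breaks_bibc <- seq(0, upper, length.out = bibc_bins + 1L)
  di <- findInterval(res$degree, breaks_degree, rightmost.closed = TRUE)
  bi <- findInterval(res$bibc, breaks_bibc, rightmost.closed = TRUE)
  counts <- matrix(0, nrow = length(breaks_degree) - 1L, ncol = bibc_bins,
                   dimnames = list(0:max_d, NULL))
  tab <- table(factor(di, levels = seq_len(nrow(counts))),
               factor(bi, levels = seq_len(bibc_bins)))
  counts[] <- as.numeric(tab)
  bin_area <- 1 * diff(breaks_bibc)[1L]
  density <- counts / (length(res$degree) * bin_area)

  structure(list(n_networks = n_networks, n = n, m = m, n_a = n_a, n_b = n_b,
                 mode = mode, seed = seed,
                 degree = res$degree, bibc = res$bibc,
                 breaks_degree = breaks_degree, breaks_bibc = breaks_bibc,
                 density = density),
            class = "tk_null")
}

#' @export
print.tk_null <- function(x, ...) {
  cat(sprintf(
    "<tk_null> %d G(n=%d, m=%d) graphs, partition %d/%d, %d pooled (%s) samples\n",
    x$n_networks, x$n, x$m, x$n_a, x$n_b, length(x$degree), x$mode))
  invisible(x)
}

#' Upper-tail probability of a (degree, BiBC) pair under the null
#'
#' Empirical fraction of pooled null node samples whose degree and normalized
#' BiBC are both at least as large as the query — the likelihood of randomly
#' finding a node with the given BiBC and degree or higher. When no null
#' sample reaches the query, the estimate is reported as the resolution bound
#' `1 / pool size` with attribute `censored = TRUE` (read "< 1/pool").
#'
#' @param summary a `tk_null` ensemble.
#' @param degree,bibc query values (vectors of equal length are recycled
#'   elementwise).
#' @return numeric vector of tail probabilities in \[0, 1\], with logical
#'   attribute `censored` marking zero-observation queries.
#' @export
tail_probability <- function(summary, degree, bibc) {
  stopifnot(inherits(summary, "tk_null"))
  k <- max(length(degree), length(bibc))
  degree <- rep_len(degree, k); bibc <- rep_len(bibc, k)
  pool <- length(summary$degree)
  cnt <- vapply(seq_len(k), function(i)
    sum(summary$degree >= degree[i] & summary$bibc >= bibc[i]), numeric(1L))
  p <- cnt / pool
  censored <- cnt == 0L
  p[censored] <- 1 / pool
  attr(p, "censored") <- censored
  p
}
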