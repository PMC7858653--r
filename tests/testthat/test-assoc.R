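make_features <- function(mat, kind = "microbe") {
  feature_table(mat, kind = kind)
}

test_that("per-group Spearman matches hand-ranked values and cor.test", {
  m <- cbind(x = c(1, 2, 3, 4, 5), y = c(1, 2, 3, 4, 5),
             z = c(5, 4, 3, 2, 1), w = c(2, 1, 4, 3, 5))
  rownames(m) <- sprintf("s%d", 1:5)
  part <- list(g1 = rownames(m))
  sp <- spearman_by_group(make_features(m), part)
  expect_equal(sp$rho$g1["x", "y"], 1)
  expect_equal(sp$rho$g1["x", "z"], -1)

  # brute-force rank formula: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  d <- rank(x) - rank(y)
  expect_equal(1 - 6 * sum(d^2) / (4 * 15), 0.6)
  m2 <- cbind(x = x, y = y); rownames(m2) <- sprintf("s%d", 1:4)
  sp2 <- spearman_by_group(make_features(m2), list(g = rownames(m2)))
  expect_equal(sp2$rho$g["x", "y"], 0.6)

  # p-value agrees with cor.test's t approximation
  set.seed(2)
  a <- rnorm(9); b <- rnorm(9)
  m3 <- cbind(a = a, b = b); rownames(m3) <- sprintf("s%d", 1:9)
  sp3 <- spearman_by_group(make_features(m3), list(g = rownames(m3)))
  ct <- cor.test(a, b, method = "spearman", exact = FALSE)
  expect_equal(sp3$rho$g["a", "b"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(sp3$p$g["a", "b"], ct$p.value, tolerance = 1e-12)

  # constant features are flagged as NA
  m4 <- cbind(c = rep(1, 5), x = 1:5); rownames(m4) <- sprintf("s%d", 1:5)
  sp4 <- spearman_by_group(make_features(m4), list(g = rownames(m4)))
  expect_true(is.na(sp4$rho$g["c", "x"]))

  expect_error(spearman_by_group(make_features(m2),
                                 list(g = rownames(m2)[1:3])), "fewer than 4")
})

test_that("sign consistency requires one strict common sign across groups", {
  expect_true(sign_consistency_filter(c(0.5, 0.4, 0.7, 0.2)))
  expect_true(sign_consistency_filter(c(-0.5, -0.4, -0.7, -0.2)))
  expect_false(sign_consistency_filter(c(0.5, -0.1, 0.7, 0.2)))
  expect_false(sign_consistency_filter(c(0.5, 0, 0.7, 0.2)))   # zero: no sign
  expect_false(sign_consistency_filter(c(0.5, NA, 0.7, 0.2)))
  expect_equal(sign_consistency_filter(rbind(c(1, 1), c(1, -1)) * 0.3),
               c(TRUE, FALSE))
})

test_that("fold-change records and consistency handle direction boundaries", {
  # two experiments, 4 + 4 samples each, groups in halves
  vals <- cbind(up = c(1, 1, 1, 1, 2, 2, 2, 2,  1, 1, 1, 1, 3, 3, 3, 3),
                flip = c(1, 1, 1, 1, 2, 2, 2, 2,  2, 2, 2, 2, 1, 1, 1, 1),
                flat = c(1, 1, 1, 1, 1, 1, 1, 1,  1, 1, 1, 1, 1, 1, 1, 1))
  rownames(vals) <- sprintf("s%d", 1:16)
  md <- rbind(toy_metadata(sprintf("s%d", 1:8), "exp1"),
              toy_metadata(sprintf("s%d", 9:16), "exp2"))
  fc <- fold_change_records(vals, md)
  expect_equal(fc$consistent, c(TRUE, FALSE, FALSE))
  expect_equal(fc$direction[1], 1)
  expect_true(is.na(fc$direction[3]))   # exact zero change: no direction
  expect_equal(fc$average_median_fold_change[1], mean(c(2, 3)))

  expect_equal(fold_change_consistency_filter(c(TRUE, TRUE, FALSE),
                                              c(TRUE, FALSE, FALSE)),
               c(TRUE, FALSE, FALSE))
})

test_that("the causality filter keeps exactly the sign-coherent combinations", {
  combos <- expand.grid(rho = c(1, -1), da = c(1, -1), db = c(1, -1))
  pass <- causality_filter(0.4 * combos$rho, combos$da, combos$db)
  expect_equal(sum(pass), 4)
  expect_equal(pass, with(combos, sign(rho) == da * db))
  # spot checks
  expect_true(causality_filter(0.5, 1, 1))     # both up, positive rho
  expect_false(causality_filter(0.5, 1, -1))   # discordant nodes, positive rho
  expect_true(causality_filter(0.5, -1, -1))   # both down, positive rho
  expect_false(causality_filter(0, 1, 1))      # zero rho has no sign
  expect_false(causality_filter(0.5, NA, 1))   # undefined direction
})

test_that("Fisher-Z fixed-effect meta-analysis matches its closed form", {
  # all-zero correlations pool to p = 1
  expect_equal(fisher_z_meta(c(0, 0, 0, 0), c(8, 8, 8, 8))$meta_p, 1)

  # single group: the plain Fisher-Z two-sided p
  m <- fisher_z_meta(0.5, 20)
  expect_equal(m$meta_p, 2 * pnorm(-atanh(0.5) * sqrt(17)), tolerance = 1e-15)
  expect_equal(m$meta_p, 0.0235221, tolerance = 1e-5)

  # pooling equal evidence beats any single group
  single <- fisher_z_meta(0.5, 10)$meta_p
  pooled <- fisher_z_meta(rep(0.5, 4), rep(10, 4))$meta_p
  expect_lt(pooled, single)

  # permutation invariance and rho -> -rho equivariance
  r <- c(0.2, 0.5, 0.35, 0.6); n <- c(8, 9, 7, 8)
  a <- fisher_z_meta(r, n); b <- fisher_z_meta(rev(r), rev(n))
  expect_equal(a$meta_p, b$meta_p, tolerance = 1e-15)
  neg <- fisher_z_meta(-r, n)
  expect_equal(neg$meta_z, -a$meta_z, tolerance = 1e-15)
  expect_equal(neg$meta_p, a$meta_p, tolerance = 1e-15)

  expect_warning(fisher_z_meta(c(1, 0.5), c(8, 8)), "clamped")
  expect_error(fisher_z_meta(0.5, 3), "n > 3")
})

test_that("meta-analysis agrees with an independent fixed-effect fit", {
  skip_if_not_installed("metafor")
  set.seed(9)
  for (i in 1:20) {
    r <- runif(4, -0.8, 0.8); n <- sample(5:15, 4, replace = TRUE)
    ours <- fisher_z_meta(r, n)
    fit <- metafor::rma(yi = atanh(r), vi = 1 / (n - 3), method = "FE")
    expect_equal(ours$meta_z, unname(fit$zval), tolerance = 1e-10)
    expect_equal(ours$meta_p, unname(fit$pval), tolerance = 1e-10)
  }
})

test_that("the individual-p prefilter screens microbe-host edges, with rescues", {
  edges <- data.frame(node_a = c("A", "A", "A", "M1"),
                      node_b = c("h1", "h2", "h3", "M2"),
                      class = c(rep("microbe-host", 3), "microbe-microbe"),
                      stringsAsFactors = FALSE)
  edges[, paste0("p.", 1:4)] <- rbind(c(0.1, 0.3, 0.5, 0.59),
                                      c(0.1, 0.3, 0.5, 0.61),
                                      c(0.7, 0.7, 0.7, 0.7),
                                      c(0.9, 0.9, 0.9, 0.9))
  out <- apply_prefilter(edges, p_cut = 0.6, rescue = "h3<==>A")
  expect_equal(out$prefilter_ok, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$rescued, c(FALSE, FALSE, TRUE, FALSE))
  # microbe-microbe edges are out of the prefilter's scope
  expect_true(out$prefilter_ok[4])
})

test_that("class-specific BH adjustment matches hand values and the step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  edges <- data.frame(node_a = c("m1", "m2", "m3", "m4", "h1"),
                      node_b = c("h1", "h2", "h3", "m5", "h2"),
                      class = c(rep("microbe-host", 3),
                                "microbe-microbe", "host-host"),
                      sign_consistent = TRUE, causality_ok = TRUE,
                      fc_consistent = TRUE, prefilter_ok = TRUE,
                      rescued = FALSE,
                      meta_p = c(0.01, 0.02, 0.03, 0.2, 0.04),
                      stringsAsFactors = FALSE)
  edges$rho.g1 <- 0.5
  out <- fdr_by_class(edges)
  # classes are adjusted independently: singletons keep their own p
  expect_equal(out$fdr[4], 0.2)
  expect_equal(out$fdr[5], 0.04)
  expect_equal(out$fdr[1:3], bh_oracle(edges$meta_p[1:3]))
  expect_equal(out$kept, c(TRUE, TRUE, TRUE, FALSE, TRUE))

  # oracle equivalence across random vectors
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("the full cascade is audit-complete with ordered removal reasons", {
  set.seed(21)
  d <- generate_dataset(synthetic_config(seed = 21))
  microbes <- preprocess_microbes(d$counts, d$metadata)
  hosts <- suppressWarnings(normalize_host_by_cohort(d$host, d$metadata))
  features <- bind_features(microbes, hosts)
  back <- pmax(2^microbes$values - 1, 0)
  fc <- fold_change_records(cbind(back, d$host), d$metadata)
  edges <- suppressWarnings(correlate_features(features, d$metadata, fc))

  expect_equal(nrow(edges), choose(ncol(features$values), 2))
  expect_true(all(edges$removal_reason[!edges$kept] != ""))
  expect_true(all(edges$removal_reason[edges$kept] == ""))
  # recorded reason respects the documented predicate order
  expect_true(all(edges$removal_reason[!edges$sign_consistent &
                                       edges$removal_reason != "constant_feature"]
                  == "sign"))
  with_sign <- !edges$kept & edges$sign_consistent & !edges$causality_ok
  expect_true(all(edges$removal_reason[with_sign] == "causality"))
  # kept implies the full conjunction
  k <- edges[edges$kept, ]
  expect_true(all(k$sign_consistent & k$causality_ok & k$fc_consistent))
  expect_true(all(k$rescued | k$fdr < c("microbe-microbe" = 0.05,
                                        "microbe-host" = 0.15,
                                        "host-host" = 0.10)[k$class]))
  # average rho carries the common per-group sign when sign-consistent
  rmat <- as.matrix(edges[, grep("^rho\\.", names(edges))])
  sc <- which(edges$sign_consistent)
  expect_true(all(sign(edges$average_rho[sc]) == sign(rmat[sc, 1])))
})

test_that("planted edges pass the causality filter under their true directions", {
  # the generator's ground-truth invariant: a planted edge's sign equals the
  # product of the microbe's planted effect direction and the direction it
  # induces in the host parameter, so sign-consistent planted edges must
  # satisfy the coherence rule when judged against those directions
  for (s in c(31, 32, 33)) {
    d <- generate_dataset(synthetic_config(seed = s))
    md <- d$metadata
    part <- make_partition(md)
    lg <- log2(relativize_per_million(d$counts)$values + 1)
    for (i in seq_len(nrow(d$truth$planted_edges))) {
      e <- d$truth$planted_edges[i, ]
      da <- unname(d$truth$shifted_asv_ids[[e$microbe]])   # microbe direction
      db <- e$sign * da                                    # induced host direction
      rhos <- vapply(part, function(ss)
        suppressWarnings(cor(lg[ss, e$microbe], d$host[ss, e$host],
                             method = "spearman")), numeric(1))
      if (sign_consistency_filter(rhos)) {
        expect_equal(sign(mean(rhos)), e$sign)
        expect_true(causality_filter(mean(rhos), da, db))
      }
    }
  }
})
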