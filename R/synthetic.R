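#' Configuration for the synthetic two-experiment study generator
#'
#' Defaults mirror a replicated dietary-intervention microbiome study: two
#' independent experiments, control and treatment groups of ~8 mice, ~100
#' ASVs with a heavy-tailed (log-normal) rank-abundance curve, a set of
#' treatment-shifted ASVs with directions consistent across experiments, and
#' host parameters driven by planted "bottleneck" ASVs.
#'
#' @param n_experiments number of independent experiments (default 2).
#' @param n_samples_per_group samples per group per experiment (default 8).
#' @param n_asvs number of ASVs (default 100).
#' @param n_host_params number of host parameters (default 10).
#' @param n_shifted_asvs ASVs shifted by treatment (default 12).
#' @param effect_log2fc log2 fold shift applied to treatment samples'
#'   shifted ASVs (default 1.0).
#' @param n_bottlenecks how many shifted ASVs drive host parameters
#'   (default 1).
#' @param hub_link_count host parameters coupled to each bottleneck
#'   (default 4).
#' @param coupling_strength coefficient in (0, 1\] (0 allowed for null-signal
#'   simulations) linking host parameters to the standardized bottleneck
#'   log-abundance (default 0.8).
#' @param sequencing_depth multinomial reads per sample (default 50000).
#' @param batch_sd per-experiment log-scale offset sd (default 0.3); cohort
#'   offsets use `batch_sd / 2`.
#' @param noise_sd per-sample log-scale noise sd for ASVs and additive noise
#'   sd for host parameters (default 0.5).
#' @param n_cohorts_per_experiment birth cohorts per experiment (default 3).
#' @param seed integer seed.
#' @return a list of class `tk_config`.
#' @export
synthetic_config <- function(n_experiments = 2L, n_samples_per_group = 8L,
                             n_asvs = 100L, n_host_params = 10L,
                             n_shifted_asvs = 12L, effect_log2fc = 1.0,
                             n_bottlenecks = 1L, hub_link_count = 4L,
                             coupling_strength = 0.8,
                             sequencing_depth = 50000L, batch_sd = 0.3,
                             noise_sd = 0.5, n_cohorts_per_experiment = 3L,
                             seed = 1L) {
  cfg <- list(n_experiments = as.integer(n_experiments),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_asvs = as.integer(n_asvs),
              n_host_params = as.integer(n_host_params),
              n_shifted_asvs = as.integer(n_shifted_asvs),
              effect_log2fc = effect_log2fc,
              n_bottlenecks = as.integer(n_bottlenecks),
              hub_link_count = as.integer(hub_link_count),
              coupling_strength = coupling_strength,
              sequencing_depth = as.integer(sequencing_depth),
              batch_sd = batch_sd, noise_sd = noise_sd,
              n_cohorts_per_experiment = as.integer(n_cohorts_per_experiment),
              seed = as.integer(seed))
  with(cfg, {
    if (n_experiments < 1L || n_samples_per_group < 1L || n_asvs < 1L ||
        n_host_params < 1L)
      stop("dimensions must be positive")
    if (n_shifted_asvs > n_asvs) stop("n_shifted_asvs must not exceed n_asvs")
    if (n_bottlenecks > n_shifted_asvs)
      stop("n_bottlenecks must not exceed n_shifted_asvs")
    if (hub_link_count > n_host_params)
      stop("hub_link_count must not exceed n_host_params")
    if (coupling_strength < 0 || coupling_strength > 1)
      stop("coupling_strength must lie in [0, 1]")
    if (sequencing_depth < n_asvs)
      stop("sequencing_depth must be at least n_asvs")
  })
  structure(cfg, class = "tk_config")
}

synthetic_phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                     "Verrucomicrobia", "Tenericutes", "Actinobacteria")

#' Generate a synthetic two-experiment microbiome + host-phenotype dataset
#'
#' Plants a known ground-truth network: a log-normal baseline community
#' shared across experiments; treatment samples' shifted ASVs multiplied by
#' `2^(+/- effect_log2fc)` with identical directions in every experiment;
#' counts drawn by multinomial sampling at the configured depth (so each
#' sample's counts sum to the depth exactly); host parameters equal to
#' `coupling_strength` times the standardized bottleneck log2 abundance plus
#' Gaussian noise for linked parameters, pure noise otherwise. Per-experiment
#' batch offsets (sd `batch_sd`) and per-cohort offsets (sd `batch_sd/2`) are
#' added on the log scale; cohorts are assigned round-robin within each
#' experiment. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `counts` (a [asv_table()] with synthetic
#'   taxonomy), `host` (samples x parameters matrix), `metadata` (data.frame)
#'   and `truth` (shifted ASVs with signed effects, bottleneck ids, planted
#'   microbe-host edges with signs).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "tk_config"))
  cfg <- config
  with_seed_(cfg$seed, {
    asv_ids <- sprintf("ASV%03d", seq_len(cfg$n_asvs))
    host_ids <- sprintf("HP%02d", seq_len(cfg$n_host_params))

    # heavy-tailed baseline shared by all experiments; all latent abundances
    # live on the log2 scale so effect, batch and noise sds share units
    base_log <- stats::rnorm(cfg$n_asvs, mean = 0, sd = 1.5)
    names(base_log) <- asv_ids

    # plant shifts among the abundant-but-not-dominant ASVs: abundant enough
    # that bottleneck counts are rarely zero and rank correlations are
    # informative, but below the top of the rank-abundance curve so that
    # compositional closure (the community total changing with the shifts)
    # cannot cancel a planted direction
    ranked <- asv_ids[order(-base_log)]
    skip_top <- min(3L, max(0L, cfg$n_asvs - cfg$n_shifted_asvs))
    upper <- max(cfg$n_shifted_asvs + skip_top, ceiling(cfg$n_asvs / 2))
    eligible <- ranked[(skip_top + 1L):min(upper, cfg$n_asvs)]
    shifted <- sample(eligible, cfg$n_shifted_asvs)
    effect_sign <- sample(c(-1, 1), cfg$n_shifted_asvs, replace = TRUE)
    names(effect_sign) <- shifted
    bottlenecks <- shifted[seq_len(cfg$n_bottlenecks)]

    # host linkage: hub_link_count parameters per bottleneck, signed
    linked <- vector("list", cfg$n_bottlenecks)
    names(linked) <- bottlenecks
    free_params <- host_ids
    for (b in bottlenecks) {
      take <- sample(free_params, min(cfg$hub_link_count, length(free_params)))
      linked[[b]] <- stats::setNames(sample(c(-1, 1), length(take),
                                            replace = TRUE), take)
      free_params <- setdiff(free_params, take)
    }

    # sample layout
    exps <- sprintf("exp%d", seq_len(cfg$n_experiments))
    meta <- do.call(rbind, lapply(exps, function(ex) {
      n <- 2L * cfg$n_samples_per_group
      cohorts <- sprintf("%s_cohort%d", ex,
                         rep_len(seq_len(cfg$n_cohorts_per_experiment), n))
      data.frame(sample_id = sprintf("%s_s%02d", ex, seq_len(n)),
                 experiment = ex,
                 group = rep(c("control", "treatment"),
                             each = cfg$n_samples_per_group),
                 cohort = cohorts,
                 timepoint = "wk12",
                 stringsAsFactors = FALSE)
    }))
    rownames(meta) <- NULL

    batch_off <- stats::setNames(stats::rnorm(length(exps), 0, cfg$batch_sd), exps)
    cohort_levels <- unique(meta$cohort)
    cohort_off <- stats::setNames(
      stats::rnorm(length(cohort_levels), 0, cfg$batch_sd / 2), cohort_levels)

    # latent log2 abundances and multinomial counts
    n_samples <- nrow(meta)
    counts <- matrix(0, nrow = n_samples, ncol = cfg$n_asvs,
                     dimnames = list(meta$sample_id, asv_ids))
    for (i in seq_len(n_samples)) {
      lg <- base_log + batch_off[meta$experiment[i]] + cohort_off[meta$cohort[i]] +
        stats::rnorm(cfg$n_asvs, 0, cfg$noise_sd)
      if (meta$group[i] == "treatment")
        lg[shifted] <- lg[shifted] + effect_sign * cfg$effect_log2fc
      pr <- 2^lg; pr <- pr / sum(pr)
      counts[i, ] <- stats::rmultinom(1L, cfg$sequencing_depth, pr)[, 1L]
    }

    # host parameters from observed bottleneck abundance (log2, standardized)
    host <- matrix(NA_real_, nrow = n_samples, ncol = cfg$n_host_params,
                   dimnames = list(meta$sample_id, host_ids))
    base_level <- stats::setNames(stats::runif(cfg$n_host_params, 5, 15), host_ids)
    signal <- stats::setNames(rep(0, cfg$n_host_params), host_ids)
    driver_sign <- stats::setNames(rep(NA_real_, cfg$n_host_params), host_ids)
    planted_edges <- NULL
    for (b in bottlenecks) {
      z <- log2(counts[, b] + 1)
      z <- (z - mean(z)) / max(stats::sd(z), .Machine$double.eps)
      for (p in names(linked[[b]])) {
        s <- linked[[b]][[p]]
        driver_sign[p] <- s
        planted_edges <- rbind(planted_edges,
                               data.frame(microbe = b, host = p, sign = s,
                                          stringsAsFactors = FALSE))
      }
      for (p in names(linked[[b]]))
        host[, p] <- host_signal_for(b, p, linked, z, cfg)
    }
    for (p in host_ids) {
      noise <- stats::rnorm(n_samples, 0, cfg$noise_sd)
      sig <- if (is.na(driver_sign[p])) 0 else host[, p]
      host[, p] <- base_level[p] + sig + noise +
        cohort_off[meta$cohort]   # cohort effect (sd = batch_sd/2)
    }

    taxonomy <- stats::setNames(sprintf(
      "k__Bacteria;p__%s;c__;o__;f__;g__",
      sample(synthetic_phyla, cfg$n_asvs, replace = TRUE,
             prob = c(0.4, 0.3, 0.1, 0.08, 0.07, 0.05))), asv_ids)

    truth <- list(
      shifted_asv_ids = stats::setNames(as.numeric(effect_sign), shifted),
      bottleneck_ids = bottlenecks,
      planted_edges = planted_edges)

    list(counts = asv_table(counts, taxonomy),
         host = host,
         metadata = meta,
         truth = truth,
         config = cfg)
  })
}

# deterministic coupled signal: coupling * sign * z on the host scale
host_signal_for <- function(bottleneck, param, linked, z, cfg) {
  s <- linked[[bottleneck]][[param]]
  cfg$coupling_strength * s * z
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Writes `counts.tsv` (ASV rows x sample columns, integers), `host.csv`,
#' `metadata.csv`, `taxonomy.tsv` and `truth.json` into `directory`; the
#' files round-trip losslessly through [read_counts()], [read_host()],
#' [read_metadata()] and [read_taxonomy()].
#'
#' @param dataset list from [generate_dataset()].
#' @param directory output path (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(dataset, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  paths <- c(counts = file.path(directory, "counts.tsv"),
             host = file.path(directory, "host.csv"),
             metadata = file.path(directory, "metadata.csv"),
             taxonomy = file.path(directory, "taxonomy.tsv"),
             truth = file.path(directory, "truth.json"))

  cm <- t(dataset$counts$counts) # ASV rows x sample columns
  counts_df <- data.frame(asv_id = rownames(cm), cm, check.names = FALSE,
                          stringsAsFactors = FALSE)
  utils::write.table(counts_df, paths["counts"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  host_df <- data.frame(sample_id = rownames(dataset$host), dataset$host,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(host_df, paths["host"], row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$metadata, paths["metadata"], row.names = FALSE,
                   quote = FALSE)

  tax <- dataset$counts$taxonomy
  utils::write.table(data.frame(asv_id = names(tax), lineage = unname(tax),
                                stringsAsFactors = FALSE),
                     paths["taxonomy"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  jsonlite::write_json(
    list(shifted_asv_ids = as.list(dataset$truth$shifted_asv_ids),
         bottleneck_ids = dataset$truth$bottleneck_ids,
         planted_edges = dataset$truth$planted_edges),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(paths)
}
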