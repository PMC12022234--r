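#' Rand index between two partitions
#'
#' Fraction of sample pairs on which two partitions agree (both together or
#' both apart). 1 means identical clusterings.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2L) return(1)
  tab <- table(a, b)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * s_ij - s_a - s_b) / total
}

#' Run the full pipeline on one simulated dataset
#'
#' Consensus building, quality indexing, retention filtering, individual
#' clustering and the staged error report, plus the truth-side quantities
#' that only a simulation can provide: realised (truth-log) dropout and
#' false-allele frequencies on the estimator's own comparison sets, and the
#' clustering accuracy against true individual labels.
#'
#' @param sim A `sim_dataset`.
#' @param qi_threshold Retention threshold.
#' @param rule A [match_rule].
#' @return List with the fitted pipeline objects (`sc`, `iset`, `errors`)
#'   and a one-row `metrics` data frame: estimated and truth AD / AD_res /
#'   FA_res panel means, Rand index, individual counts.
#' @export
evaluate_simulation <- function(sim, qi_threshold = 0.5,
                                rule = match_rule()) {
  panel <- sim$config$panel
  loci <- autosomal_loci(panel)
  sc <- add_quality(consensus_dataset(sim$replicates, panel),
                    sim$replicates)
  flt <- filter_high_quality(sc, qi_threshold)
  iset <- cluster_individuals(flt$retained, rule)
  errors <- staged_error_report(sim$replicates, sc, iset, qi_threshold)

  # truth-side initial AD: each replicate observation against its own
  # source genotype (rows of replicates and truth_calls are aligned)
  auto <- sim$replicates$locus %in% loci
  cmp_truth <- data.frame(
    locus = sim$replicates$locus[auto],
    o1 = sim$replicates$allele_1[auto], o2 = sim$replicates$allele_2[auto],
    o_called = sim$replicates$status[auto] == "called",
    r1 = sim$truth_calls$allele_1[auto], r2 = sim$truth_calls$allele_2[auto],
    r_called = TRUE, stringsAsFactors = FALSE
  )
  ad_truth <- mean(allelic_dropout_rate(cmp_truth, loci)$ad, na.rm = TRUE)

  # truth-side residual rates: the estimator's recaptured sample
  # consensus calls against the true genotype of each sample's individual
  recap_ids <- iset$individuals$individual_id[iset$individuals$n_samples >= 2L]
  recap_samples <- iset$membership$sample_id[
    iset$membership$individual_id %in% recap_ids]
  ad_res_truth <- fa_res_truth <- NA_real_
  if (length(recap_samples)) {
    obs <- sc$calls[sc$calls$sample_id %in% recap_samples &
                      sc$calls$locus %in% loci, , drop = FALSE]
    obs$true_ind <- sim$samples$individual_id[
      match(obs$sample_id, sim$samples$sample_id)]
    ref <- sim$truth$genotypes
    ref$status <- "called"
    cmp_res <- stage_comparisons(obs, ref, obs_key = "true_ind",
                                 ref_key = "individual_id")
    ad_res_truth <- mean(allelic_dropout_rate(cmp_res, loci)$ad,
                         na.rm = TRUE)
    fa_res_truth <- mean(false_allele_rate(cmp_res, loci)$fa, na.rm = TRUE)
  }

  retained_ids <- flt$retained$samples$sample_id
  est_lab <- iset$membership$individual_id[
    match(retained_ids, iset$membership$sample_id)]
  true_lab <- sim$samples$individual_id[
    match(retained_ids, sim$samples$sample_id)]
  metrics <- data.frame(
    n_samples = nrow(sim$samples), n_retained = length(retained_ids),
    ad_est = errors$means$ad, ad_truth = ad_truth,
    ad_high_est = errors$means$ad_high,
    ad_res_est = errors$means$ad_res, ad_res_truth = ad_res_truth,
    fa_res_est = errors$means$fa_res, fa_res_truth = fa_res_truth,
    rand = rand_index(est_lab, true_lab),
    n_individuals_est = nrow(iset$individuals),
    n_individuals_true = length(unique(true_lab))
  )
  list(sc = sc, iset = iset, errors = errors, metrics = metrics)
}

#' Parameter-recovery experiment over replicated simulated datasets
#'
#' Simulates `n_datasets` independent datasets under one configuration,
#' runs the full pipeline on each, and summarises how well the staged error
#' estimators recover the realised truth-log event frequencies and how
#' accurately clustering recovers the true individuals. The Monte-Carlo
#' standard error of each mean estimate is `sd / sqrt(n_datasets)`.
#'
#' @param config A [sim_config].
#' @param n_datasets Number of datasets (>= 10 recommended).
#' @param seed Integer seed; per-dataset seeds are drawn from it.
#' @param qi_threshold,rule Passed to [evaluate_simulation()].
#' @return List `per_dataset` (metrics data frame, one row per dataset) and
#'   `summary` (for AD, AD_res, FA_res: mean estimate, mean truth
#'   frequency, bias, Monte-Carlo SE; plus mean Rand index).
#' @export
recovery_experiment <- function(config, n_datasets = 10L, seed = 1L,
                                qi_threshold = 0.5, rule = match_rule()) {
  stopifnot(n_datasets >= 1L)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_datasets)
  per <- do.call(rbind, lapply(seq_len(n_datasets), function(i) {
    sim <- simulate_dataset(config, seeds[i])
    cbind(dataset = i, evaluate_simulation(sim, qi_threshold, rule)$metrics)
  }))
  stat <- function(est, truth) {
    est <- est[!is.na(est)]; truth <- truth[!is.na(truth)]
    list(mean_est = mean(est), mean_truth = mean(truth),
         bias = mean(est) - mean(truth),
         mc_se = stats::sd(est) / sqrt(length(est)))
  }
  list(per_dataset = per,
       summary = list(
         ad = stat(per$ad_est, per$ad_truth),
         ad_res = stat(per$ad_res_est, per$ad_res_truth),
         fa_res = stat(per$fa_res_est, per$fa_res_truth),
         mean_rand = mean(per$rand),
         n_datasets = n_datasets))
}
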