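#' Classify genotype observations against a reference genotype
#'
#' Event taxonomy for replicated genotyping: comparing an observed call to a
#' reference (the sample consensus, or the individual consensus for
#' residual rates) at one locus,
#' * `AD` (allelic dropout): the reference is heterozygous and the
#'   observation is homozygous for exactly one reference allele;
#' * `FA` (false allele): the observation contains at least one allele
#'   absent from the reference -- including a homozygote for a foreign
#'   allele and a heterozygote sharing only one allele with a heterozygous
#'   reference (the foreign allele is the event);
#' * `match`: the observation equals the reference;
#' * `uncompared`: observation or reference not called.
#'
#' @param o1,o2 Observed allele pair (canonical order).
#' @param o_called Logical, observation called.
#' @param r1,r2 Reference allele pair.
#' @param r_called Logical, reference called.
#' @return Character vector of event classes.
#' @export
classify_events <- function(o1, o2, o_called, r1, r2, r_called) {
  ev <- rep("uncompared", length(o1))
  both <- o_called & r_called
  exact <- both & o1 == r1 & o2 == r2
  foreign <- both & !exact & ((o1 != r1 & o1 != r2) | (o2 != r1 & o2 != r2))
  ad <- both & !exact & !foreign & r1 != r2 & o1 == o2
  ev[exact] <- "match"
  ev[foreign] <- "FA"
  ev[ad] <- "AD"
  # remaining called disagreements (none possible for diploid pairs, kept
  # as a guard): treat as FA
  rest <- both & !exact & !foreign & !ad
  ev[rest] <- "FA"
  ev
}

#' Per-locus allelic dropout rate
#'
#' Dropout rate in the sense of replicate-versus-consensus comparison:
#' the number of observed AD events divided by the number of successful
#' amplifications, counting only comparisons whose reference genotype is
#' heterozygous. A locus with no such comparisons has an undefined (NA)
#' rate, never 0.
#'
#' @param comparisons Data frame with columns `locus`, `o1`, `o2`,
#'   `o_called`, `r1`, `r2`, `r_called` (see [stage_comparisons()]).
#' @param loci Locus names to report (rates for loci absent from
#'   `comparisons` are NA).
#' @return Data frame `locus`, `ad`, `n_ad` (events), `n_obs` (denominator).
#' @export
allelic_dropout_rate <- function(comparisons, loci = unique(comparisons$locus)) {
  het <- comparisons$r_called & comparisons$r1 != comparisons$r2
  use <- het & comparisons$o_called
  ev <- classify_events(comparisons$o1, comparisons$o2, comparisons$o_called,
                        comparisons$r1, comparisons$r2, comparisons$r_called)
  f <- factor(comparisons$locus[use], levels = loci)
  denom <- as.integer(table(f))
  num <- as.integer(table(factor(comparisons$locus[use & ev == "AD"],
                                 levels = loci)))
  data.frame(locus = loci, ad = ifelse(denom > 0, num / denom, NA_real_),
             n_ad = num, n_obs = denom, stringsAsFactors = FALSE)
}

#' Per-locus false allele rate
#'
#' The number of observations containing at least one allele absent from
#' the reference genotype, divided by the number of successful
#' amplifications at reference-called loci. Undefined (NA) when a locus has
#' no comparisons.
#'
#' @inheritParams allelic_dropout_rate
#' @return Data frame `locus`, `fa`, `n_fa`, `n_obs`.
#' @export
false_allele_rate <- function(comparisons, loci = unique(comparisons$locus)) {
  use <- comparisons$r_called & comparisons$o_called
  ev <- classify_events(comparisons$o1, comparisons$o2, comparisons$o_called,
                        comparisons$r1, comparisons$r2, comparisons$r_called)
  f <- factor(comparisons$locus[use], levels = loci)
  denom <- as.integer(table(f))
  num <- as.integer(table(factor(comparisons$locus[use & ev == "FA"],
                                 levels = loci)))
  data.frame(locus = loci, fa = ifelse(denom > 0, num / denom, NA_real_),
             n_fa = num, n_obs = denom, stringsAsFactors = FALSE)
}

#' Build observation-versus-reference comparison tables
#'
#' Aligns an observation table (replicate calls, or sample consensus calls)
#' with a reference genotype per sample (sample consensus, or individual
#' consensus) into the flat comparison layout consumed by
#' [allelic_dropout_rate()] and [false_allele_rate()].
#'
#' @param obs Data frame with `sample_id`, `locus`, `allele_1`, `allele_2`,
#'   `status` (and optionally `replicate`).
#' @param ref Data frame with `locus`, `allele_1`, `allele_2`, `status` and
#'   a key column named by `ref_key` matching `obs_key` in `obs`.
#' @param obs_key,ref_key Join key column names (default `sample_id`).
#' @return Comparison data frame with the event coordinates preserved.
#' @export
stage_comparisons <- function(obs, ref, obs_key = "sample_id",
                              ref_key = "sample_id") {
  idx <- match(paste(obs[[obs_key]], obs$locus, sep = "\r"),
               paste(ref[[ref_key]], ref$locus, sep = "\r"))
  data.frame(
    sample_id = obs$sample_id,
    replicate = if ("replicate" %in% names(obs)) obs$replicate else NA_integer_,
    locus = obs$locus,
    o1 = obs$allele_1, o2 = obs$allele_2,
    o_called = obs$status == "called",
    r1 = ref$allele_1[idx], r2 = ref$allele_2[idx],
    r_called = !is.na(idx) & ref$status[idx] == "called",
    stringsAsFactors = FALSE
  )
}

#' Staged genotyping-error report
#'
#' The full error-rate cascade of a multitube dataset, per autosomal locus:
#' * `pcr_success`: called replicate observations / attempted;
#' * `ad`: initial allelic dropout, replicates of all samples vs their
#'   sample consensus;
#' * `ad_high`: same, restricted to replicates of high-quality
#'   (QI > threshold), uncontaminated samples;
#' * `ad_res`, `fa_res`: residual rates, sample consensus genotypes of
#'   recaptured individuals (>= 2 samples) vs the individual consensus.
#'
#' Panel means are unweighted means over loci with estimable (non-NA)
#' rates. An event log with the coordinates of every counted AD/FA event
#' accompanies the table.
#'
#' @param replicates Replicate data frame.
#' @param sc Quality-filled `sample_consensus` (all genotyped samples).
#' @param iset Optional `individual_set` for the residual stage; without
#'   recaptured individuals the residual rates are NA.
#' @param qi_threshold QI cutoff defining high-quality samples (default 0.5).
#' @return An `error_rate_table`: list with `per_locus` (data frame),
#'   `means`, `n_recaptured_samples`, `events` (log data frame).
#' @export
staged_error_report <- function(replicates, sc, iset = NULL,
                                qi_threshold = 0.5) {
  stopifnot(inherits(sc, "sample_consensus"))
  panel <- sc$panel
  loci <- autosomal_loci(panel)
  replicates <- complete_replicates(replicates, panel)
  auto_rep <- replicates[replicates$locus %in% loci, , drop = FALSE]

  pcr <- tapply(auto_rep$status == "called",
                factor(auto_rep$locus, levels = loci), mean)

  cmp_all <- stage_comparisons(auto_rep, sc$calls)
  ad_all <- allelic_dropout_rate(cmp_all, loci)

  hq_ids <- sc$samples$sample_id[sc$samples$mean_qi > qi_threshold &
                                   !sc$samples$contaminated]
  cmp_high <- cmp_all[cmp_all$sample_id %in% hq_ids, , drop = FALSE]
  ad_high <- allelic_dropout_rate(cmp_high, loci)

  n_recap <- 0L
  if (!is.null(iset)) {
    recap_ids <- iset$individuals$individual_id[iset$individuals$n_samples >= 2L]
    recap_samples <- iset$membership$sample_id[
      iset$membership$individual_id %in% recap_ids]
    n_recap <- length(recap_samples)
  }
  if (n_recap > 0L) {
    obs <- sc$calls[sc$calls$sample_id %in% recap_samples &
                      sc$calls$locus %in% loci, , drop = FALSE]
    obs$individual_id <- iset$membership$individual_id[
      match(obs$sample_id, iset$membership$sample_id)]
    cmp_res <- stage_comparisons(obs, iset$consensus,
                                 obs_key = "individual_id",
                                 ref_key = "individual_id")
    ad_res <- allelic_dropout_rate(cmp_res, loci)
    fa_res <- false_allele_rate(cmp_res, loci)
  } else {
    na_tab <- data.frame(locus = loci, rate = NA_real_, n = NA_integer_,
                         n_obs = NA_integer_)
    ad_res <- stats::setNames(na_tab, c("locus", "ad", "n_ad", "n_obs"))
    fa_res <- stats::setNames(na_tab, c("locus", "fa", "n_fa", "n_obs"))
    cmp_res <- NULL
  }

  per_locus <- data.frame(
    locus = loci,
    pcr_success = as.numeric(pcr),
    ad = ad_all$ad, ad_n = ad_all$n_ad, ad_obs = ad_all$n_obs,
    ad_high = ad_high$ad, ad_high_n = ad_high$n_ad,
    ad_high_obs = ad_high$n_obs,
    ad_res = ad_res$ad, ad_res_n = ad_res$n_ad, ad_res_obs = ad_res$n_obs,
    fa_res = fa_res$fa, fa_res_n = fa_res$n_fa, fa_res_obs = fa_res$n_obs,
    stringsAsFactors = FALSE
  )
  means <- list(
    pcr_success = mean(per_locus$pcr_success),
    ad = mean(per_locus$ad, na.rm = TRUE),
    ad_high = mean(per_locus$ad_high, na.rm = TRUE),
    ad_res = if (all(is.na(per_locus$ad_res))) NA_real_ else
      mean(per_locus$ad_res, na.rm = TRUE),
    fa_res = if (all(is.na(per_locus$fa_res))) NA_real_ else
      mean(per_locus$fa_res, na.rm = TRUE)
  )

  log_events <- function(cmp, stage) {
    if (is.null(cmp)) return(NULL)
    ev <- classify_events(cmp$o1, cmp$o2, cmp$o_called,
                          cmp$r1, cmp$r2, cmp$r_called)
    keep <- ev %in% c("AD", "FA") &
      (ev != "AD" | (cmp$r_called & cmp$r1 != cmp$r2))
    if (!any(keep)) return(NULL)
    data.frame(stage = stage, sample_id = cmp$sample_id[keep],
               replicate = cmp$replicate[keep], locus = cmp$locus[keep],
               event = ev[keep], stringsAsFactors = FALSE)
  }
  events <- rbind(log_events(cmp_all, "initial"),
                  log_events(cmp_res, "residual"))

  structure(list(per_locus = per_locus, means = means,
                 n_recaptured_samples = n_recap,
                 events = if (is.null(events))
                   data.frame(stage = character(0), sample_id = character(0),
                              replicate = integer(0), locus = character(0),
                              event = character(0)) else events),
            class = "error_rate_table")
}

#' @export
print.error_rate_table <- function(x, ...) {
  m <- x$means
  cat("<error_rate_table> panel means: PCR success ",
      sprintf("%.3f", m$pcr_success), ", AD ", sprintf("%.3f", m$ad),
      ", AD_high ", sprintf("%.3f", m$ad_high), ", AD_res ",
      ifelse(is.na(m$ad_res), "NA", sprintf("%.3f", m$ad_res)),
      ", FA_res ",
      ifelse(is.na(m$fa_res), "NA", sprintf("%.3f", m$fa_res)),
      " (", x$n_recaptured_samples, " recaptured samples)\n", sep = "")
  invisible(x)
}
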