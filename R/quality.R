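#' Score one replicate call against the sample consensus
#'
#' Miquel-style agreement score: 1 if the replicate genotype matches the
#' consensus genotype at the locus, 0.5 if the replicate shows an allelic
#' dropout of a heterozygous consensus (homozygous for one consensus
#' allele -- the replicate still carries usable information), 0 if the
#' replicate is missing, disputed, contaminated, or disagrees in any other
#' way (a disagreement with a homozygous consensus is a corrected false
#' allele, not a dropout, and scores 0).
#'
#' @param replicate_call,consensus_call [genotype_call] objects at the same
#'   locus, the consensus taken from the replicate's own sample.
#' @return 1, 0.5 or 0.
#' @export
score_replicate_locus <- function(replicate_call, consensus_call) {
  stopifnot(inherits(replicate_call, "genotype_call"),
            inherits(consensus_call, "genotype_call"))
  score_calls(replicate_call$allele_1, replicate_call$allele_2,
              replicate_call$status == "called",
              consensus_call$allele_1, consensus_call$allele_2,
              consensus_call$status == "called")
}

# vectorised scoring kernel
score_calls <- function(r1, r2, r_called, c1, c2, c_called) {
  score <- numeric(length(r1))
  both <- r_called & c_called
  exact <- both & r1 == c1 & r2 == c2
  ad <- both & !exact & c1 != c2 & r1 == r2 & (r1 == c1 | r1 == c2)
  score[exact] <- 1
  score[ad] <- 0.5
  score
}

#' Fill per-locus quality scores and per-sample mean QI
#'
#' For each sample x locus, the quality score is the mean replicate score
#' (each replicate scored against the sample's consensus); the sample's
#' quality index (QI) is the mean of these scores over all autosomal panel
#' loci, from 0 (poor quality: nothing amplified) to 1 (every replicate
#' reproduced the consensus everywhere). Loci with a missing consensus score
#' 0 for every replicate, so pervasive amplification failure drags QI down.
#'
#' @param sc A `sample_consensus` from [consensus_dataset()].
#' @param replicates The replicate data frame the consensus was built from.
#' @return `sc` with `calls$qi` and `samples$mean_qi` filled.
#' @export
add_quality <- function(sc, replicates) {
  stopifnot(inherits(sc, "sample_consensus"))
  replicates <- complete_replicates(replicates, sc$panel)
  key_r <- paste(replicates$sample_id, replicates$locus, sep = "\r")
  key_c <- paste(sc$calls$sample_id, sc$calls$locus, sep = "\r")
  idx <- match(key_r, key_c)
  score <- score_calls(replicates$allele_1, replicates$allele_2,
                       replicates$status == "called",
                       sc$calls$allele_1[idx], sc$calls$allele_2[idx],
                       sc$calls$status[idx] == "called")
  qi <- tapply(score, key_r, mean)
  sc$calls$qi <- as.numeric(qi[key_c])
  auto <- sc$calls$locus %in% autosomal_loci(sc$panel)
  mean_qi <- tapply(sc$calls$qi[auto], sc$calls$sample_id[auto], mean)
  sc$samples$mean_qi <- as.numeric(mean_qi[sc$samples$sample_id])
  sc
}

#' Per-locus PCR success and quality summary
#'
#' PCR success per locus is the number of successful amplifications (called
#' replicate x locus observations) divided by the number attempted (all
#' replicate x locus observations). Per-locus QI aggregates the replicate
#' agreement scores across all replicates of all samples.
#'
#' @param sc A quality-filled `sample_consensus` (see [add_quality()]).
#' @param replicates The replicate data frame.
#' @return List with `per_locus` (data frame `locus`, `pcr_success`,
#'   `mean_qi`, `n_attempted`), `mean_pcr_success`, `mean_qi` (means over
#'   autosomal loci), and `per_sample` (sample id, mean QI).
#' @export
quality_summary <- function(sc, replicates) {
  stopifnot(inherits(sc, "sample_consensus"))
  if (anyNA(sc$samples$mean_qi)) sc <- add_quality(sc, replicates)
  replicates <- complete_replicates(replicates, sc$panel)
  key_c <- paste(sc$calls$sample_id, sc$calls$locus, sep = "\r")
  idx <- match(paste(replicates$sample_id, replicates$locus, sep = "\r"),
               key_c)
  score <- score_calls(replicates$allele_1, replicates$allele_2,
                       replicates$status == "called",
                       sc$calls$allele_1[idx], sc$calls$allele_2[idx],
                       sc$calls$status[idx] == "called")
  loci <- sc$panel$name
  f <- factor(replicates$locus, levels = loci)
  per_locus <- data.frame(
    locus = loci,
    pcr_success = as.numeric(tapply(replicates$status == "called", f, mean)),
    mean_qi = as.numeric(tapply(score, f, mean)),
    n_attempted = as.integer(tapply(score, f, length)),
    stringsAsFactors = FALSE
  )
  auto <- per_locus$locus %in% autosomal_loci(sc$panel)
  list(per_locus = per_locus,
       mean_pcr_success = mean(per_locus$pcr_success[auto]),
       mean_qi = mean(per_locus$mean_qi[auto]),
       per_sample = sc$samples[, c("sample_id", "mean_qi")])
}

#' Retain high-quality, uncontaminated samples
#'
#' The retention filter ahead of individual identification: keep samples
#' with mean QI strictly above the threshold and no evidence of
#' contamination. A sample at exactly the threshold is excluded.
#'
#' @param sc A quality-filled `sample_consensus`.
#' @param qi_threshold QI cutoff in `[0, 1]` (default 0.5).
#' @return List with `retained` (a `sample_consensus` restricted to the
#'   retained samples), `n_retained`, `retention_percent` (one-decimal,
#'   denominator = genotyped samples).
#' @export
filter_high_quality <- function(sc, qi_threshold = 0.5) {
  stopifnot(inherits(sc, "sample_consensus"))
  if (!is.numeric(qi_threshold) || qi_threshold < 0 || qi_threshold > 1) {
    stop("qi_threshold must be in [0, 1]")
  }
  if (anyNA(sc$samples$mean_qi)) {
    stop("mean QI not computed; call add_quality() first")
  }
  keep <- sc$samples$mean_qi > qi_threshold & !sc$samples$contaminated
  ids <- sc$samples$sample_id[keep]
  retained <- sc
  retained$samples <- sc$samples[keep, , drop = FALSE]
  retained$calls <- sc$calls[sc$calls$sample_id %in% ids, , drop = FALSE]
  rownames(retained$samples) <- rownames(retained$calls) <- NULL
  list(retained = retained, n_retained = length(ids),
       retention_percent = percent_of(length(ids), nrow(sc$samples)))
}
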