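#' Build per-sample consensus genotypes from replicate calls
#'
#' Multitube consensus rule: every allele observed in any called replicate of
#' a sample is treated as a true allele of that sample (false alleles are
#' assumed corrected at electropherogram scoring), so the consensus at a
#' locus is the set of distinct alleles pooled across its called replicates.
#' One distinct allele gives a homozygote, two a heterozygote, none a missing
#' call. More than two distinct alleles at a locus is biologically impossible
#' for one diploid individual, so the sample is flagged contaminated --
#' whether the excess arises within a single replicate (the `contaminated`
#' input status scored at reading) or only when pooling across replicates.
#' Contaminated samples are excluded from all downstream matching and
#' diversity stages. Disputed calls count as missing.
#'
#' @param replicates Canonical replicate data frame (see
#'   [read_replicate_table()]), already completed to the full panel.
#' @param panel The active [locus_panel].
#' @return A `sample_consensus` object: list with
#'   * `calls`: data frame `sample_id`, `locus`, `allele_1`, `allele_2`,
#'     `status`, `qi` (per-locus quality score, `NA` until
#'     [add_quality()] fills it);
#'   * `samples`: data frame `sample_id`, `n_replicates`, `contaminated`,
#'     `mean_qi`;
#'   * `panel`.
#' @seealso [build_consensus()] for the single-sample contract,
#'   [consensus_counts()] for dataset-level summaries.
#' @export
consensus_dataset <- function(replicates, panel) {
  stopifnot(inherits(panel, "locus_panel"))
  if (nrow(replicates) == 0L) {
    calls <- data.frame(sample_id = character(0), locus = character(0),
                        allele_1 = integer(0), allele_2 = integer(0),
                        status = character(0), qi = numeric(0))
    samples <- data.frame(sample_id = character(0), n_replicates = integer(0),
                          contaminated = logical(0), mean_qi = numeric(0))
    return(structure(list(calls = calls, samples = samples, panel = panel),
                     class = "sample_consensus"))
  }
  replicates <- complete_replicates(replicates, panel)
  sample_ids <- sort(unique(replicates$sample_id))

  n_rep <- tapply(replicates$replicate, replicates$sample_id,
                  function(r) length(unique(r)))
  n_rep <- as.integer(n_rep[sample_ids])

  # distinct alleles per (sample, locus), pooled over called replicates
  called <- replicates[replicates$status == "called", , drop = FALSE]
  al <- unique(rbind(
    data.frame(sample_id = called$sample_id, locus = called$locus,
               allele = called$allele_1, stringsAsFactors = FALSE),
    data.frame(sample_id = called$sample_id, locus = called$locus,
               allele = called$allele_2, stringsAsFactors = FALSE)
  ))
  key <- paste(al$sample_id, al$locus, sep = "\r")
  n_alleles <- tapply(al$allele, key, length)
  a_min <- tapply(al$allele, key, min)
  a_max <- tapply(al$allele, key, max)

  grid <- expand.grid(locus = panel$name, sample_id = sample_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("sample_id", "locus")]
  gkey <- paste(grid$sample_id, grid$locus, sep = "\r")
  cnt <- n_alleles[gkey]
  cnt[is.na(cnt)] <- 0L
  calls <- data.frame(
    sample_id = grid$sample_id, locus = grid$locus,
    allele_1 = ifelse(cnt %in% 1:2, as.integer(a_min[gkey]), NA_integer_),
    allele_2 = ifelse(cnt %in% 1:2, as.integer(a_max[gkey]), NA_integer_),
    status = ifelse(cnt %in% 1:2, "called", "missing"),
    qi = NA_real_, stringsAsFactors = FALSE
  )

  over2 <- unique(grid$sample_id[cnt > 2L])
  flagged_input <- unique(replicates$sample_id[replicates$status ==
                                                 "contaminated"])
  contaminated <- sample_ids %in% c(over2, flagged_input)

  samples <- data.frame(sample_id = sample_ids, n_replicates = n_rep,
                        contaminated = contaminated, mean_qi = NA_real_,
                        stringsAsFactors = FALSE)
  structure(list(calls = calls, samples = samples, panel = panel),
            class = "sample_consensus")
}

#' Consensus genotype for a single sample
#'
#' @param replicates Replicate data frame for exactly one sample (1-4
#'   replicates).
#' @param panel The active [locus_panel].
#' @return A single-sample `sample_consensus`.
#' @export
build_consensus <- function(replicates, panel) {
  if (is.null(replicates) || nrow(replicates) == 0L) {
    stop("at least one replicate is required")
  }
  if (length(unique(replicates$sample_id)) != 1L) {
    stop("replicates mix sample ids: ",
         paste(unique(replicates$sample_id), collapse = ", "))
  }
  consensus_dataset(replicates, panel)
}

#' Dataset-level consensus counts
#'
#' Tallies the genotyping funnel of a consensus dataset: samples with no
#' amplification at any locus, contaminated samples, and the remainder.
#' Percentages use the genotyped-samples denominator and the one-decimal
#' reporting convention.
#'
#' @param sc A `sample_consensus`.
#' @return List with `n_samples`, `no_amplification`, `contaminated`,
#'   `retained`, each of the latter a `c(count, percent)` pair.
#' @export
consensus_counts <- function(sc) {
  stopifnot(inherits(sc, "sample_consensus"))
  n <- nrow(sc$samples)
  if (n == 0L) {
    zero <- c(count = 0L, percent = NA_real_)
    return(list(n_samples = 0L, no_amplification = zero,
                contaminated = zero, retained = zero))
  }
  all_missing <- tapply(sc$calls$status == "missing", sc$calls$sample_id, all)
  all_missing <- all_missing[sc$samples$sample_id]
  no_amp <- sum(all_missing & !sc$samples$contaminated)
  contam <- sum(sc$samples$contaminated)
  retained <- n - no_amp - contam
  mk <- function(k) c(count = k, percent = percent_of(k, n))
  list(n_samples = n, no_amplification = mk(no_amp),
       contaminated = mk(contam), retained = mk(retained))
}

#' @export
print.sample_consensus <- function(x, ...) {
  cat("<sample_consensus> ", nrow(x$samples), " samples x ",
      nrow(x$panel), " loci; ", sum(x$samples$contaminated),
      " contaminated\n", sep = "")
  invisible(x)
}
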