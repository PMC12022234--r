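#' Run the full monitoring workflow
#'
#' Orchestrates the analysis stages in their canonical order -- mtDNA
#' species screen (optional), sample consensus, quality indexing, QI
#' retention filter, individual clustering, staged error rates, population
#' diversity -- and records a machine-readable manifest with the seed,
#' configuration and the sample-count funnel through the stages.
#'
#' @param replicates Replicate data frame (see [read_replicate_table()]).
#' @param panel A [locus_panel].
#' @param meta Optional sample metadata.
#' @param seqs Optional named character vector of control-region consensus
#'   sequences; with `refs`, samples not assigned to a wolf-specific
#'   mitotype are dropped before genotype analysis.
#' @param refs Optional mitotype reference panel
#'   (see [read_haplotype_panel()]).
#' @param qi_threshold QI retention threshold (default 0.5).
#' @param rule A [match_rule].
#' @param n_perm Permutations for the Hardy-Weinberg tests.
#' @param seed Integer seed for the permutation/bootstrap stages.
#' @param out_dir Optional directory; when given, stage outputs and
#'   `manifest.json` are written there.
#' @return A `pipeline_result` list: `screen`, `sc`, `counts`, `quality`,
#'   `filter`, `iset`, `errors`, `diversity`, `manifest`.
#' @export
run_pipeline <- function(replicates, panel, meta = NULL, seqs = NULL,
                         refs = NULL, qi_threshold = 0.5,
                         rule = match_rule(), n_perm = 1000L, seed = 1L,
                         out_dir = NULL) {
  n_submitted <- length(unique(replicates$sample_id))
  screen <- NULL
  if (!is.null(seqs) && !is.null(refs)) {
    screen <- screen_mitotypes(seqs, refs)
    wolf_ids <- screen$assignments$sample_id[
      screen$assignments$verdict == "wolf"]
    replicates <- replicates[replicates$sample_id %in% wolf_ids, ,
                             drop = FALSE]
    if (nrow(replicates) == 0L) stop("mtdna screen retained no samples")
  }

  sc <- add_quality(consensus_dataset(replicates, panel), replicates)
  counts <- consensus_counts(sc)
  quality <- quality_summary(sc, replicates)
  flt <- filter_high_quality(sc, qi_threshold)
  if (flt$n_retained == 0L) stop("quality filter retained no samples")
  iset <- cluster_individuals(flt$retained, rule, meta = meta)
  errors <- staged_error_report(replicates, sc, iset, qi_threshold)
  diversity <- diversity_report(iset, panel, n_perm = n_perm, seed = seed)

  manifest <- list(
    seed = seed,
    config = list(qi_threshold = qi_threshold,
                  min_shared_loci = rule$min_shared_loci,
                  max_mismatches = rule$max_mismatches, n_perm = n_perm,
                  n_loci = nrow(panel)),
    funnel = list(
      submitted = n_submitted,
      species_identified = if (is.null(screen)) n_submitted else
        length(unique(replicates$sample_id)),
      genotyped = counts$n_samples,
      retained = flt$n_retained,
      individuals = nrow(iset$individuals)
    ),
    captures = capture_summary(iset)
  )

  res <- structure(list(screen = screen, sc = sc, counts = counts,
                        quality = quality, filter = flt, iset = iset,
                        errors = errors, diversity = diversity,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' Write pipeline stage outputs
#'
#' @param res A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  tsv <- function(x, f) utils::write.table(x, p(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  if (!is.null(res$screen)) tsv(res$screen$assignments, "mitotypes.tsv")
  write_consensus_table(res$sc, p("consensus.tsv"))
  tsv(res$quality$per_locus, "quality_per_locus.tsv")
  tsv(res$iset$individuals, "individuals.tsv")
  tsv(res$iset$membership, "membership.tsv")
  tsv(res$errors$per_locus, "error_rates.tsv")
  tsv(res$diversity$per_locus, "diversity.tsv")
  write_genepop(res$iset, res$iset$panel, p("individuals.genepop.txt"))
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  f <- x$manifest$funnel
  cat("<pipeline_result> funnel: submitted ", f$submitted,
      " -> species-identified ", f$species_identified, " -> genotyped ",
      f$genotyped, " -> retained ", f$retained, " -> individuals ",
      f$individuals, "\n", sep = "")
  invisible(x)
}

#' Path to the bundled French wolf per-locus diversity reference table
#'
#' Published per-locus diversity statistics (allele counts, observed and
#' expected heterozygosity, FIS) for the 22-locus French gray wolf
#' monitoring panel, used as an aggregation example and as the default
#' allele-count template for the simulator.
#'
#' @return File path of the bundled tab-separated table.
#' @export
french_wolf_diversity <- function() {
  system.file("extdata", "french_wolf_diversity.tsv", package = "nivgeno",
              mustWork = TRUE)
}
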