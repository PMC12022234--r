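# small panels and replicate-table builders used across the suite

tiny_panel <- function(n_auto = 4L, sex = TRUE) {
  nm <- c(paste0("L", seq_len(n_auto)), if (sex) "AMEL")
  locus_panel(nm, size_min = 100L, size_max = 140L,
              is_sex_marker = c(rep(FALSE, n_auto), if (sex) TRUE))
}

# build a replicate data frame from vectors; NA alleles -> missing status
reps_df <- function(sample_id, replicate, locus, a1, a2,
                    status = NULL) {
  if (is.null(status)) {
    status <- ifelse(is.na(a1), "missing", "called")
  }
  data.frame(sample_id = sample_id, replicate = as.integer(replicate),
             locus = locus,
             allele_1 = ifelse(status == "called", pmin(a1, a2),
                               NA_integer_),
             allele_2 = ifelse(status == "called", pmax(a1, a2),
                               NA_integer_),
             status = status, stringsAsFactors = FALSE)
}

# single-sample consensus-style call table
call_df <- function(locus, a1 = NA, a2 = NA, status = NULL,
                    sample_id = "s1") {
  d <- reps_df(sample_id, 1L, locus, a1, a2, status)
  d$replicate <- NULL
  d
}

# one fully-called genotype on every autosomal locus of a panel
full_sample_reps <- function(sample_id, panel, base = 120L,
                             replicate = 1L) {
  loci <- panel$name
  reps_df(sample_id, replicate, loci, rep(base, length(loci)),
          rep(base + 4L, length(loci)))
}

# quality-filled consensus for a replicate table
quick_sc <- function(replicates, panel) {
  add_quality(consensus_dataset(replicates, panel), replicates)
}
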