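#' Assign a control-region consensus sequence to a mitotype
#'
#' Offline species and lineage assignment: the query is compared to every
#' reference haplotype by Hamming distance over the common aligned length
#' (references are curated equal-length control-region haplotypes, ~605 bp;
#' the query is trimmed to the overlap). `N` matches any base. The verdict
#' follows the specificity of the best-matching reference:
#' `wolf` (haplotype specific to gray wolves; sample retained downstream),
#' `canis_sp` (haplotype shared by domestic dog and gray wolf; cannot be
#' confidently attributed to wolf), `non_target` (another species), or
#' `unidentified` (sequence too short, too divergent, or tied between
#' references of different identity).
#'
#' @param seq Query DNA sequence (character scalar, A/C/G/T/N).
#' @param refs Reference panel data frame from [read_haplotype_panel()].
#' @param max_mismatch Maximum accepted Hamming distance (default 2).
#' @param min_length Minimum query length to attempt identification
#'   (default 500 bp).
#' @return A one-row data frame: `best_match`, `distance`, `verdict`.
#' @export
assign_mitotype <- function(seq, refs, max_mismatch = 2L, min_length = 500L) {
  stopifnot(is.data.frame(refs), nrow(refs) >= 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("query contains non-DNA characters")
  }
  unid <- data.frame(best_match = NA_character_, distance = NA_integer_,
                     verdict = "unidentified", stringsAsFactors = FALSE)
  if (nchar(seq) < min_length) return(unid)

  q <- strsplit(seq, "")[[1]]
  d <- vapply(refs$sequence, function(ref) {
    r <- strsplit(ref, "")[[1]]
    n <- min(length(q), length(r))
    qi <- q[seq_len(n)]; ri <- r[seq_len(n)]
    informative <- qi != "N" & ri != "N"
    sum(qi[informative] != ri[informative])
  }, integer(1), USE.NAMES = FALSE)

  best <- min(d)
  if (best > max_mismatch) return(unid)
  hits <- which(d == best)
  if (length(hits) > 1L) return(unid)  # ambiguous between references
  verdict <- switch(refs$specificity[hits],
                    wolf = "wolf", shared = "canis_sp", other = "non_target")
  data.frame(best_match = refs$name[hits], distance = best,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Screen a set of control-region sequences
#'
#' @param seqs Named character vector of query sequences (names = sample
#'   ids), or a `DNAStringSet`.
#' @param refs Reference panel data frame.
#' @param max_mismatch,min_length Passed to [assign_mitotype()].
#' @return A `mitotype_screen` list: `assignments` (one row per sample) and
#'   `summary` from [screen_summary()].
#' @export
screen_mitotypes <- function(seqs, refs, max_mismatch = 2L,
                             min_length = 500L) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("query sequences must be named by sample id")
  }
  rows <- lapply(seq_along(seqs), function(i) {
    cbind(data.frame(sample_id = names(seqs)[i], stringsAsFactors = FALSE),
          assign_mitotype(seqs[[i]], refs, max_mismatch, min_length))
  })
  assignments <- do.call(rbind, rows)
  structure(list(assignments = assignments,
                 summary = screen_summary(assignments)),
            class = "mitotype_screen")
}

#' Summarise mitotype assignments
#'
#' Counts and percentages per verdict (denominator: all samples submitted)
#' and per mitotype among wolf-assigned samples (denominator: wolf samples),
#' percentages rounded to one decimal as conventionally reported.
#'
#' @param assignments Data frame with columns `sample_id`, `best_match`,
#'   `verdict`.
#' @return List with `n_submitted`, `by_verdict` and `by_mitotype` data
#'   frames. Empty input gives zero-row tables.
#' @export
screen_summary <- function(assignments) {
  n <- nrow(assignments)
  if (n == 0L) {
    return(list(n_submitted = 0L,
                by_verdict = data.frame(verdict = character(0),
                                        count = integer(0),
                                        percent = numeric(0)),
                by_mitotype = data.frame(mitotype = character(0),
                                         count = integer(0),
                                         percent = numeric(0))))
  }
  verdicts <- c("wolf", "canis_sp", "non_target", "unidentified")
  cnt <- table(factor(assignments$verdict, levels = verdicts))
  by_verdict <- data.frame(verdict = verdicts, count = as.integer(cnt),
                           percent = percent_of(as.integer(cnt), n))
  wolf <- assignments[assignments$verdict == "wolf", , drop = FALSE]
  if (nrow(wolf)) {
    mt <- sort(table(wolf$best_match), decreasing = TRUE)
    by_mitotype <- data.frame(mitotype = names(mt), count = as.integer(mt),
                              percent = percent_of(as.integer(mt), nrow(wolf)))
  } else {
    by_mitotype <- data.frame(mitotype = character(0), count = integer(0),
                              percent = numeric(0))
  }
  list(n_submitted = n, by_verdict = by_verdict, by_mitotype = by_mitotype)
}

#' Percentage of a count over a denominator, reported to one decimal
#'
#' The rounding convention used for all screening/retention summaries
#' (e.g. 7234 of 8733 -> 82.8).
#'
#' @param count Numerator count(s).
#' @param total Denominator.
#' @return Numeric percentage(s) rounded to 1 decimal place.
#' @export
percent_of <- function(count, total) {
  if (total == 0) return(rep(NA_real_, length(count)))
  round(100 * count / total, 1)
}
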