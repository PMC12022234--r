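#' Genotype call statuses
#'
#' A call at one locus is either `called` (an unordered diploid allele pair),
#' `missing` (no amplification), `contaminated`, or `disputed` (analysts could
#' not agree on the read). Non-called statuses carry no alleles and behave as
#' missing in every comparison.
#' @keywords internal
#' @name call-status
NULL

.call_statuses <- c("called", "missing", "contaminated", "disputed")

#' Construct a genotype call
#'
#' @param allele_1,allele_2 Integer allele labels (fragment sizes in base
#'   pairs). Both must be given for a called genotype; homozygotes are the
#'   equal pair. Stored in nondecreasing order.
#' @param status One of `"called"`, `"missing"`, `"contaminated"`,
#'   `"disputed"`. Defaults to `"called"` when alleles are given, `"missing"`
#'   otherwise.
#' @return A `genotype_call`: a list with fields `status`, `allele_1`,
#'   `allele_2`.
#' @examples
#' genotype_call(124, 120)   # stored as 120/124
#' genotype_call(status = "missing")
#' @export
genotype_call <- function(allele_1 = NA_integer_, allele_2 = NA_integer_,
                          status = NULL) {
  if (is.null(status)) {
    status <- if (is.na(allele_1) && is.na(allele_2)) "missing" else "called"
  }
  status <- match.arg(status, .call_statuses)
  if (status == "called") {
    if (is.na(allele_1) || is.na(allele_2)) {
      stop("a called genotype needs both alleles; ",
           "write homozygotes as an equal pair")
    }
    if (!is.numeric(allele_1) || !is.numeric(allele_2) ||
        allele_1 != as.integer(allele_1) || allele_2 != as.integer(allele_2)) {
      stop("allele labels must be integer fragment sizes (bp)")
    }
    a <- sort(c(as.integer(allele_1), as.integer(allele_2)))
  } else {
    if (!is.na(allele_1) || !is.na(allele_2)) {
      stop("a non-called genotype carries no alleles")
    }
    a <- c(NA_integer_, NA_integer_)
  }
  structure(list(status = status, allele_1 = a[1], allele_2 = a[2]),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  if (x$status == "called") {
    cat(x$allele_1, "/", x$allele_2, "\n", sep = "")
  } else {
    cat("<", x$status, ">\n", sep = "")
  }
  invisible(x)
}

#' Count allele mismatches between two calls at one locus
#'
#' Mismatches are counted per allele under the best pairing of the two
#' unordered pairs, so the count is 0, 1 or 2. If either call is not a
#' called genotype (missing, disputed, contaminated) the comparison is
#' uninformative and counts as similarity (0 mismatches) -- missing data never
#' separate two samples.
#'
#' @param g1,g2 [genotype_call] objects at the same locus.
#' @return Integer in `0:2`.
#' @examples
#' allele_mismatches(genotype_call(120, 124), genotype_call(120, 120)) # 1
#' allele_mismatches(genotype_call(120, 124), genotype_call())         # 0
#' @export
allele_mismatches <- function(g1, g2) {
  stopifnot(inherits(g1, "genotype_call"), inherits(g2, "genotype_call"))
  if (g1$status != "called" || g2$status != "called") return(0L)
  mismatch_pairs(g1$allele_1, g1$allele_2, g2$allele_1, g2$allele_2)
}

#' Vectorised allele-pair mismatch count
#'
#' Internal workhorse shared by matching and error-rate code. All arguments
#' are integer vectors of canonically ordered allele pairs (`a1 <= a2`); NA
#' pairs (non-called) yield 0 mismatches.
#'
#' The best-pairing multiset overlap of two ordered pairs is
#' `max(a1==b1 + a2==b2, a1==b2 + a2==b1)`; mismatches = 2 - overlap.
#' @noRd
mismatch_pairs <- function(a1, a2, b1, b2) {
  m <- pmax((a1 == b1) + (a2 == b2), (a1 == b2) + (a2 == b1))
  out <- 2L - m
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Number of autosomal loci called in both of two consensus genotypes
#'
#' The "shared complete loci" count underlying the individual-identification
#' rule: only loci where both samples have a called consensus genotype are
#' informative for matching. The sex marker never counts.
#'
#' @param a,b Single-sample slices of a sample-consensus call table
#'   (data frames with columns `locus`, `status`), or `sample_consensus`
#'   objects containing exactly one sample each.
#' @param panel The [locus_panel] both genotypes were typed on.
#' @return Integer count of autosomal loci called in both.
#' @export
shared_complete_loci <- function(a, b, panel) {
  stopifnot(inherits(panel, "locus_panel"))
  a <- .as_call_table(a)
  b <- .as_call_table(b)
  loci <- autosomal_loci(panel)
  bad <- setdiff(unique(c(a$locus, b$locus)), panel$name)
  if (length(bad)) {
    stop("loci not in panel: ", paste(bad, collapse = ", "))
  }
  called_a <- a$locus[a$status == "called"]
  called_b <- b$locus[b$status == "called"]
  length(intersect(intersect(called_a, loci), called_b))
}

.as_call_table <- function(x) {
  if (inherits(x, "sample_consensus")) {
    if (length(unique(x$calls$sample_id)) != 1L) {
      stop("expected a consensus for a single sample")
    }
    return(x$calls)
  }
  stopifnot(is.data.frame(x), all(c("locus", "status") %in% names(x)))
  x
}
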