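#' Matching rule for individual identification
#'
#' Two high-quality samples are attributed to the same individual when they
#' share at least `min_shared_loci` autosomal loci with no missing data and
#' disagree by at most `max_mismatches` alleles over those loci. The
#' defaults (12 shared loci, 3 mismatches) are justified by the binomial
#' mismatch model: with a per-locus dropout rate around 0.07 for
#' high-quality samples, at least one mismatch between two samples of the
#' same individual is expected more often than not (see
#' [mismatch_probability()]), and almost all such errors fall between one
#' and three mismatches.
#'
#' @param min_shared_loci Minimum shared complete autosomal loci (>= 1).
#' @param max_mismatches Maximum tolerated allele mismatches (>= 0).
#' @return A `match_rule` list.
#' @export
match_rule <- function(min_shared_loci = 12L, max_mismatches = 3L) {
  min_shared_loci <- as.integer(min_shared_loci)
  max_mismatches <- as.integer(max_mismatches)
  if (min_shared_loci < 1L) stop("min_shared_loci must be >= 1")
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  structure(list(min_shared_loci = min_shared_loci,
                 max_mismatches = max_mismatches), class = "match_rule")
}

#' Probability of at least one mismatch between repeat samples
#'
#' Under the binomial mismatch model, each of `n` compared loci
#' independently shows an error (an allelic dropout surviving into one of
#' the two consensus genotypes) with probability `p`, so the probability of
#' observing at least one mismatch is `1 - (1 - p)^n`.
#'
#' @param n Number of compared loci (>= 0).
#' @param p Per-locus error probability.
#' @return Probability of one or more mismatches.
#' @examples
#' mismatch_probability(12, 0.071)  # ~0.587
#' @export
mismatch_probability <- function(n, p) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  1 - (1 - p)^n
}

#' Binomial probability of a mismatch-count range
#'
#' Probability that the number of mismatched loci falls in `[lo, hi]` under
#' the binomial mismatch model, optionally conditional on observing at least
#' one mismatch.
#'
#' @param n Number of compared loci.
#' @param p Per-locus error probability.
#' @param lo,hi Range bounds, `0 <= lo <= hi <= n`.
#' @param conditional_on_at_least_one Divide by `P(X >= 1)`?
#' @return A probability.
#' @examples
#' mismatch_range_probability(12, 0.071, 1, 3, TRUE)  # >= 0.99
#' @export
mismatch_range_probability <- function(n, p, lo, hi,
                                       conditional_on_at_least_one = FALSE) {
  stopifnot(lo >= 0, lo <= hi, hi <= n)
  pr <- sum(stats::dbinom(lo:hi, n, p))
  if (conditional_on_at_least_one) {
    pr <- pr / (1 - stats::dbinom(0, n, p))
  }
  pr
}

#' Compare two sample consensus genotypes
#'
#' @param a,b Single-sample call tables (or single-sample
#'   `sample_consensus` objects).
#' @param panel The common [locus_panel].
#' @return List `shared` (autosomal loci called in both) and `mismatches`
#'   (summed allele mismatches over those loci).
#' @export
pairwise_compare <- function(a, b, panel) {
  a <- .as_call_table(a); b <- .as_call_table(b)
  loci <- autosomal_loci(panel)
  ia <- match(loci, a$locus); ib <- match(loci, b$locus)
  ok <- !is.na(ia) & !is.na(ib) &
    a$status[ia] == "called" & b$status[ib] == "called"
  mism <- mismatch_pairs(a$allele_1[ia][ok], a$allele_2[ia][ok],
                         b$allele_1[ib][ok], b$allele_2[ib][ok])
  list(shared = sum(ok), mismatches = sum(mism))
}

#' Group samples into individuals
#'
#' Deterministic greedy agglomeration of quality-filtered sample consensus
#' genotypes into individuals. Samples are processed in order of decreasing
#' mean QI (ties broken by sample id), so the best-supported genotypes found
#' individuals first. Each sample joins the existing individual whose
#' running consensus it matches under the rule with the fewest mismatches
#' (ties: most shared loci, then earliest-founded individual), otherwise it
#' founds a new individual. After each join the individual consensus is
#' updated: per locus the modal genotype across member samples; tied modes
#' that are mutually consistent (a dropout-truncated homozygote and the
#' full heterozygote) are completed to their union, favouring the dropout
#' interpretation, while inconsistent ties resolve toward the higher-QI
#' member. A residual false allele carried by a minority of member samples
#' is therefore outvoted rather than absorbed, which is what makes the
#' residual false-allele rate measurable at all.
#'
#' Because the processing order is a deterministic function of the input,
#' the clustering is invariant to input row permutation.
#'
#' @param sc A quality-filled `sample_consensus` of retained (QI-filtered,
#'   uncontaminated) samples.
#' @param rule A [match_rule].
#' @param meta Optional sample metadata (see [read_sample_meta()]) used to
#'   attach capture dates.
#' @return An `individual_set`: list with `individuals` (id, n_samples, sex,
#'   first_capture, last_capture), `membership` (sample_id ->
#'   individual_id), `consensus` (long call table per individual), `panel`,
#'   `rule`.
#' @export
cluster_individuals <- function(sc, rule = match_rule(), meta = NULL) {
  stopifnot(inherits(sc, "sample_consensus"), inherits(rule, "match_rule"))
  if (any(sc$samples$contaminated)) {
    stop("contaminated samples must be removed before clustering")
  }
  if (anyNA(sc$samples$mean_qi)) {
    stop("mean QI not computed; call add_quality() first")
  }
  panel <- sc$panel
  loci <- panel$name
  auto_idx <- which(!panel$is_sex_marker)
  ord <- order(-sc$samples$mean_qi, sc$samples$sample_id)
  ids <- sc$samples$sample_id[ord]
  qis <- sc$samples$mean_qi[ord]
  n <- length(ids)

  # sample genotype matrices, rows in processing order, cols in panel order
  calls <- sc$calls
  key <- paste(calls$sample_id, calls$locus, sep = "\r")
  grid <- match(paste(rep(ids, each = length(loci)),
                      rep(loci, n), sep = "\r"), key)
  ok <- calls$status[grid] == "called"
  SA1 <- matrix(ifelse(ok, calls$allele_1[grid], NA_integer_),
                nrow = n, byrow = TRUE)
  SA2 <- matrix(ifelse(ok, calls$allele_2[grid], NA_integer_),
                nrow = n, byrow = TRUE)

  IA1 <- matrix(NA_integer_, nrow = 0, ncol = length(loci))
  IA2 <- matrix(NA_integer_, nrow = 0, ncol = length(loci))
  members <- list()
  assignment <- integer(n)

  consensus_of <- function(midx) {
    # midx: member row indices in processing order (QI-desc within equal set).
    # Per locus the consensus is the modal genotype across member samples;
    # tied modes that are pairwise consistent (one call extends the other,
    # e.g. a dropout-truncated homozygote vs the full heterozygote) are
    # completed to their union, favouring the dropout interpretation;
    # inconsistent ties go to the highest-QI member.
    a1 <- rep(NA_integer_, length(loci))
    a2 <- rep(NA_integer_, length(loci))
    for (l in seq_along(loci)) {
      g1 <- SA1[midx, l]; g2 <- SA2[midx, l]
      called <- !is.na(g1)
      if (!any(called)) next
      geno <- paste(g1[called], g2[called])
      tab <- table(geno)
      modal <- unique(geno[geno %in% names(tab)[tab == max(tab)]])
      if (length(modal) == 1L) {
        parts <- as.integer(strsplit(modal, " ")[[1]])
      } else {
        sets <- lapply(strsplit(modal, " "),
                       function(g) unique(as.integer(g)))
        consistent <- all(vapply(seq_along(sets), function(i)
          all(vapply(seq_along(sets), function(j)
            all(sets[[i]] %in% sets[[j]]) || all(sets[[j]] %in% sets[[i]]),
            logical(1))), logical(1)))
        pooled <- unique(unlist(sets))
        if (consistent && length(pooled) <= 2L) {
          parts <- c(min(pooled), max(pooled))
        } else {
          pick <- geno[geno %in% modal][1]  # first member = highest QI
          parts <- as.integer(strsplit(pick, " ")[[1]])
        }
      }
      a1[l] <- parts[1]; a2[l] <- max(parts)
    }
    list(a1 = a1, a2 = a2)
  }

  for (i in seq_len(n)) {
    joined <- FALSE
    if (nrow(IA1) > 0L) {
      nI <- nrow(IA1)
      a1m <- matrix(SA1[i, ], nrow = nI, ncol = length(loci), byrow = TRUE)
      a2m <- matrix(SA2[i, ], nrow = nI, ncol = length(loci), byrow = TRUE)
      sharedm <- !is.na(IA1) & !is.na(a1m)
      mm <- 2L - pmax((IA1 == a1m) + (IA2 == a2m),
                      (IA1 == a2m) + (IA2 == a1m))
      mm[!sharedm] <- 0L
      shared_cnt <- rowSums(sharedm[, auto_idx, drop = FALSE])
      mism <- rowSums(mm[, auto_idx, drop = FALSE])
      eligible <- shared_cnt >= rule$min_shared_loci &
        mism <= rule$max_mismatches
      if (any(eligible)) {
        cand <- which(eligible)
        cand <- cand[order(mism[cand], -shared_cnt[cand], cand)]
        k <- cand[1]
        members[[k]] <- c(members[[k]], i)
        cons <- consensus_of(members[[k]])
        IA1[k, ] <- cons$a1; IA2[k, ] <- cons$a2
        assignment[i] <- k
        joined <- TRUE
      }
    }
    if (!joined) {
      IA1 <- rbind(IA1, SA1[i, ])
      IA2 <- rbind(IA2, SA2[i, ])
      members[[length(members) + 1L]] <- i
      assignment[i] <- length(members)
    }
  }

  nI <- length(members)
  ind_ids <- sprintf("IND%05d", seq_len(nI))
  consensus <- data.frame(
    individual_id = rep(ind_ids, each = length(loci)),
    locus = rep(loci, nI),
    allele_1 = as.integer(t(IA1)),
    allele_2 = as.integer(t(IA2)),
    stringsAsFactors = FALSE
  )
  consensus$status <- ifelse(is.na(consensus$allele_1), "missing", "called")

  sexm <- sex_marker(panel)
  sex <- vapply(seq_len(nI), function(k) {
    if (is.na(sexm)) return("unknown")
    l <- match(sexm, loci)
    assign_sex_call(IA1[k, l], IA2[k, l])
  }, character(1))

  membership <- data.frame(sample_id = ids, individual_id = ind_ids[assignment],
                           stringsAsFactors = FALSE)
  individuals <- data.frame(
    individual_id = ind_ids,
    n_samples = as.integer(lengths(members)),
    sex = sex,
    first_capture = as.Date(NA), last_capture = as.Date(NA),
    stringsAsFactors = FALSE
  )
  if (!is.null(meta)) {
    dates <- meta$collection_date[match(membership$sample_id, meta$sample_id)]
    if (!all(is.na(dates))) {
      first <- tapply(dates, membership$individual_id, min, na.rm = TRUE)
      last <- tapply(dates, membership$individual_id, max, na.rm = TRUE)
      individuals$first_capture <-
        as.Date(as.numeric(first[individuals$individual_id]),
                origin = "1970-01-01")
      individuals$last_capture <-
        as.Date(as.numeric(last[individuals$individual_id]),
                origin = "1970-01-01")
    }
  }
  structure(list(individuals = individuals, membership = membership,
                 consensus = consensus, panel = panel, rule = rule),
            class = "individual_set")
}

#' @export
print.individual_set <- function(x, ...) {
  cat("<individual_set> ", nrow(x$individuals), " individuals from ",
      nrow(x$membership), " samples (rule: >=", x$rule$min_shared_loci,
      " shared loci, <=", x$rule$max_mismatches, " mismatches)\n", sep = "")
  invisible(x)
}

#' Sex from a sex-marker genotype
#'
#' Amelogenin in canids: heterozygous in males, homozygous in females.
#'
#' @param allele_1,allele_2 Sex-marker consensus alleles (NA when missing).
#' @return `"male"`, `"female"` or `"unknown"`.
#' @export
assign_sex_call <- function(allele_1, allele_2) {
  if (is.na(allele_1) || is.na(allele_2)) return("unknown")
  if (allele_1 != allele_2) "male" else "female"
}

#' Re-cluster under alternative matching rules
#'
#' Sensitivity of the individual count to the matching thresholds: the
#' dataset is re-clustered under each rule and counts are reported with the
#' change relative to the first rule.
#'
#' @param sc A quality-filled, filtered `sample_consensus`.
#' @param rules List of [match_rule]s (the first is the baseline).
#' @return Data frame `min_shared_loci`, `max_mismatches`, `n_individuals`,
#'   `percent_change` (vs the first rule).
#' @export
threshold_sensitivity <- function(sc, rules) {
  stopifnot(length(rules) >= 1L)
  counts <- vapply(rules, function(r)
    nrow(cluster_individuals(sc, r)$individuals), integer(1))
  data.frame(
    min_shared_loci = vapply(rules, `[[`, integer(1), "min_shared_loci"),
    max_mismatches = vapply(rules, `[[`, integer(1), "max_mismatches"),
    n_individuals = counts,
    percent_change = round(100 * (counts - counts[1]) / counts[1], 1)
  )
}

#' Audit an individual set against its matching rule
#'
#' Post-hoc verification that every member sample still satisfies the rule
#' against the final individual consensus (greedy agglomeration updates the
#' consensus after each join, so this is not guaranteed by construction),
#' and count cross-individual sample pairs that would also have matched
#' (intransitivity indicator).
#'
#' @param iset An `individual_set`.
#' @param sc The `sample_consensus` it was built from.
#' @return List `violations` (data frame of member samples failing the rule
#'   against their individual consensus) and `cross_matches` (count of
#'   rule-satisfying sample pairs that ended up in different individuals).
#' @export
audit_individuals <- function(iset, sc) {
  rule <- iset$rule
  panel <- iset$panel
  viol <- list()
  for (i in seq_len(nrow(iset$membership))) {
    sid <- iset$membership$sample_id[i]
    iid <- iset$membership$individual_id[i]
    a <- sc$calls[sc$calls$sample_id == sid, ]
    b <- iset$consensus[iset$consensus$individual_id == iid, ]
    names(b)[names(b) == "individual_id"] <- "sample_id"
    cmp <- pairwise_compare(a, b, panel)
    if (cmp$shared < rule$min_shared_loci ||
        cmp$mismatches > rule$max_mismatches) {
      viol[[length(viol) + 1L]] <- data.frame(
        sample_id = sid, individual_id = iid, shared = cmp$shared,
        mismatches = cmp$mismatches, stringsAsFactors = FALSE)
    }
  }
  ids <- sc$samples$sample_id
  cross <- 0L
  if (length(ids) > 1L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq((i + 1L), length(ids))) {
        mi <- iset$membership$individual_id[match(ids[i],
                                                  iset$membership$sample_id)]
        mj <- iset$membership$individual_id[match(ids[j],
                                                  iset$membership$sample_id)]
        if (identical(mi, mj)) next
        a <- sc$calls[sc$calls$sample_id == ids[i], ]
        b <- sc$calls[sc$calls$sample_id == ids[j], ]
        cmp <- pairwise_compare(a, b, panel)
        if (cmp$shared >= rule$min_shared_loci &&
            cmp$mismatches <= rule$max_mismatches) cross <- cross + 1L
      }
    }
  }
  list(violations = if (length(viol)) do.call(rbind, viol) else
    data.frame(sample_id = character(0), individual_id = character(0),
               shared = integer(0), mismatches = integer(0)),
    cross_matches = cross)
}

#' Flag spatiotemporally implausible merges for review
#'
#' Auxiliary evidence (sample quality, date and location) is used by
#' reviewers to confirm genotype-based assignments, never to decide them
#' automatically. This report flags, within each individual, pairs of
#' same-day samples collected further apart than `max_km` (great-circle
#' distance from `lon`/`lat` metadata columns).
#'
#' @param iset An `individual_set`.
#' @param meta Sample metadata with numeric `lon` and `lat` columns and
#'   `collection_date`.
#' @param max_km Distance threshold in kilometres (default 50).
#' @return Data frame of flagged pairs (individual, samples, date, km).
#' @export
review_individuals <- function(iset, meta, max_km = 50) {
  stopifnot(all(c("lon", "lat", "collection_date", "sample_id") %in%
                  names(meta)))
  out <- list()
  hav <- function(lon1, lat1, lon2, lat2) {
    r <- pi / 180
    a <- sin((lat2 - lat1) * r / 2)^2 +
      cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
    2 * 6371 * asin(pmin(1, sqrt(a)))
  }
  for (iid in unique(iset$membership$individual_id)) {
    sids <- iset$membership$sample_id[iset$membership$individual_id == iid]
    m <- meta[match(sids, meta$sample_id), ]
    if (nrow(m) < 2L) next
    for (i in seq_len(nrow(m) - 1L)) {
      for (j in seq((i + 1L), nrow(m))) {
        if (is.na(m$collection_date[i]) || is.na(m$collection_date[j]) ||
            m$collection_date[i] != m$collection_date[j]) next
        km <- hav(m$lon[i], m$lat[i], m$lon[j], m$lat[j])
        if (!is.na(km) && km > max_km) {
          out[[length(out) + 1L]] <- data.frame(
            individual_id = iid, sample_a = m$sample_id[i],
            sample_b = m$sample_id[j], date = m$collection_date[i],
            km = round(km, 1), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(individual_id = character(0), sample_a = character(0),
               sample_b = character(0), date = as.Date(character(0)),
               km = numeric(0))
}
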