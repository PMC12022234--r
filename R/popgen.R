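#' Extract called genotypes at one locus from an individual set
#'
#' @param x An `individual_set` or a long consensus data frame
#'   (`individual_id`, `locus`, `allele_1`, `allele_2`, `status`).
#' @param locus Locus name.
#' @return Data frame `allele_1`, `allele_2` of called genotypes.
#' @export
locus_genotypes <- function(x, locus) {
  cons <- if (inherits(x, "individual_set")) x$consensus else x
  if (!"status" %in% names(cons)) {
    cons$status <- ifelse(is.na(cons$allele_1), "missing", "called")
  }
  rows <- cons[cons$locus == locus & cons$status == "called", , drop = FALSE]
  data.frame(allele_1 = rows$allele_1, allele_2 = rows$allele_2)
}

#' Allele frequencies at a locus
#'
#' Frequencies over the `2n` allele copies of the called genotypes.
#'
#' @inheritParams locus_genotypes
#' @return Named numeric vector of frequencies (sums to 1), or an error if
#'   no genotype is called at the locus.
#' @export
allele_frequencies <- function(x, locus) {
  g <- locus_genotypes(x, locus)
  if (nrow(g) == 0L) stop("no called genotypes at locus ", locus)
  tab <- table(c(g$allele_1, g$allele_2))
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Observed and expected heterozygosity at a locus
#'
#' `Ho` is the fraction of called genotypes that are heterozygous; `He` is
#' Nei's unbiased gene diversity, `(1 - sum(p^2)) * 2n / (2n - 1)`.
#'
#' @inheritParams locus_genotypes
#' @return List `ho`, `he`, `n` (number of called genotypes).
#' @export
heterozygosities <- function(x, locus) {
  g <- locus_genotypes(x, locus)
  n <- nrow(g)
  if (n == 0L) stop("no called genotypes at locus ", locus)
  p <- allele_frequencies(x, locus)
  he <- (1 - sum(p^2))
  if (n > 1L) he <- he * 2 * n / (2 * n - 1)
  list(ho = mean(g$allele_1 != g$allele_2), he = he, n = n)
}

#' Fixation index from heterozygosities
#'
#' Per-locus (or overall, from locus-mean heterozygosities):
#' `FIS = 1 - Ho / He`. Undefined (NA) when `He` is 0.
#'
#' @param ho,he Observed and expected heterozygosity.
#' @return FIS value or NA.
#' @export
fis <- function(ho, he) {
  ifelse(he > 0, 1 - ho / he, NA_real_)
}

#' Hardy-Weinberg permutation test at one locus
#'
#' Tests departure from Hardy-Weinberg genotype proportions by permuting
#' allele copies within the population and re-pairing them into genotypes.
#' The statistic is the per-locus FIS; expected heterozygosity is invariant
#' under allele permutation, so the null distribution is driven by the
#' permuted observed heterozygosity. Two-sided p-value with the add-one
#' estimator: `(1 + #{|FIS_perm| >= |FIS_obs|}) / (n_perm + 1)`.
#'
#' @inheritParams locus_genotypes
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed (the RNG state is restored on exit).
#' @return List `p`, `fis_obs`, `n_perm`, `monomorphic` (flag; monomorphic
#'   loci return p = 1 by convention).
#' @export
hwe_permutation_test <- function(x, locus, n_perm = 1000L, seed = NULL) {
  g <- locus_genotypes(x, locus)
  n <- nrow(g)
  if (n < 5L) stop("need at least 5 called genotypes")
  alleles <- c(g$allele_1, g$allele_2)
  if (length(unique(alleles)) == 1L) {
    return(list(p = 1, fis_obs = NA_real_, n_perm = n_perm,
                monomorphic = TRUE))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  p_freq <- table(alleles) / (2 * n)
  he <- (1 - sum(p_freq^2)) * 2 * n / (2 * n - 1)
  ho_obs <- mean(g$allele_1 != g$allele_2)
  fis_obs <- 1 - ho_obs / he
  ho_perm <- vapply(seq_len(n_perm), function(b) {
    s <- sample(alleles)
    mean(s[seq_len(n)] != s[n + seq_len(n)])
  }, numeric(1))
  fis_perm <- 1 - ho_perm / he
  hits <- sum(abs(fis_perm) >= abs(fis_obs) - 1e-12)
  list(p = (1 + hits) / (n_perm + 1), fis_obs = fis_obs, n_perm = n_perm,
       monomorphic = FALSE)
}

#' Probability of identity among siblings at one locus
#'
#' The conservative per-locus probability that two full siblings share a
#' genotype by chance:
#' `PI_sibs = 0.25 + 0.5*S2 + 0.5*S2^2 - 0.25*S4` with `S2 = sum(p^2)`,
#' `S4 = sum(p^4)`.
#'
#' @param freqs Allele frequency vector (sums to 1).
#' @return Probability in `[0, 1]`.
#' @examples
#' pi_sibs_locus(c(0.5, 0.5))  # 19/32
#' @export
pi_sibs_locus <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  s2 <- sum(freqs^2); s4 <- sum(freqs^4)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
}

#' Multi-locus identity probability over locus subsets
#'
#' Under locus independence the multi-locus PI_sibs of a subset is the
#' product of its per-locus values. For subsets of size `k` this reports
#' the minimum (product of the `k` smallest values), maximum (`k` largest)
#' and mean over all `choose(n, k)` subsets. The mean is
#' `e_k(values) / choose(n, k)` with `e_k` the k-th elementary symmetric
#' polynomial, computed by the stable incremental recurrence rather than
#' subset enumeration.
#'
#' @param per_locus_values Per-locus PI_sibs values.
#' @param k Subset size(s), each in `1..length(per_locus_values)`.
#' @return Data frame with one row per `k`: `k`, `min`, `max`, `mean`.
#' @export
pi_sibs_subsets <- function(per_locus_values, k) {
  n <- length(per_locus_values)
  if (any(k < 1L | k > n)) stop("k out of range 1..", n)
  v <- sort(per_locus_values)
  # elementary symmetric polynomials e_0..e_n
  e <- c(1, rep(0, n))
  for (x in per_locus_values) {
    e[2:(n + 1)] <- e[2:(n + 1)] + x * e[1:n]
  }
  out <- data.frame(k = as.integer(k))
  out$min <- vapply(k, function(kk) prod(v[seq_len(kk)]), numeric(1))
  out$max <- vapply(k, function(kk) prod(v[n - seq_len(kk) + 1L]), numeric(1))
  out$mean <- vapply(k, function(kk) e[kk + 1] / choose(n, kk), numeric(1))
  out
}

#' Maximum-likelihood null-allele frequency at one locus
#'
#' Fits, by expectation-maximization, the Hardy-Weinberg multinomial model
#' with one unobservable null allele under the observation model: a
#' heterozygote carrying the null allele amplifies as an apparent
#' homozygote for its visible allele; a null homozygote amplifies as
#' missing. Amplification failure is not modelled separately, so missing
#' counts should only include loci believed to have amplifiable DNA.
#'
#' @param allele_1,allele_2 Allele pairs of apparent (called) genotypes.
#' @param n_missing Count of missing genotypes attributed to null
#'   homozygotes (default 0).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return List `null_freq`, `freqs` (visible alleles), `loglik`,
#'   `iterations`, `converged`, `n`.
#' @export
null_allele_ml <- function(allele_1, allele_2, n_missing = 0L,
                           tol = 1e-8, max_iter = 10000L) {
  n_called <- length(allele_1)
  n <- n_called + n_missing
  if (n_called < 1L) stop("no called genotypes")
  if (n_called < 20L) {
    warning("fewer than 20 called genotypes; estimate will be unstable")
  }
  alleles <- sort(unique(c(allele_1, allele_2)))
  k <- length(alleles)
  i1 <- match(allele_1, alleles); i2 <- match(allele_2, alleles)
  hom <- i1 == i2
  m_i <- tabulate(i1[hom], nbins = k)              # apparent homozygotes
  het_counts <- tabulate(c(i1[!hom], i2[!hom]), nbins = k)

  p <- tabulate(c(i1, i2), nbins = k) / (2 * n_called)
  r <- max(0.01, n_missing / n)
  p <- p * (1 - r)

  ll_of <- function(p, r) {
    ll <- sum(m_i * log(pmax(p^2 + 2 * p * r, 1e-300))) +
      sum(het_counts * log(pmax(p, 1e-300))) + sum(!hom) * log(2)
    if (n_missing > 0) ll <- ll + 2 * n_missing * log(max(r, 1e-300))
    ll
  }
  ll <- ll_of(p, r)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- ifelse(p + 2 * r > 0, p / (p + 2 * r), 1)  # P(true homo | apparent)
    cnt <- het_counts + m_i * (1 + w)
    null_cnt <- sum(m_i * (1 - w)) + 2 * n_missing
    total <- sum(cnt) + null_cnt
    p <- cnt / total
    r <- null_cnt / total
    ll_new <- ll_of(p, r)
    if (is.finite(ll) && abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(null_freq = r, freqs = stats::setNames(p, alleles), loglik = ll,
       iterations = it, converged = converged, n = n)
}

#' One-proportion z-test for sex-ratio bias
#'
#' Tests the proportion of males against 0.5 with the normal approximation:
#' `z = (p_hat - 0.5) / sqrt(0.25 / n)`, two-sided p from the normal CDF.
#'
#' @param sexes Character vector of `"male"` / `"female"` (unknowns are
#'   dropped), or `NULL` if counts are given directly.
#' @param n_male,n_female Direct counts (used when `sexes` is NULL).
#' @return List `proportion_male`, `n`, `z`, `p`.
#' @export
sex_ratio_test <- function(sexes = NULL, n_male = NULL, n_female = NULL) {
  if (!is.null(sexes)) {
    n_male <- sum(sexes == "male")
    n_female <- sum(sexes == "female")
  }
  n <- n_male + n_female
  if (is.null(n) || n < 1L) stop("no sexed individuals")
  phat <- n_male / n
  z <- (phat - 0.5) / sqrt(0.25 / n)
  list(proportion_male = phat, n = n, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Per-locus diversity table with panel aggregates
#'
#' The standard per-locus summary of an individual consensus dataset:
#' number of alleles (Na), observed (Ho) and unbiased expected (He)
#' heterozygosity, FIS, Hardy-Weinberg permutation p-value, and per-locus
#' PI_sibs. The Total row sums Na and takes unweighted locus means of Ho
#' and He; overall FIS is `1 - mean(Ho)/mean(He)` with a bootstrap-over-loci
#' 95% CI, and the panel PI_sibs is the product of per-locus values.
#'
#' @param x An `individual_set` or long consensus data frame.
#' @param panel A [locus_panel]; autosomal loci are reported.
#' @param n_perm Permutations for the HWE test (default 1000).
#' @param seed Optional seed controlling permutations and bootstrap.
#' @param exclude Locus names to drop before computing aggregates (e.g.
#'   loci with suspected null alleles).
#' @param n_boot Bootstrap replicates for the overall FIS CI.
#' @return A `diversity_table`: list with `per_locus` (data frame) and
#'   `totals` (list: `na`, `mean_ho`, `mean_he`, `fis`, `fis_ci`,
#'   `pi_sibs`).
#' @export
diversity_report <- function(x, panel, n_perm = 1000L, seed = NULL,
                             exclude = NULL, n_boot = 1000L) {
  loci <- setdiff(autosomal_loci(panel), exclude)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  rows <- lapply(loci, function(loc) {
    g <- locus_genotypes(x, loc)
    if (nrow(g) == 0L) {
      return(data.frame(locus = loc, na = NA_integer_, ho = NA_real_,
                        he = NA_real_, fis = NA_real_, hwe_p = NA_real_,
                        pi_sibs = NA_real_, n = 0L))
    }
    freqs <- allele_frequencies(x, loc)
    h <- heterozygosities(x, loc)
    hwe <- if (h$n >= 5L) hwe_permutation_test(x, loc, n_perm = n_perm)$p
      else NA_real_
    data.frame(locus = loc, na = length(freqs), ho = h$ho, he = h$he,
               fis = fis(h$ho, h$he), hwe_p = hwe,
               pi_sibs = pi_sibs_locus(freqs), n = h$n)
  })
  per_locus <- do.call(rbind, rows)
  totals <- aggregate_diversity(per_locus, n_boot = n_boot)
  structure(list(per_locus = per_locus, totals = totals),
            class = "diversity_table")
}

#' Aggregate a per-locus diversity table
#'
#' Panel-level totals from per-locus values, usable both on tables computed
#' by [diversity_report()] and on published per-locus tables read from
#' text: total Na, unweighted mean Ho and He, overall
#' `FIS = 1 - mean(Ho)/mean(He)` with a bootstrap-over-loci 95% CI, and the
#' cumulative PI_sibs (product over loci, when a `pi_sibs` column exists).
#'
#' @param per_locus Data frame with columns `na`, `ho`, `he` (and optionally
#'   `fis`, `pi_sibs`, `locus`).
#' @param exclude Optional locus names to drop first (requires a `locus`
#'   column).
#' @param n_boot Bootstrap replicates for the FIS CI (0 to skip).
#' @return List `n_loci`, `na`, `mean_ho`, `mean_he`, `fis`, `fis_ci`,
#'   `pi_sibs`.
#' @export
aggregate_diversity <- function(per_locus, exclude = NULL, n_boot = 1000L) {
  if (!is.null(exclude)) {
    per_locus <- per_locus[!(per_locus$locus %in% exclude), , drop = FALSE]
  }
  ok <- !is.na(per_locus$ho) & !is.na(per_locus$he)
  tab <- per_locus[ok, , drop = FALSE]
  mean_ho <- mean(tab$ho); mean_he <- mean(tab$he)
  fis_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L && nrow(tab) > 1L) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(tab), replace = TRUE)
      1 - mean(tab$ho[idx]) / mean(tab$he[idx])
    }, numeric(1))
    fis_ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  }
  list(n_loci = nrow(tab), na = sum(tab$na, na.rm = TRUE),
       mean_ho = mean_ho, mean_he = mean_he,
       fis = fis(mean_ho, mean_he), fis_ci = fis_ci,
       pi_sibs = if ("pi_sibs" %in% names(tab))
         prod(tab$pi_sibs) else NA_real_)
}

#' @export
print.diversity_table <- function(x, ...) {
  cat("<diversity_table> ", nrow(x$per_locus), " loci; total Na ",
      x$totals$na, "; mean Ho ", sprintf("%.3f", x$totals$mean_ho),
      "; mean He ", sprintf("%.3f", x$totals$mean_he), "; FIS ",
      sprintf("%.3f", x$totals$fis), "\n", sep = "")
  print(x$per_locus, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Capture-history summary
#'
#' Tallies how often each identified individual was sampled: singletons,
#' recaptured individuals, and the mean number of samples per recaptured
#' individual (reported to two decimals, as conventional).
#'
#' @param n_samples_per_individual Integer vector, samples per individual
#'   (or an `individual_set`).
#' @return List `n_individuals`, `n_singletons`, `n_recaptured`,
#'   `n_samples`, `mean_samples_per_recaptured` (two-decimal).
#' @export
capture_summary <- function(n_samples_per_individual) {
  if (inherits(n_samples_per_individual, "individual_set")) {
    n_samples_per_individual <-
      n_samples_per_individual$individuals$n_samples
  }
  k <- n_samples_per_individual
  stopifnot(all(k >= 1L))
  recap <- k[k >= 2L]
  list(n_individuals = length(k), n_singletons = sum(k == 1L),
       n_recaptured = length(recap), n_samples = sum(k),
       mean_samples_per_recaptured =
         if (length(recap)) round(mean(recap), 2) else NA_real_)
}
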