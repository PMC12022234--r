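ind_df <- function(locus, a1, a2) {
  data.frame(individual_id = sprintf("I%03d", seq_along(a1)), locus = locus,
             allele_1 = pmin(a1, a2), allele_2 = pmax(a1, a2),
             status = "called", stringsAsFactors = FALSE)
}

test_that("allele frequencies count allele copies", {
  d <- ind_df("L1", c(120L, 120L), c(120L, 124L))
  f <- allele_frequencies(d, "L1")
  expect_equal(unname(f["120"]), 0.75)
  expect_equal(unname(f["124"]), 0.25)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_error(allele_frequencies(d, "L9"), "no called genotypes")
})

test_that("heterozygosities match their definitions", {
  d <- ind_df("L1", c(120L, 120L), c(124L, 124L))
  h <- heterozygosities(d, "L1")
  expect_equal(h$ho, 1)
  mono <- ind_df("L1", rep(120L, 10), rep(120L, 10))
  hm <- heterozygosities(mono, "L1")
  expect_equal(hm$ho, 0)
  expect_equal(hm$he, 0)
  # unbiased correction vanishes at large n
  set.seed(5)
  n <- 50000
  a <- matrix(sample(c(100L, 102L), 2 * n, TRUE), ncol = 2)
  big <- ind_df("L1", a[, 1], a[, 2])
  p <- allele_frequencies(big, "L1")
  expect_equal(heterozygosities(big, "L1")$he, 1 - sum(p^2),
               tolerance = 1e-4)
})

test_that("FIS behaves at its limits and is near zero under HWE", {
  expect_equal(fis(0.5, 0.5), 0)
  expect_equal(fis(0, 0.3), 1)
  expect_true(is.na(fis(0, 0)))
  cfg <- sim_config(n_individuals = 1000)
  truth <- simulate_individuals(cfg, seed = 303)
  per <- do.call(rbind, lapply(autosomal_loci(cfg$panel), function(l) {
    h <- heterozygosities(truth$genotypes, l)
    data.frame(na = 1L, ho = h$ho, he = h$he)
  }))
  agg <- aggregate_diversity(per, n_boot = 0)
  expect_lt(abs(agg$fis), 0.02)
})

test_that("HWE permutation test is deterministic, calibrated and powerful", {
  set.seed(404)
  n <- 500
  a <- matrix(sample(c(100L, 102L, 104L), 2 * n, TRUE), ncol = 2)
  d <- ind_df("L1", a[, 1], a[, 2])
  p1 <- hwe_permutation_test(d, "L1", n_perm = 500, seed = 9)
  p2 <- hwe_permutation_test(d, "L1", n_perm = 500, seed = 9)
  expect_identical(p1$p, p2$p)

  # delete half the heterozygotes: strong deficit, small p
  het <- d$allele_1 != d$allele_2
  kill <- which(het)[seq_len(floor(sum(het) / 2))]
  d2 <- d[-kill, ]
  expect_lt(hwe_permutation_test(d2, "L1", n_perm = 1000, seed = 10)$p,
            0.05)

  mono <- ind_df("L1", rep(120L, 20), rep(120L, 20))
  res <- hwe_permutation_test(mono, "L1")
  expect_identical(res$p, 1)
  expect_true(res$monomorphic)
  expect_error(hwe_permutation_test(d[1:3, ], "L1"), "at least 5")
})

test_that("per-locus PI_sibs matches closed-form cases", {
  expect_equal(pi_sibs_locus(1), 1)
  expect_equal(pi_sibs_locus(c(0.5, 0.5)), 19 / 32)
  expect_error(pi_sibs_locus(c(0.5, 0.2)), "sum to 1")
})

test_that("subset PI statistics agree with exhaustive enumeration", {
  set.seed(6)
  v <- runif(6)
  res <- pi_sibs_subsets(v, 1:6)
  for (k in 1:6) {
    prods <- apply(combn(6, k), 2, function(ix) prod(v[ix]))
    expect_equal(res$min[k], min(prods))
    expect_equal(res$max[k], max(prods))
    expect_equal(res$mean[k], mean(prods))
  }
  # mean weakly decreasing in k for values <= 1
  expect_true(all(diff(res$mean) <= 1e-12))
  # symmetric case and the full-panel subset
  sym <- pi_sibs_subsets(rep(0.5, 3), 2)
  expect_equal(unlist(sym[, c("min", "max", "mean")]),
               c(min = 0.25, max = 0.25, mean = 0.25))
  full <- pi_sibs_subsets(v, 6)
  expect_equal(full$min, prod(v))
  expect_equal(full$mean, prod(v))
  expect_error(pi_sibs_subsets(v, 7), "out of range")
})

test_that("null-allele EM recovers simulated frequencies", {
  # all-heterozygote data show no homozygote excess
  het <- suppressWarnings(
    null_allele_ml(rep(100L, 10), rep(102L, 10)))
  expect_lt(het$null_freq, 1e-4)

  sim_null <- function(r_true, n, seed) {
    set.seed(seed)
    p <- c(0.35, 0.35, 0.30) * (1 - r_true)
    pv <- c(p, r_true)
    g <- matrix(sample(4, 2 * n, TRUE, pv), ncol = 2)
    a1 <- pmin(g[, 1], g[, 2]); a2 <- pmax(g[, 1], g[, 2])
    missing <- a1 == 4
    a2[a2 == 4] <- a1[a2 == 4]  # null carrier looks homozygous
    sizes <- c(100L, 102L, 104L, NA)
    null_allele_ml(sizes[a1[!missing]], sizes[a2[!missing]],
                   n_missing = sum(missing))
  }
  fit <- sim_null(0.2, 1000, 505)
  expect_true(fit$converged)
  expect_lt(abs(fit$null_freq - 0.2), 0.05)
  fit0 <- sim_null(0, 1000, 506)
  expect_lt(fit0$null_freq, 0.02)
  expect_warning(null_allele_ml(rep(100L, 5), rep(100L, 5)), "unstable")
})

test_that("sex-ratio z-test matches the standard formula and a MC oracle", {
  bal <- sex_ratio_test(n_male = 50, n_female = 50)
  expect_equal(bal$z, 0)
  expect_equal(bal$p, 1)
  skew <- sex_ratio_test(n_male = round(0.55 * 1735),
                         n_female = 1735 - round(0.55 * 1735))
  expect_equal(skew$z, 4.165, tolerance = 0.01)
  expect_error(sex_ratio_test(character(0)), "no sexed")

  # Monte-Carlo two-sided p under the null
  obs <- sex_ratio_test(n_male = 112, n_female = 88)
  set.seed(7)
  mc <- mean(abs(rbinom(40000, 200, 0.5) / 200 - 0.5) >=
               abs(obs$proportion_male - 0.5) - 1e-12)
  expect_lt(abs(obs$p - mc), 0.02)
})

test_that("diversity report aggregates per-locus rows coherently", {
  cfg <- sim_config(n_individuals = 150)
  truth <- simulate_individuals(cfg, seed = 606)
  div <- diversity_report(truth$genotypes, cfg$panel, n_perm = 200,
                          seed = 11, n_boot = 200)
  pl <- div$per_locus
  expect_identical(nrow(pl), 22L)
  expect_true(all(pl$ho >= 0 & pl$ho <= 1))
  expect_true(all(pl$he >= 0 & pl$he <= 1))
  expect_true(all(pl$pi_sibs > 0 & pl$pi_sibs <= 1))
  expect_identical(div$totals$na, sum(pl$na))
  expect_equal(div$totals$mean_ho, mean(pl$ho))
  expect_equal(div$totals$pi_sibs, prod(pl$pi_sibs))
  expect_equal(div$totals$pi_sibs,
               pi_sibs_subsets(pl$pi_sibs, 22)$mean)

  # excluding loci recomputes the aggregates on the remainder
  worst <- pl$locus[which.max(pl$fis)]
  agg2 <- aggregate_diversity(pl, exclude = worst, n_boot = 0)
  expect_identical(agg2$n_loci, 21L)
  expect_equal(agg2$mean_ho, mean(pl$ho[pl$locus != worst]))

  single <- aggregate_diversity(pl[1, ], n_boot = 0)
  expect_equal(single$mean_ho, pl$ho[1])
  expect_identical(single$na, pl$na[1])
})

test_that("capture summaries report the recapture structure", {
  cs <- capture_summary(c(1L, 1L, 2L, 5L))
  expect_identical(cs$n_singletons, 2L)
  expect_identical(cs$n_recaptured, 2L)
  expect_equal(cs$mean_samples_per_recaptured, 3.5)
  expect_identical(cs$n_samples, 9L)
})
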