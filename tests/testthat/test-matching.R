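test_that("binomial mismatch model matches brute-force pmf summation", {
  expect_equal(mismatch_probability(12, 0.071),
               1 - sum(dbinom(0, 12, 0.071)))
  expect_identical(mismatch_probability(7, 0), 0)
  # full pmf oracle
  expect_equal(mismatch_probability(12, 0.071),
               sum(dbinom(1:12, 12, 0.071)))
  # exhaustive enumeration oracle at n = 6: every outcome vector
  n <- 6; p <- 0.3
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  probs <- apply(grid, 1, function(v) prod(ifelse(v == 1, p, 1 - p)))
  k <- rowSums(grid)
  for (range in list(c(1, 3), c(0, 6), c(2, 2))) {
    exact <- sum(probs[k >= range[1] & k <= range[2]])
    expect_equal(mismatch_range_probability(n, p, range[1], range[2]),
                 exact)
    exact_cond <- sum(probs[k >= max(1, range[1]) & k <= range[2]]) /
      sum(probs[k >= 1])
    if (range[1] >= 1) {
      expect_equal(
        mismatch_range_probability(n, p, range[1], range[2], TRUE),
        exact_cond)
    }
  }
  expect_equal(mismatch_range_probability(12, 0.071, 0, 12), 1)
})

test_that("pairwise comparison counts shared loci and summed mismatches", {
  panel <- default_wolf_panel()
  loci <- autosomal_loci(panel)
  a <- call_df(loci, rep(120L, 22), rep(124L, 22))
  expect_identical(pairwise_compare(a, a, panel),
                   list(shared = 22L, mismatches = 0L))

  b <- a
  b$status[13:22] <- "missing"
  b$allele_1[13:22] <- b$allele_2[13:22] <- NA_integer_
  b$allele_2[1] <- 120L  # het vs homo at one shared locus
  cmp <- pairwise_compare(a, b, panel)
  expect_identical(cmp$shared, 12L)
  expect_identical(cmp$mismatches, 1L)
})

test_that("clustering joins matching samples and splits non-matching ones", {
  panel <- tiny_panel(14)
  loci <- autosomal_loci(panel)
  g <- function(id, a1, a2) {
    r <- reps_df(id, 1, c(loci, "AMEL"), c(a1, 194L), c(a2, 194L))
    r
  }
  base1 <- rep(120L, 14); base2 <- rep(124L, 14)
  reps <- rbind(g("s1", base1, base2), g("s2", base1, base2))
  sc <- quick_sc(reps, panel)
  iset <- cluster_individuals(sc, match_rule(12, 3))
  expect_identical(nrow(iset$individuals), 1L)
  expect_identical(iset$individuals$n_samples, 2L)

  # 14 shared loci, 4 allele mismatches -> two individuals under <=3
  a2_mod <- base2; a2_mod[1:4] <- base1[1:4]   # het -> homo at 4 loci
  reps4 <- rbind(g("s1", base1, base2), g("s2", base1, a2_mod))
  sc4 <- quick_sc(reps4, panel)
  expect_identical(nrow(cluster_individuals(sc4, match_rule(12, 3))$individuals),
                   2L)
  # boundary: exactly 3 mismatches joins
  a2_mod3 <- base2; a2_mod3[1:3] <- base1[1:3]
  reps3 <- rbind(g("s1", base1, base2), g("s2", base1, a2_mod3))
  sc3 <- quick_sc(reps3, panel)
  expect_identical(nrow(cluster_individuals(sc3, match_rule(12, 3))$individuals),
                   1L)

  # 11 shared complete loci cannot match under the 12-locus rule
  few <- g("s2", base1, base2)
  few$status[12:14] <- "missing"
  few$allele_1[12:14] <- few$allele_2[12:14] <- NA_integer_
  sc11 <- quick_sc(rbind(g("s1", base1, base2), few), panel)
  expect_identical(nrow(cluster_individuals(sc11, match_rule(12, 0))$individuals),
                   2L)
  expect_identical(nrow(cluster_individuals(sc11, match_rule(11, 0))$individuals),
                   1L)
})

test_that("clustering is invariant to input row permutation", {
  cfg <- sim_config(n_individuals = 25)
  sim <- simulate_dataset(cfg, seed = 55)
  sc <- quick_sc(sim$replicates, cfg$panel)
  flt <- filter_high_quality(sc)
  iset1 <- cluster_individuals(flt$retained, match_rule())

  perm <- flt$retained
  set.seed(1)
  perm$samples <- perm$samples[sample(nrow(perm$samples)), ]
  perm$calls <- perm$calls[sample(nrow(perm$calls)), ]
  iset2 <- cluster_individuals(perm, match_rule())
  m1 <- iset1$membership[order(iset1$membership$sample_id), ]
  m2 <- iset2$membership[order(iset2$membership$sample_id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_identical(m1, m2)
})

test_that("error-free simulations are clustered exactly", {
  cfg <- sim_config(n_individuals = 30, failure = 0, dropout = 0,
                    false_allele = 0, contamination = 0, p_poor = 0)
  sim <- simulate_dataset(cfg, seed = 77)
  sc <- quick_sc(sim$replicates, cfg$panel)
  flt <- filter_high_quality(sc)
  iset <- cluster_individuals(flt$retained, match_rule())
  truth <- sim$samples$individual_id[
    match(iset$membership$sample_id, sim$samples$sample_id)]
  expect_equal(rand_index(iset$membership$individual_id, truth), 1)
  expect_identical(nrow(iset$individuals),
                   length(unique(sim$samples$individual_id)))
  # with no errors to tolerate, a zero-mismatch rule changes nothing
  iset0 <- cluster_individuals(flt$retained, match_rule(12, 0))
  expect_identical(nrow(iset0$individuals), nrow(iset$individuals))
})

test_that("individual counts are monotone in rule strictness", {
  cfg <- sim_config(n_individuals = 40)
  sim <- simulate_dataset(cfg, seed = 91)
  flt <- filter_high_quality(quick_sc(sim$replicates, cfg$panel))
  sens <- threshold_sensitivity(flt$retained,
                                list(match_rule(12, 3), match_rule(16, 3),
                                     match_rule(12, 0)))
  expect_true(sens$n_individuals[2] >= sens$n_individuals[1])
  expect_true(sens$n_individuals[3] >= sens$n_individuals[1])
  expect_identical(sens$percent_change[1], 0)
})

test_that("sex is read from the amelogenin consensus", {
  expect_identical(assign_sex_call(194L, 200L), "male")
  expect_identical(assign_sex_call(194L, 194L), "female")
  expect_identical(assign_sex_call(NA_integer_, NA_integer_), "unknown")

  cfg <- sim_config(n_individuals = 30, failure = 0, dropout = 0,
                    false_allele = 0, contamination = 0, p_poor = 0)
  sim <- simulate_dataset(cfg, seed = 13)
  flt <- filter_high_quality(quick_sc(sim$replicates, cfg$panel))
  iset <- cluster_individuals(flt$retained, match_rule())
  member1 <- iset$membership$sample_id[
    match(iset$individuals$individual_id, iset$membership$individual_id)]
  true_ind <- sim$samples$individual_id[
    match(member1, sim$samples$sample_id)]
  truth_sex <- sim$truth$individuals$sex[
    match(true_ind, sim$truth$individuals$individual_id)]
  expect_identical(iset$individuals$sex, truth_sex)
})

test_that("the post-hoc audit passes on a clean clustering", {
  cfg <- sim_config(n_individuals = 12, dropout = 0.03, p_poor = 0,
                    contamination = 0)
  sim <- simulate_dataset(cfg, seed = 21)
  flt <- filter_high_quality(quick_sc(sim$replicates, cfg$panel))
  iset <- cluster_individuals(flt$retained, match_rule())
  audit <- audit_individuals(iset, flt$retained)
  expect_identical(nrow(audit$violations), 0L)
  expect_identical(audit$cross_matches, 0L)
})

test_that("same-day distant samples of one individual are flagged", {
  panel <- tiny_panel(12)
  loci <- autosomal_loci(panel)
  reps <- rbind(
    reps_df("s1", 1, loci, rep(120L, 12), rep(124L, 12)),
    reps_df("s2", 1, loci, rep(120L, 12), rep(124L, 12))
  )
  sc <- quick_sc(reps, panel)
  iset <- cluster_individuals(sc, match_rule(12, 3))
  meta <- data.frame(sample_id = c("s1", "s2"),
                     collection_date = as.Date(c("2020-01-01", "2020-01-01")),
                     lon = c(5.0, 7.0), lat = c(44.5, 44.5))
  flags <- review_individuals(iset, meta, max_km = 50)
  expect_identical(nrow(flags), 1L)
  expect_gt(flags$km, 100)
  expect_identical(nrow(review_individuals(iset, meta, max_km = 500)), 0L)
})
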