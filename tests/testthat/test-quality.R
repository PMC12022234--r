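test_that("replicate scores follow the 1 / 0.5 / 0 agreement scale", {
  het <- genotype_call(120, 124)
  expect_identical(score_replicate_locus(het, het), 1)
  expect_identical(score_replicate_locus(genotype_call(120, 120), het), 0.5)
  expect_identical(score_replicate_locus(genotype_call(124, 124), het), 0.5)
  expect_identical(score_replicate_locus(genotype_call(), het), 0)
  expect_identical(
    score_replicate_locus(genotype_call(status = "disputed"), het), 0)
  # disagreement with a homozygous consensus is a corrected false allele
  expect_identical(
    score_replicate_locus(het, genotype_call(120, 120)), 0)
  # foreign allele against a heterozygous consensus
  expect_identical(
    score_replicate_locus(genotype_call(120, 128), het), 0)
  # consensus missing scores every replicate 0
  expect_identical(
    score_replicate_locus(het, genotype_call()), 0)
})

test_that("sample QI is the mean locus score over autosomal panel loci", {
  panel <- tiny_panel(2, sex = FALSE)
  # L1: both replicates match (1, 1); L2: one match, one dropout (1, 0.5)
  reps <- rbind(
    reps_df("s1", 1, c("L1", "L2"), c(120L, 130L), c(124L, 134L)),
    reps_df("s1", 2, c("L1", "L2"), c(120L, 130L), c(124L, 130L))
  )
  sc <- quick_sc(reps, panel)
  expect_equal(sort(sc$calls$qi), c(0.75, 1.0))
  expect_equal(sc$samples$mean_qi, 0.875)

  all_match <- quick_sc(
    rbind(full_sample_reps("s", panel, replicate = 1),
          full_sample_reps("s", panel, replicate = 2)), panel)
  expect_equal(all_match$samples$mean_qi, 1.0)

  all_missing <- quick_sc(
    reps_df("s", 1, c("L1", "L2"), c(NA, NA), c(NA, NA)), panel)
  expect_equal(all_missing$samples$mean_qi, 0.0)
})

test_that("QI never exceeds the sample's PCR success fraction", {
  cfg <- sim_config(n_individuals = 20)
  sim <- simulate_dataset(cfg, seed = 71)
  sc <- quick_sc(sim$replicates, cfg$panel)
  auto <- sim$replicates$locus %in% autosomal_loci(cfg$panel)
  success <- tapply(sim$replicates$status[auto] == "called",
                    sim$replicates$sample_id[auto], mean)
  qi <- sc$samples$mean_qi[match(names(success), sc$samples$sample_id)]
  expect_true(all(qi <= success + 1e-12))
})

test_that("the retention filter applies strict QI and contamination rules", {
  panel <- tiny_panel(1, sex = FALSE)
  reps <- rbind(
    # QI exactly 0.5: one match, one missing replicate
    reps_df("border", 1:2, "L1", c(120L, NA), c(124L, NA)),
    # clean high-quality sample
    reps_df("good", 1:2, "L1", c(120L, 120L), c(124L, 124L)),
    # contaminated but otherwise high-scoring
    reps_df("cont", 1:3, "L1", c(120L, 124L, 128L), c(120L, 124L, 128L))
  )
  sc <- quick_sc(reps, panel)
  flt <- filter_high_quality(sc, 0.5)
  expect_identical(flt$retained$samples$sample_id, "good")
  expect_identical(flt$n_retained, 1L)
  expect_equal(flt$retention_percent, 33.3)
  expect_error(filter_high_quality(sc, 1.5), "\\[0, 1\\]")
})

test_that("per-locus QI improves when restricted to high-quality samples", {
  cfg <- sim_config(n_individuals = 120)
  sim <- simulate_dataset(cfg, seed = 88)
  sc <- quick_sc(sim$replicates, cfg$panel)
  qs_all <- quality_summary(sc, sim$replicates)
  flt <- filter_high_quality(sc)
  hq_reps <- sim$replicates[sim$replicates$sample_id %in%
                              flt$retained$samples$sample_id, ]
  qs_hq <- quality_summary(flt$retained, hq_reps)
  expect_gt(qs_hq$mean_qi, qs_all$mean_qi)
  expect_gt(qs_hq$mean_pcr_success, qs_all$mean_pcr_success)
})

test_that("dropping a sample does not change other samples' QI", {
  panel <- tiny_panel(2, sex = FALSE)
  reps <- rbind(
    reps_df("a", 1:2, "L1", c(120L, 120L), c(124L, 120L)),
    reps_df("a", 1:2, "L2", c(130L, 130L), c(130L, 130L)),
    reps_df("b", 1, c("L1", "L2"), c(120L, NA), c(124L, NA))
  )
  sc <- quick_sc(reps, panel)
  qi_a <- sc$samples$mean_qi[sc$samples$sample_id == "a"]
  reps_only_a <- reps[reps$sample_id == "a", ]
  sc2 <- quick_sc(reps_only_a, panel)
  expect_identical(sc2$samples$mean_qi, qi_a)
})
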