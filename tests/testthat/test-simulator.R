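test_that("identical config and seed reproduce the dataset byte-for-byte", {
  cfg <- sim_config(n_individuals = 20)
  s1 <- simulate_dataset(cfg, seed = 1)
  s2 <- simulate_dataset(cfg, seed = 1)
  expect_identical(s1$replicates, s2$replicates)
  expect_identical(s1$log, s2$log)
  expect_identical(s1$truth$genotypes, s2$truth$genotypes)
  expect_identical(s1$meta, s2$meta)
  s3 <- simulate_dataset(cfg, seed = 2)
  expect_false(identical(s1$replicates, s3$replicates))
})

test_that("with all error processes off, replicates equal the truth", {
  cfg <- sim_config(n_individuals = 15, failure = 0, dropout = 0,
                    false_allele = 0, contamination = 0, p_poor = 0)
  sim <- simulate_dataset(cfg, seed = 3)
  expect_identical(sim$replicates[, c("allele_1", "allele_2")],
                   sim$truth_calls[, c("allele_1", "allele_2")])
  expect_true(all(sim$replicates$status == "called"))
  expect_identical(nrow(sim$log), 0L)
})

test_that("replaying the truth log regenerates the emitted table exactly", {
  cfg <- sim_config(n_individuals = 40, contamination = 0.1)
  sim <- simulate_dataset(cfg, seed = 4)
  expect_gt(nrow(sim$log), 0L)
  expect_true(all(c("contamination", "failure", "dropout", "false_allele")
                  %in% sim$log$event))
  expect_identical(replay_truth_log(sim), sim$replicates)
})

test_that("logged dropout frequency matches the configured rate", {
  cfg <- sim_config(n_individuals = 150, p_poor = 0, contamination = 0,
                    false_allele = 0)
  sim <- simulate_dataset(cfg, seed = 5)
  het <- sim$truth_calls$allele_1 != sim$truth_calls$allele_2
  key <- paste(sim$truth_calls$sample_id, sim$truth_calls$replicate,
               sim$truth_calls$locus)
  failed <- key %in% paste(sim$log$sample_id, sim$log$replicate,
                           sim$log$locus)[sim$log$event == "failure"]
  n_copy_draws <- 2 * sum(het & !failed)
  n_dropped <- sum(sim$log$event == "dropout" &
                     sim$log$copies == 1L)
  d_hat <- n_dropped / n_copy_draws
  se <- sqrt(cfg$dropout * (1 - cfg$dropout) / n_copy_draws)
  expect_lt(abs(d_hat - cfg$dropout), 2.5 * se)
})

test_that("genotypes are drawn under Hardy-Weinberg proportions", {
  panel <- tiny_panel(1, sex = FALSE)
  cfg <- sim_config(n_individuals = 10000, panel = panel,
                    allele_freqs = list(L1 = c("100" = 0.5, "102" = 0.5)))
  truth <- simulate_individuals(cfg, seed = 6)
  ho <- heterozygosities(truth$genotypes, "L1")$ho
  expect_lt(abs(ho - 0.5), 0.02)

  mono <- sim_config(n_individuals = 50, panel = panel,
                     allele_freqs = list(L1 = c("100" = 1)))
  tm <- simulate_individuals(mono, seed = 7)
  expect_true(all(tm$genotypes$allele_1 == 100L &
                    tm$genotypes$allele_2 == 100L))
})

test_that("sex marker genotypes encode the drawn sex", {
  cfg <- sim_config(n_individuals = 200, sex_ratio = 0.55)
  truth <- simulate_individuals(cfg, seed = 8)
  amel <- truth$genotypes[truth$genotypes$locus == sex_marker(cfg$panel), ]
  het <- amel$allele_1 != amel$allele_2
  expect_identical(unname(het),
                   truth$individuals$sex[match(amel$individual_id,
                                               truth$individuals$individual_id)]
                   == "male")
  expect_lt(abs(mean(het) - 0.55), 0.1)
})

test_that("contaminated samples surface extra alleles and get flagged", {
  cfg <- sim_config(n_individuals = 40, contamination = 0.5,
                    failure = 0, dropout = 0, false_allele = 0, p_poor = 0)
  sim <- simulate_dataset(cfg, seed = 9)
  mixed <- !is.na(sim$samples$contaminant_id)
  expect_gt(sum(mixed), 0L)
  sc <- consensus_dataset(sim$replicates, cfg$panel)
  flagged <- sc$samples$sample_id[sc$samples$contaminated]
  # flagged samples are exactly a subset of truly mixed samples
  expect_true(all(flagged %in% sim$samples$sample_id[mixed]))
  # with 22 polymorphic loci nearly every true mixture shows > 2 alleles
  expect_gt(length(flagged), 0.8 * sum(mixed))
})

test_that("recapture structure respects its configured distribution", {
  cfg <- sim_config(n_individuals = 600)
  sim <- simulate_dataset(cfg, seed = 10)
  k <- table(factor(sim$samples$individual_id,
                    levels = sim$truth$individuals$individual_id))
  expect_true(all(k >= 1L & k <= cfg$max_samples))
  expect_lt(abs(mean(k >= 2) - cfg$p_recapture), 0.06)
  expect_lt(abs(mean(k[k >= 2]) - 4.03), 0.35)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(dropout = 1.2), "probabilities")
  expect_error(sim_config(n_alleles = 0L), "at least one allele")
  panel <- tiny_panel(1, sex = FALSE)
  expect_error(
    sim_config(panel = panel, allele_freqs = list(L1 = c("100" = 0.7))),
    "sum to 1")
})
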