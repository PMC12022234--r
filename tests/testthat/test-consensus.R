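test_that("consensus retains every allele observed across replicates", {
  panel <- tiny_panel(1, sex = FALSE)
  reps <- reps_df("s1", 1:4, "L1",
                  c(120L, 120L, NA, 120L), c(124L, 120L, NA, 124L))
  sc <- build_consensus(reps, panel)
  expect_identical(sc$calls$allele_1, 120L)
  expect_identical(sc$calls$allele_2, 124L)
  expect_identical(sc$calls$status, "called")
  expect_false(sc$samples$contaminated)
  expect_identical(sc$samples$n_replicates, 4L)

  homo <- build_consensus(reps_df("s1", 1:2, "L1", c(120L, 120L),
                                  c(120L, 120L)), panel)
  expect_identical(homo$calls$allele_1, 120L)
  expect_identical(homo$calls$allele_2, 120L)
})

test_that("more than two pooled alleles flags contamination", {
  panel <- tiny_panel(1, sex = FALSE)
  reps <- reps_df("s1", 1:3, "L1", c(120L, 124L, 128L),
                  c(120L, 124L, 128L))
  sc <- build_consensus(reps, panel)
  expect_true(sc$samples$contaminated)
  expect_identical(sc$calls$status, "missing")  # no diploid consensus

  # a CONT-scored replicate call also flags the sample
  reps2 <- reps_df("s2", 1:2, "L1", c(120L, NA), c(124L, NA),
                   status = c("called", "contaminated"))
  expect_true(build_consensus(reps2, panel)$samples$contaminated)
})

test_that("consensus is invariant to replicate order and missing padding", {
  panel <- tiny_panel(3)
  set.seed(9)
  reps <- rbind(
    reps_df("s1", 1, panel$name, c(120L, 130L, NA, 194L),
            c(124L, 130L, NA, 200L)),
    reps_df("s1", 2, panel$name, c(120L, NA, 110L, 194L),
            c(120L, NA, 112L, 194L))
  )
  base <- consensus_dataset(reps, panel)
  shuffled <- consensus_dataset(reps[sample(nrow(reps)), ], panel)
  expect_identical(base$calls, shuffled$calls)

  padded <- rbind(reps, reps_df("s1", 3, panel$name, rep(NA, 4), rep(NA, 4)))
  sc_pad <- consensus_dataset(padded, panel)
  expect_identical(sc_pad$calls[, c("allele_1", "allele_2", "status")],
                   base$calls[, c("allele_1", "allele_2", "status")])
  expect_identical(sc_pad$samples$n_replicates, 3L)
})

test_that("consensus heterozygote alleles each trace back to a replicate", {
  cfg <- sim_config(n_individuals = 15)
  sim <- simulate_dataset(cfg, seed = 33)
  sc <- consensus_dataset(sim$replicates, cfg$panel)
  het <- sc$calls[sc$calls$status == "called" &
                    sc$calls$allele_1 != sc$calls$allele_2, ]
  rep_called <- sim$replicates[sim$replicates$status == "called", ]
  key <- paste(rep_called$sample_id, rep_called$locus)
  for (i in sample(nrow(het), min(50, nrow(het)))) {
    rows <- rep_called[key == paste(het$sample_id[i], het$locus[i]), ]
    seen <- c(rows$allele_1, rows$allele_2)
    expect_true(het$allele_1[i] %in% seen && het$allele_2[i] %in% seen)
  }
})

test_that("single-sample contract errors are raised", {
  panel <- tiny_panel(1, sex = FALSE)
  expect_error(build_consensus(reps_df("s1", 1, "L1", 120L, 124L)[0, ],
                               panel), "at least one replicate")
  mixed <- reps_df(c("s1", "s2"), c(1, 1), c("L1", "L1"),
                   c(120L, 120L), c(124L, 124L))
  expect_error(build_consensus(mixed, panel), "mix sample ids")
})

test_that("dataset counts separate no-amplification and contamination", {
  panel <- tiny_panel(2, sex = FALSE)
  reps <- rbind(
    reps_df("ok", 1, c("L1", "L2"), c(120L, 130L), c(124L, 130L)),
    reps_df("blank", 1, c("L1", "L2"), c(NA, NA), c(NA, NA)),
    reps_df("cont", 1:3, "L1", c(120L, 124L, 128L), c(120L, 124L, 128L))
  )
  counts <- consensus_counts(consensus_dataset(reps, panel))
  expect_identical(counts$n_samples, 3L)
  expect_identical(unname(counts$no_amplification["count"]), 1)
  expect_identical(unname(counts$contaminated["count"]), 1)
  expect_identical(unname(counts$retained["count"]), 1)
  expect_equal(unname(counts$no_amplification["percent"]), 33.3)

  empty <- consensus_counts(consensus_dataset(
    reps_df("x", 1, "L1", 120L, 124L)[0, ], panel))
  expect_identical(empty$n_samples, 0L)
})
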