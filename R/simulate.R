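#' Configuration for the synthetic multitube dataset generator
#'
#' The generator reproduces the statistical structure the pipeline assumes:
#' diploid multi-locus genotypes drawn under Hardy-Weinberg equilibrium from
#' per-locus allele frequencies; a recapture structure in which a fraction
#' of individuals is sampled repeatedly; four PCR replicates per noninvasive
#' sample and two for tissue or blood; per-locus amplification failure,
#' per-allele-copy dropout, rare false alleles, and whole-sample
#' contamination by a second individual; and a two-class (good/poor) sample
#' quality mixture reproducing the bimodal quality-index distribution of
#' degraded field samples.
#'
#' @param n_individuals Number of individuals in the population sample.
#' @param panel A [locus_panel].
#' @param n_alleles Integer vector (one per autosomal locus, recycled): how
#'   many alleles segregate per locus. The default mirrors the allele counts
#'   observed in the French wolf monitoring panel.
#' @param concentration Symmetric Dirichlet concentration for drawing
#'   allele frequencies (1 = uniform over the simplex).
#' @param allele_freqs Optional list of per-locus frequency vectors
#'   overriding the Dirichlet draw (names = autosomal loci).
#' @param p_recapture Probability an individual is sampled more than once.
#' @param extra_mean Mean number of samples beyond the second for
#'   recaptured individuals (Poisson); with the defaults recaptured
#'   individuals average ~4 samples, and no individual exceeds
#'   `max_samples`.
#' @param max_samples Cap on samples per individual.
#' @param sample_type_probs Named proportions over scat, tissue, urine,
#'   hair, blood.
#' @param failure Per-locus amplification failure probability (good-quality
#'   class).
#' @param dropout Per-allele-copy dropout probability `d`; an observable
#'   dropout (heterozygote appearing homozygous) occurs with probability
#'   `2d(1-d)`.
#' @param false_allele Per-replicate probability `f` that one of the
#'   replicate's called loci carries a false allele (a scoring slip
#'   substituting a wrong fragment size).
#' @param contamination Per-sample probability (noninvasive samples) that
#'   the sample is a mixture with a second individual.
#' @param p_poor Proportion of noninvasive samples in the poor-quality
#'   class.
#' @param poor_failure_mult,poor_dropout_mult Multipliers applied to
#'   `failure` and `dropout` for poor-quality samples (capped at 1).
#' @param sex_ratio Proportion of males.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 50L,
                       panel = default_wolf_panel(),
                       n_alleles = c(7L, 8L, 8L, 6L, 8L, 7L, 5L, 6L, 15L,
                                     4L, 8L, 7L, 15L, 13L, 6L, 16L, 9L, 6L,
                                     11L, 9L, 8L, 6L),
                       concentration = 1,
                       allele_freqs = NULL,
                       p_recapture = 681 / 1735,
                       extra_mean = 2.03,
                       max_samples = 35L,
                       sample_type_probs = c(scat = 0.838, tissue = 0.070,
                                             urine = 0.062, hair = 0.020,
                                             blood = 0.010),
                       failure = 0.08,
                       dropout = 0.07,
                       false_allele = 0.01,
                       contamination = 0.02,
                       p_poor = 0.3,
                       poor_failure_mult = 6,
                       poor_dropout_mult = 3,
                       sex_ratio = 0.55) {
  stopifnot(inherits(panel, "locus_panel"), n_individuals >= 1)
  probs <- c(p_recapture, failure, dropout, false_allele, contamination,
             p_poor, sex_ratio)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  auto <- autosomal_loci(panel)
  n_alleles <- rep_len(as.integer(n_alleles), length(auto))
  if (any(n_alleles < 1L)) stop("each locus needs at least one allele")
  if (!is.null(allele_freqs)) {
    stopifnot(is.list(allele_freqs),
              setequal(names(allele_freqs), auto))
    bad <- vapply(allele_freqs,
                  function(f) abs(sum(f) - 1) > 1e-8 || any(f < 0),
                  logical(1))
    if (any(bad)) stop("allele frequency vectors must be nonnegative and sum to 1")
  }
  structure(list(
    n_individuals = as.integer(n_individuals), panel = panel,
    n_alleles = n_alleles, concentration = concentration,
    allele_freqs = allele_freqs, p_recapture = p_recapture,
    extra_mean = extra_mean, max_samples = as.integer(max_samples),
    sample_type_probs = sample_type_probs, failure = failure,
    dropout = dropout, false_allele = false_allele,
    contamination = contamination, p_poor = p_poor,
    poor_failure_mult = poor_failure_mult,
    poor_dropout_mult = poor_dropout_mult, sex_ratio = sex_ratio
  ), class = "sim_config")
}

# allele size lattice of a locus (2-bp microsatellite steps)
.allele_lattice <- function(panel, locus) {
  i <- match(locus, panel$name)
  seq(panel$size_min[i], panel$size_max[i], by = 2L)
}

.rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, alpha)
  g / sum(g)
}

#' Draw true individual genotypes
#'
#' Each individual's genotype is drawn locus-independently under HWE: two
#' allele copies i.i.d. from the locus frequency vector. The sex marker is
#' drawn from the configured sex ratio (heterozygous = male).
#'
#' @param config A [sim_config].
#' @param seed Optional integer seed.
#' @return List `individuals` (data frame `individual_id`, `sex`),
#'   `genotypes` (long data frame `individual_id`, `locus`, `allele_1`,
#'   `allele_2`), `freqs` (named list of per-locus frequency vectors, names
#'   are allele sizes).
#' @export
simulate_individuals <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- config$panel
  auto <- autosomal_loci(panel)
  nI <- config$n_individuals

  freqs <- if (!is.null(config$allele_freqs)) {
    lapply(config$allele_freqs, function(f) {
      if (is.null(names(f))) stop("allele frequencies must be named by size")
      f
    })[auto]
  } else {
    stats::setNames(lapply(seq_along(auto), function(l) {
      lattice <- .allele_lattice(panel, auto[l])
      k <- config$n_alleles[l]
      if (k > length(lattice)) stop("more alleles than lattice sites at ",
                                    auto[l])
      sizes <- sort(sample(lattice, k))
      if (k == 1L) return(stats::setNames(1, sizes))
      stats::setNames(.rdirichlet1(k, config$concentration), sizes)
    }), auto)
  }
  degenerate <- vapply(freqs, function(f) any(f < 0) || sum(f) <= 0,
                       logical(1))
  if (any(degenerate)) stop("degenerate frequency vector")

  ind_ids <- sprintf("W%04d", seq_len(nI))
  geno <- do.call(rbind, lapply(auto, function(loc) {
    sizes <- as.integer(names(freqs[[loc]]))
    a <- matrix(sizes[sample.int(length(sizes), 2 * nI, replace = TRUE,
                                 prob = freqs[[loc]])], ncol = 2)
    data.frame(individual_id = ind_ids, locus = loc,
               allele_1 = pmin(a[, 1], a[, 2]),
               allele_2 = pmax(a[, 1], a[, 2]), stringsAsFactors = FALSE)
  }))

  sex <- ifelse(stats::runif(nI) < config$sex_ratio, "male", "female")
  sexm <- sex_marker(panel)
  if (!is.na(sexm)) {
    xy <- c(194L, 200L)  # X- and Y-specific amelogenin fragment sizes
    geno <- rbind(geno, data.frame(
      individual_id = ind_ids, locus = sexm,
      allele_1 = xy[1],
      allele_2 = ifelse(sex == "male", xy[2], xy[1]),
      stringsAsFactors = FALSE))
  }
  geno <- geno[order(match(geno$individual_id, ind_ids),
                     match(geno$locus, panel$name)), ]
  rownames(geno) <- NULL
  list(individuals = data.frame(individual_id = ind_ids, sex = sex,
                                stringsAsFactors = FALSE),
       genotypes = geno, freqs = freqs)
}

#' Generate replicate genotype data with a complete truth log
#'
#' Emits the replicate-level dataset for a set of true genotypes: samples
#' are allocated to individuals by the recapture model, typed, assigned a
#' quality class, optionally contaminated by a second individual, then each
#' sample x replicate x locus observation passes through amplification
#' failure, per-allele-copy dropout and the per-replicate false-allele
#' process. Every injected event is logged with its coordinates so that
#' [replay_truth_log()] regenerates the emitted table exactly and
#' parameter-recovery experiments can compare estimates with realised event
#' frequencies.
#'
#' @param truth Output of [simulate_individuals()].
#' @param config The [sim_config] used.
#' @param seed Optional integer seed.
#' @return A `sim_dataset` list: `samples` (sample table with true
#'   individual, type, quality class, contaminant), `replicates` (canonical
#'   replicate data frame), `truth_calls` (per-row source genotype before
#'   errors), `log` (event log), `meta` (sample metadata with synthetic
#'   dates/coordinates), plus `truth`, `config`, `seed`.
#' @export
simulate_replicates <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- config$panel
  loci <- panel$name
  L <- length(loci)
  nI <- nrow(truth$individuals)
  ind_ids <- truth$individuals$individual_id

  # genotype matrices ind x locus
  gkey <- paste(truth$genotypes$individual_id, truth$genotypes$locus,
                sep = "\r")
  idx <- match(paste(rep(ind_ids, each = L), rep(loci, nI), sep = "\r"),
               gkey)
  G1 <- matrix(truth$genotypes$allele_1[idx], nrow = nI, byrow = TRUE)
  G2 <- matrix(truth$genotypes$allele_2[idx], nrow = nI, byrow = TRUE)

  # recapture structure
  extra <- pmin(stats::rpois(nI, config$extra_mean),
                config$max_samples - 2L)
  k <- ifelse(stats::runif(nI) < config$p_recapture, 2L + extra, 1L)
  nS <- sum(k)
  s_ind <- rep(seq_len(nI), k)
  sample_ids <- sprintf("S%05d", seq_len(nS))
  type <- sample(names(config$sample_type_probs), nS, replace = TRUE,
                 prob = config$sample_type_probs)
  noninv <- !(type %in% c("tissue", "blood"))
  n_reps <- ifelse(noninv, 4L, 2L)
  poor <- noninv & stats::runif(nS) < config$p_poor
  fail_p <- pmin(1, config$failure *
                   ifelse(poor, config$poor_failure_mult, 1))
  drop_p <- pmin(1, config$dropout *
                   ifelse(poor, config$poor_dropout_mult, 1))
  contaminant <- rep(NA_integer_, nS)
  if (nI >= 2L) {
    hit <- noninv & stats::runif(nS) < config$contamination
    contaminant[hit] <- vapply(s_ind[hit], function(i)
      sample(setdiff(seq_len(nI), i), 1L), integer(1))
  }

  # observation grid
  row_s <- rep(seq_len(nS), n_reps * L)
  row_r <- unlist(lapply(n_reps, function(r) rep(seq_len(r), each = L)),
                  use.names = FALSE)
  row_l <- unlist(lapply(n_reps, function(r) rep(seq_len(L), r)),
                  use.names = FALSE)
  nrow_g <- length(row_s)

  # source genotype (contaminated samples: 50/50 own vs contaminant per
  # replicate x locus -- a mixture template competing in each reaction)
  src <- s_ind[row_s]
  mix <- !is.na(contaminant[row_s]) & stats::runif(nrow_g) < 0.5
  src[mix] <- contaminant[row_s][mix]
  t1 <- G1[cbind(src, row_l)]
  t2 <- G2[cbind(src, row_l)]

  fail <- stats::runif(nrow_g) < fail_p[row_s]
  d <- drop_p[row_s]
  drop1 <- !fail & stats::runif(nrow_g) < d
  drop2 <- !fail & stats::runif(nrow_g) < d
  het <- t1 != t2

  o1 <- t1; o2 <- t2
  gone <- fail | (drop1 & drop2)
  # heterozygote single-copy dropout: apparent homozygote
  sel <- !gone & het & drop1
  o1[sel] <- t2[sel]
  sel <- !gone & het & drop2 & !drop1
  o2[sel] <- t1[sel]
  o1[gone] <- NA_integer_; o2[gone] <- NA_integer_

  # event log ------------------------------------------------------------
  logs <- list()
  add_log <- function(rows, event, allele = NA_integer_,
                      copies = NA_integer_, replaced = NA_integer_,
                      a1 = NA_integer_, a2 = NA_integer_) {
    if (!length(rows)) return()
    logs[[length(logs) + 1L]] <<- data.frame(
      sample_id = sample_ids[row_s[rows]], replicate = row_r[rows],
      locus = loci[row_l[rows]], event = event,
      allele = rep_len(allele, length(rows)),
      copies = rep_len(copies, length(rows)),
      replaced = rep_len(replaced, length(rows)),
      allele_1 = rep_len(a1, length(rows)),
      allele_2 = rep_len(a2, length(rows)), stringsAsFactors = FALSE)
  }
  w <- which(mix)
  add_log(w, "contamination", a1 = t1[w], a2 = t2[w])
  add_log(which(fail), "failure")
  # observable dropout events
  w <- which(!fail & het & drop1)
  add_log(w, "dropout", allele = t1[w], copies = 1L)
  w <- which(!fail & het & drop2)
  add_log(w, "dropout", allele = t2[w], copies = 1L)
  w <- which(!fail & !het & drop1 & drop2)
  add_log(w, "dropout", allele = t1[w], copies = 2L)

  # false alleles: one per affected replicate, at a random called locus
  unit_first <- which(row_l == 1L)
  n_units <- length(unit_first)
  fa_units <- which(stats::runif(n_units) < config$false_allele)
  for (u in fa_units) {
    rows <- unit_first[u] + seq_len(L) - 1L
    called <- rows[!is.na(o1[rows])]
    if (!length(called)) next
    rw <- if (length(called) == 1L) called else sample(called, 1L)
    lat <- .allele_lattice(panel, loci[row_l[rw]])
    wrong <- setdiff(lat, c(t1[rw], t2[rw]))
    if (!length(wrong)) next
    new_a <- if (length(wrong) == 1L) wrong else sample(wrong, 1L)
    pos <- sample(1:2, 1L)
    old <- if (pos == 1L) o1[rw] else o2[rw]
    if (pos == 1L) o1[rw] <- new_a else o2[rw] <- new_a
    add_log(rw, "false_allele", allele = as.integer(new_a),
            replaced = as.integer(old))
  }

  replicates <- data.frame(
    sample_id = sample_ids[row_s], replicate = row_r, locus = loci[row_l],
    allele_1 = pmin(o1, o2), allele_2 = pmax(o1, o2),
    status = ifelse(is.na(o1), "missing", "called"),
    stringsAsFactors = FALSE
  )
  truth_calls <- data.frame(
    sample_id = sample_ids[row_s], replicate = row_r, locus = loci[row_l],
    allele_1 = pmin(t1, t2), allele_2 = pmax(t1, t2), status = "called",
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = sample_ids, individual_id = ind_ids[s_ind],
    sample_type = type, n_replicates = n_reps,
    quality_class = ifelse(poor, "poor", "good"),
    contaminant_id = ifelse(is.na(contaminant), NA_character_,
                            ind_ids[contaminant]),
    stringsAsFactors = FALSE
  )
  meta <- data.frame(
    sample_id = sample_ids, sample_type = type,
    collection_date = as.Date("2006-01-01") +
      sample.int(6209L, nS, replace = TRUE) - 1L,
    lon = round(stats::runif(nS, 5, 7.5), 4),
    lat = round(stats::runif(nS, 43.5, 46), 4),
    stringsAsFactors = FALSE
  )
  meta$location <- paste0(meta$lon, ",", meta$lat)

  structure(list(samples = samples, replicates = replicates,
                 truth_calls = truth_calls,
                 log = if (length(logs)) do.call(rbind, logs) else
                   data.frame(sample_id = character(0),
                              replicate = integer(0), locus = character(0),
                              event = character(0), allele = integer(0),
                              copies = integer(0), replaced = integer(0),
                              allele_1 = integer(0), allele_2 = integer(0)),
                 meta = meta, truth = truth, config = config, seed = seed),
            class = "sim_dataset")
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_individuals()] then
#' [simulate_replicates()] under a single seed. `(config, seed)` fully
#' determines the output.
#'
#' @param config A [sim_config].
#' @param seed Integer seed.
#' @return A `sim_dataset` (see [simulate_replicates()]).
#' @export
simulate_dataset <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- simulate_individuals(config)
  simulate_replicates(truth, config)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$truth$individuals), " individuals, ",
      nrow(x$samples), " samples, ", nrow(x$replicates),
      " replicate calls, ", nrow(x$log), " logged events\n", sep = "")
  invisible(x)
}

#' Regenerate the replicate table from truth genotypes and the event log
#'
#' Replays the logged contamination, failure, dropout and false-allele
#' events on top of the true genotypes. The result must equal the emitted
#' replicate table exactly; this is the reconciliation guarantee that makes
#' the truth log a complete account of every injected error.
#'
#' @param sim A `sim_dataset`.
#' @return A replicate data frame in the same order as `sim$replicates`.
#' @export
replay_truth_log <- function(sim) {
  panel <- sim$config$panel
  loci <- panel$name
  L <- length(loci)
  n_reps <- sim$samples$n_replicates
  row_s <- rep(seq_len(nrow(sim$samples)), n_reps * L)
  row_r <- unlist(lapply(n_reps, function(r) rep(seq_len(r), each = L)),
                  use.names = FALSE)
  row_l <- unlist(lapply(n_reps, function(r) rep(seq_len(L), r)),
                  use.names = FALSE)
  key <- paste(sim$samples$sample_id[row_s], row_r, loci[row_l], sep = "\r")

  gkey <- paste(sim$truth$genotypes$individual_id,
                sim$truth$genotypes$locus, sep = "\r")
  own <- match(paste(sim$samples$individual_id[row_s], loci[row_l],
                     sep = "\r"), gkey)
  a1 <- sim$truth$genotypes$allele_1[own]
  a2 <- sim$truth$genotypes$allele_2[own]

  lg <- sim$log
  lkey <- paste(lg$sample_id, lg$replicate, lg$locus, sep = "\r")

  cont <- lg$event == "contamination"
  m <- match(key, lkey[cont])
  hit <- !is.na(m)
  a1[hit] <- lg$allele_1[cont][m[hit]]
  a2[hit] <- lg$allele_2[cont][m[hit]]

  fail <- lg$event == "failure"
  gone <- key %in% lkey[fail]

  dr <- which(lg$event == "dropout")
  for (i in dr) {
    at <- match(lkey[i], key)
    if (lg$copies[i] == 2L) {
      a1[at] <- NA_integer_; a2[at] <- NA_integer_
    } else if (!is.na(a1[at]) && a1[at] == lg$allele[i]) {
      a1[at] <- a2[at]
    } else {
      a2[at] <- a1[at]
    }
  }
  # two single-copy dropout rows at the same observation => missing
  dd <- table(lkey[dr][lg$copies[dr] == 1L])
  dbl <- names(dd)[dd == 2L]
  at <- match(dbl, key)
  a1[at] <- NA_integer_; a2[at] <- NA_integer_

  fa <- which(lg$event == "false_allele")
  for (i in fa) {
    at <- match(lkey[i], key)
    if (!is.na(a1[at]) && a1[at] == lg$replaced[i]) {
      a1[at] <- lg$allele[i]
    } else {
      a2[at] <- lg$allele[i]
    }
  }
  a1[gone] <- NA_integer_; a2[gone] <- NA_integer_

  data.frame(
    sample_id = sim$samples$sample_id[row_s], replicate = row_r,
    locus = loci[row_l], allele_1 = pmin(a1, a2), allele_2 = pmax(a1, a2),
    status = ifelse(is.na(a1), "missing", "called"),
    stringsAsFactors = FALSE
  )
}
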