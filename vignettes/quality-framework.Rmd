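---
title: "A quality framework for noninvasive microsatellite genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quality framework for noninvasive microsatellite genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nivgeno)
```

## The problem

Noninvasive samples (scat, urine, hair) are the workhorse of long-term
monitoring of elusive carnivores such as the gray wolf. Their DNA is
degraded and dilute, and microsatellite genotypes read from such templates
suffer two characteristic errors: **allelic dropout** (AD), where one
allele of a heterozygote fails to amplify and the genotype appears
homozygous, and **false alleles** (FA), artefactual peaks scored as real
alleles. Left uncontrolled, both errors fabricate "new" individuals and
corrupt every downstream quantity — population size, sex ratio,
heterozygosity.

`nivgeno` implements the multitube quality framework: amplify each sample
several times independently (four replicates for noninvasive samples, two
for tissue), reconcile the replicates into a consensus genotype, score the
agreement into a quality index, identify individuals with an error-tolerant
matching rule, and *measure* — rather than assume — the error rates that
survive each control step.

## Models and procedures

### Sample consensus and contamination

Every allele observed in any called replicate of a sample is treated as a
true allele (false alleles are presumed corrected at electropherogram
scoring); the consensus at a locus is the pooled set of distinct alleles.
One allele is a homozygote, two a heterozygote, none a missing call. More
than two distinct alleles — within one replicate (scored on input as a
`CONT` token) or pooled across replicates — is biologically impossible for
one diploid individual, so the sample is flagged contaminated and excluded
from matching and diversity stages. Both triggers are live because a real
mixture reveals itself either way, depending on which template wins each
reaction.

Single-observation alleles are accepted (no two-replicate confirmation
rule). This is deliberate: requiring confirmation would discard most of
the information in marginal samples, and the residual error that this
leniency admits is exactly what the staged error estimators quantify.

### Quality index

Each replicate is scored against its sample's consensus per locus: 1 for
an exact match, 0.5 for a dropout-consistent homozygote (one consensus
allele, heterozygous consensus) — the replicate still carries usable
information — and 0 for a missing, disputed or otherwise discordant call.
A replicate disagreeing with a *homozygous* consensus is a corrected false
allele, not a dropout, and scores 0. The per-sample QI averages the locus
scores over all 22 autosomal loci (the sex marker is never counted), so a
sample that amplifies nowhere scores 0 and a flawless one scores 1.
Samples with QI > 0.5 (strict) and no contamination are retained; on
simulated field-like data this keeps roughly two thirds of genotyped
samples, concentrated in the good-quality class.

### Individual identification

Two retained samples are attributed to the same individual when they share
at least 12 autosomal loci called in both and disagree by at most 3
alleles over those loci (mismatches counted per allele under the best
pairing of the unordered pairs; missing data never separate samples). The
tolerance follows from the binomial mismatch model: if each of n compared
loci independently carries an error with probability p, the chance of at
least one mismatch between two samples of the same animal is
1 − (1 − p)ⁿ — at n = 12 and the high-quality dropout rate p ≈ 0.071,
about 0.587 — and ~99% of expected error counts fall between one and
three. A stricter rule would shred true recapture histories; a looser one
would merge siblings, whose collision probability is tracked by PI_sibs.

Clustering is greedy and deterministic: samples are processed in order of
decreasing QI (ties by sample id) and join the best-matching existing
individual (fewest mismatches, then most shared loci, then earliest
founded) or found a new one. Determinism makes reruns auditable; the
`audit_individuals()` report checks post hoc that every member still
satisfies the rule against the final consensus and counts cross-individual
pairs that would also have matched (intransitivity).

The **individual consensus** is, per locus, the modal genotype across
member samples; tied modes that are mutually consistent (a
dropout-truncated homozygote and the full heterozygote) are completed to
their union — the dropout-favouring prior, since dropout is an order of
magnitude more frequent than false alleles — while inconsistent ties
resolve toward the highest-QI member. The majority step matters: an
unconditional union would absorb any residual false allele carried by one
member into the individual consensus, making the residual false-allele
rate unmeasurable by construction. With a majority rule, a minority FA is
outvoted and surfaces as an FA_res event; only two-member individuals and
even splits retain the dropout-favouring ambiguity.

Auxiliary evidence (dates, locations) never decides a merge: the
`review_individuals()` report flags same-day samples of one individual
collected implausibly far apart (threshold configurable, default 50 km)
for human review.

### Staged error rates

All rates are per locus over successful amplifications, following the
replicate-comparison estimators of Broquet & Petit:

* **AD** — replicates vs sample consensus, heterozygous consensus only:
  share of called observations homozygous for exactly one consensus
  allele. Computed over all genotyped samples.
* **AD_high** — the same restricted to retained (QI > 0.5,
  uncontaminated) samples.
* **AD_res**, **FA_res** — sample consensus genotypes of recaptured
  individuals (≥ 2 samples) vs the individual consensus; FA_res counts
  observations carrying at least one allele absent from the reference.

An observation homozygous for a foreign allele, or heterozygous sharing
only one allele with a heterozygous reference, is an FA event, not AD.
Loci with empty denominators report `NA`, never 0, and panel means average
only estimable loci. Every counted event is listed in an event log with
its sample/replicate/locus coordinates.

On field-like simulations the cascade reproduces the expected ordering
AD ≥ AD_high ≥ AD_res: filtering removes the error-prone samples, and the
multitube consensus removes most of what remains.

### Population diversity

Per locus: allele counts, observed heterozygosity, Nei's unbiased expected
heterozygosity (1 − Σp²)·2n/(2n−1), F_IS = 1 − Ho/He, and a
Hardy–Weinberg permutation test: allele copies are permuted within the
population and re-paired, the statistic is F_IS, and the two-sided p-value
uses the add-one estimator (1 + #{|F_perm| ≥ |F_obs|})/(B + 1). Expected
heterozygosity is permutation-invariant, so the null is driven by the
permuted Ho alone — an optimisation, not an approximation. The overall
F_IS is 1 − mean(Ho)/mean(He) with unweighted locus means and a
bootstrap-over-loci 95% CI; published aggregation conventions for overall
F_IS vary and are often unrecoverable, so this quantity is property-tested
on simulations rather than against any printed value. The sex ratio is
tested with the standard one-proportion z against 0.5.

PI_sibs, the probability that two full siblings share a multi-locus
genotype, is the conservative benchmark for identification power. Over
subsets of k loci the package reports the minimum, maximum and mean
multi-locus PI_sibs; the mean over all C(n,k) subsets is
e_k(values)/C(n,k) with e_k the k-th elementary symmetric polynomial,
computed by the incremental recurrence in O(n²) rather than subset
enumeration (verified against enumeration for n ≤ 12 in the suite).

The null-allele estimator fits, by EM, the Hardy–Weinberg multinomial with
one unobservable allele under a stated observation model: a null
heterozygote presents as an apparent homozygote of its visible allele, a
null homozygote as missing. Missing counts default to 0; if supplied they
are attributed to null homozygotes, so amplification-failure missingness
should not be passed in. Convergence: relative log-likelihood change
< 1e−8, capped at 10,000 iterations, non-convergence flagged.

## The simulator

`sim_config()` defines the study conditions; its defaults emulate the
structure of a national wolf-monitoring dataset:

| Parameter | Default | What it emulates |
|---|---|---|
| allele counts | 7,8,8,…,6 (panel Na values, 4–16) | published allelic richness per locus; frequencies ~ symmetric Dirichlet(1) |
| `p_recapture` | 681/1735 | share of individuals sampled more than once |
| `extra_mean` | 2.03 | recaptured individuals average ≈ 4 samples (2 + Poisson, capped at 35) |
| `sample_type_probs` | scat .838, tissue .070, urine .062, hair .020, blood .010 | observed sample-type mix; tissue/blood get 2 replicates, others 4 |
| `failure` | 0.08 | per-locus amplification failure, good-quality class |
| `dropout` | 0.07 | per-allele-copy dropout; an observable dropout occurs at 2d(1−d) |
| `false_allele` | 0.01 | per-replicate chance of one mis-scored allele at a random called locus |
| `contamination` | 0.02 | per-sample mixture with a second individual (noninvasive only) |
| `p_poor`, multipliers | 0.3, ×6 failure, ×3 dropout | two-class quality mixture reproducing the bimodal QI distribution |
| `sex_ratio` | 0.55 | male share |

Dropout acts per allele copy, so heterozygote dropout probability is
2d(1−d) and estimators are compared against realised truth-log
frequencies, never against the raw d. False alleles are injected per
replicate (a rare scoring slip corrupting one locus of one replicate)
rather than independently per locus; this matches the framework's premise
that FA is corrected at scoring and only a residue survives, and keeps the
injected process on the same order as the residual rates the real data
show. Contamination draws each replicate × locus genotype from the host or
the contaminating individual with equal probability, which is what makes
pooled >2-allele detection effective on polymorphic panels.

Every injected event — contamination source, failure, each dropped copy,
each substituted allele — is logged with its coordinates, and
`replay_truth_log()` regenerates the emitted replicate table exactly from
truth + log; the suite asserts byte identity. `(config, seed)` fully
determines all output.

What the simulator does **not** model: relatedness among individuals (all
unrelated, so PI_sibs-scale collisions are absent by construction),
spatial sampling structure, per-locus quality differences beyond allele
counts, allele-size-dependent dropout, and analyst behaviour. Passing
tests therefore demonstrate internal consistency of the estimators and
pipeline under the stated generative model, not performance on any
particular real dataset.

## Calibration experiments and numerical choices

`recovery_experiment()` simulates K datasets, runs the full pipeline on
each, and compares panel-mean estimates with truth-side frequencies
computed on the estimator's own comparison sets — for initial AD, each
replicate observation is classified against its *source* genotype (the
contaminant's when contamination injected it), so the truth side is exact.
The calibration study in the acceptance suite uses 100 datasets of 50
individuals, 22 loci, 4 replicates, dropout 0.07 and false-allele 0.01
with homogeneous sample quality and no contamination: estimator
calibration is only well-defined when the estimand is a single dropout
regime, because the replicate-vs-consensus estimator conditions on the
consensus it builds, and mixing quality classes shifts that conditioning
(the measured discrepancy under the heterogeneous default is about −0.01,
several Monte-Carlo SEs). The Monte-Carlo SE of a mean is sd/√K.

The Hardy–Weinberg calibration check simulates 1000 null loci of 200
genotypes each, with allele counts drawn from the panel's published Na
values: a two-sided permutation p-value on a discrete Ho lattice is
conservative in proportion to tie mass, and few-allele loci (3–5 alleles)
push the achieved level visibly below nominal, while panel-realistic
richness holds it near 0.045 at α = 0.05. For the same reason exact
uniformity of these p-values (e.g. a Kolmogorov–Smirnov check) is not
attainable and calibration is asserted via the rejection rate.

Other numerical conventions: allele labels are integer fragment sizes and
text labels are rejected rather than coerced; allele pairs are stored in
nondecreasing order and mismatches use the best-pairing multiset overlap;
percentages in summaries are reported to one decimal; permutation and
bootstrap stages accept an explicit seed and restore the RNG state;
undefined rates propagate as `NA` so that panel means stay honest.

Problem sizes in the shipped suite and acceptance script (100 calibration
datasets of 50 individuals; 1000 null loci × 1000 permutations; a
300-individual end-to-end emulation) were chosen as the smallest designs
whose Monte-Carlo error is clearly below the effects being checked.

## Known limitations

* Greedy clustering is order-deterministic but not globally optimal; rare
  intransitive configurations are reported by the audit, not resolved.
* The 2-member individual consensus cannot distinguish a residual false
  allele from a dropout; the dropout-favouring prior is applied and the
  residual FA estimate is correspondingly a slight underestimate.
* The null-allele model attributes supplied missing counts entirely to
  null homozygotes; with substantial amplification failure, fit the model
  on called genotypes only.
* The mitotype screen assumes a curated, equal-length, alignment-free
  reference panel; indel-containing haplotypes need external alignment
  first.
* Genepop export uses 3-digit coding and therefore requires allele sizes
  below 1000 bp.
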