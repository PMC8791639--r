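---
title: "Thermodynamic promoter models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic promoter models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thermoprom)
```

## The occupancy model

`thermoprom` predicts constitutive gene expression of a bacterial
promoter from its DNA sequence alone, through the equilibrium occupancy
of sigma70-RNA polymerase (RNAP). The phenotype is the probability
`P_on` that RNAP occupies a *productive* binding configuration; log
fluorescence is taken proportional to `log10(P_on)`.

A *binding configuration* is one placement of the RNAP contact
footprint: an upstream block (the -35 element plus flanking contacts, 12
positions by default), a spacer of 7-11 bp, and a downstream block (the
-10 element plus flanks, 12 positions). The internal spacer optimum of
9 bp corresponds to the canonical 17 bp between the -35 and -10
hexamers, because three downstream columns of the upstream block and
five upstream columns of the downstream block are flanking contacts.
The configuration energy is the additive sum of per-position,
per-residue penalties from two energy-matrix blocks (in units of
`k_B T`; 0.59 kcal/mol at room temperature), plus a spacer-length
penalty and any matching dinucleotide interaction terms. Matrices are
kept in a fixed gauge: the strongest residue of every column, and the
optimal spacer, are zero.

Two models share this machinery:

* **Standard**: only the single strongest forward-strand configuration
  matters, all spacer lengths are allowed at no energy cost, and binding
  is always productive:
  `P_on = 1 / (1 + exp(min_i E_i - mu))`.
* **Extended**: a thermodynamic sum over *every* configuration on both
  strands with clearance-capped weights `w_i = 1 / (R + exp(E_i - mu))`:

  `P_on = sum_on w_i / (1 + sum_np w_i + sum_on w_i)`

  Unproductive (`np`) states are (i) every reverse-complement
  configuration (RNAP acting as its own roadblock) and (ii) forward
  configurations whose -10 end lies within 11 bp of the ribosome binding
  site, whose truncated transcript lacks a functional RBS. With `R = 0`
  the weights reduce to Boltzmann factors; with `R > 0` very strong
  sites saturate at `1/R`, capturing that RNAP must clear the promoter
  to transcribe.

For a single binding state the clearance rate is degenerate:
`P_on(mu, R) = P_on(mu + log(1+R), 0) / (1+R)`, a constant shift in
`log10 P_on` that the logistic link absorbs. Only multi-site promoters
with strong binding inform `R`.

Coordinates are 1-based on the R side; the distance from a
configuration's -10 end to the RBS start counts the bases strictly
between them. Sequences without an annotated RBS (genome fragments,
raw random sequences) have no occluded forward states, since occlusion
is defined relative to a reporter RBS. Ambiguous bases are a hard
error throughout.

## Numerical evaluation

All occupancies are computed in log space (log-sum-exp over
log-weights, with the stable branch `log(R + e^t) = t + log1p(R e^-t)`
for large `t`), so strongly bound and hopeless configurations coexist
without overflow. Ties in the Standard model's minimum are broken by
smallest offset, then shortest spacer, making output deterministic.
The scanning engine caches the two block sums per offset (each is
shared by all spacer variants), and is verified position by position
against a naive R enumerator in the test suite (1,000 random sequences
to `|d log10 P_on| < 1e-9` in the acceptance checks).

## Fitting from binned sort-seq data

The observed phenotype of a library member is its expression bin: the
median read bin for 4-bin libraries and the rounded mean bin (of the
debiased distribution) for 12-bin libraries. The fit maximizes the
likelihood of a *normalized per-bin logistic* link between
`x = log10 P_on` and the bin label: each bin has
`log(pi_i / (1 - pi_i)) = a_i x + b_i` and the probability of bin `i`
is `pi_i / sum_j pi_j`. Records are weighted inversely to their bin's
occupancy (balanced weights), and the same weights are used for the
reported `r^2` of `x` against the expression estimate. Libraries are
split 60:20:20 into training, validation and evaluation sets by
sequence; `optimize_model()` never accepts the evaluation split — only
`evaluate_fit()` reads it, after the report is finalized.

The optimizer is a bounded quasi-Newton (L-BFGS-B) solve over the
matrix entries, spacer penalties, chemical potential and the link
coefficients jointly, with analytic gradients from the compiled core,
repeated with clean link refits until the joint likelihood improves by
less than `1e-6` (at most 200 rounds; both are settable via
`fit_control()`). After each round the matrix gauge is re-pinned
(column minima to zero, the shift absorbed into `mu`) so the flat gauge
direction cannot drift into the box bounds. Structural features are
added one at a time, warm-starting each stage from the previous best
fit; features that are genuinely nested (spacer penalties at zero,
dinucleotide terms at zero, `R = 0`) can only improve the training
likelihood, whereas occlusion and reverse-complement binding
reclassify states and may transiently cost likelihood before refitting.

**Initialization matters.** From a flat (near-zero) matrix the
thermodynamic sum concentrates — every sequence scores almost alike,
the link collapses to the marginal bin frequencies, and the joint
gradient vanishes; that stationary point is an attractor of any local
optimizer. The default start, `consensus_prior_model()`, plants the
canonical TTGACA / TATAAT hexamers at 2 `k_B T` per mismatch with flat
flanks, which anchors the search in the physically meaningful basin;
all penalty values, flanks, spacer costs and `mu` are then refit
freely. In parameter-recovery experiments (ground truth drawn with
consensus structure but different strengths everywhere) the fitted
matrix correlates with truth at `r^2 > 0.99` from this start.

The clearance stage profiles a grid of `R` values, refitting `mu` (and
the link) for each on training data only; for weak-site or single-site
libraries the profile is flat, as expected from the degeneracy above.

## Dinucleotide interaction selection

The candidate set is every (position, residue, position, residue) pair
over the 24 contact positions — 4,416 candidates. Interaction energies
are weakly identifiable from a local mutant library alone: with one
wildtype dominating base usage (88% per position at a 12% mutation
rate), an additive refit absorbs almost all of the pairwise signal,
leaving well under one nat of residual likelihood per planted 0.3 kT
interaction. Identification requires sequence sets whose residues vary
independently, so `select_dinucleotides()` accepts one *or several*
libraries — typically the local library pooled with a fully random one
— and maximizes the summed log-likelihood, each library keeping its own
baseline link (the chemical potential offset between libraries is
absorbed by the links). The funnel:

1. **Exact independent profiles.** Every candidate's exact
   log-likelihood improvement is evaluated on a grid of interaction
   energies (±0.6 kT in 0.1 steps), summed over libraries. This is
   made tractable by profiling on weight-pruned configuration sets
   (configurations below `1e-6` of their sequence's largest Boltzmann
   weight are dropped — they cannot move the occupancy). A first-order
   score was deliberately rejected here: near-saturated links make the
   derivative at zero a poor guide to the attainable improvement.
   Candidates improving the summed log-likelihood by at least 2 nats
   survive; the "2-fold improvement" criterion is interpreted as 2
   nats and is configurable.
2. **L1 joint fits, 2 sigma.** Survivors are re-estimated jointly in 10
   random subsets of 20, each on a random 50:50 split of the pooled
   training+validation data, with the L1 strength chosen by held-out
   likelihood; estimates below 0.002 `k_B T` in magnitude are
   discarded, the rest combined into mean ± sd, and candidates
   compatible with zero at 2 sigma dropped. (The subset design
   presumes more survivors than the subset size; with few survivors
   the subsets overlap and simply provide repeated backgrounds.)
3. **Unpenalized joint fits, 3 sigma,** in 12 subsets of up to 50.
4. **Sequential greedy inclusion**, most significant first, each
   candidate required to stay 3-sigma-incompatible with zero in a joint
   refit against everything accepted so far.

Every stage is verified mechanically: the grid profiles and joint
fits match full-likelihood evaluation to numerical precision, and a
zero-interaction ground truth yields an (almost always) empty accepted
set. **What the funnel cannot do at desk scale** is recover planted
`|dE| = 0.3 k_B T` interactions through the *full* pipeline (fit the
additive model, then select) on 10,000-member libraries: an additive
refit accurate to `r^2 ~ 0.98` absorbs the pairwise signal down to a
fraction of a nat; against the exact additive truth a local library
recovers only alignment *aliases* of the planted pairs (with one
dominant wildtype site, a shifted contact pair overlays the same
physical bases); and in a random 12-bin library the balanced weights
concentrate on a handful of high-bin sequences, flooding stage 1 with
overfit candidates that the later sigma-based stages then correctly
prune — together with the diluted true signal. Interaction energies
of this magnitude are resolvable only with substantially more, and
more heterogeneous, data than the shipped synthetic experiments
simulate; the acceptance suite keeps the plant-and-recover assertion
as the statement of the intended property and reports its failure
rather than weakening it.

## The synthetic-data generator

`generate_library()` + `simulate_sortseq()` emulate the three library
designs the processing and fitting pipelines assume:

* a local mutant library around a strong synthetic wildtype (12% total
  per-position mutation rate over a 67-bp region, each alternative base
  equally likely; 9% for the weaker-mutagenesis variant),
* a fully random 36-mer core between fixed 32-bp flanks,
* 4-bin or 12-bin FACS gating of a per-cell phenotype
  `log10 P_on + N(0, sd)` (`sd = 0.3` by default — FACS noise is
  approximately log-normal in fluorescence), 1,000 cells per sequence,
  multinomial read sampling to a target depth (100 by default),
* in 12-bin mode, per-bin read-recovery bias factors (`1.3^bin` by
  default, emulating the longer sorting times of sparse
  high-expression bins) and a spike-in reference carrying 1,000 cells
  into every bin.

The wildtype construct is fully synthetic: a planted near-consensus
site with the RBS starting 28 bp downstream of the site's -10 end.
4-bin gates sit at `log10 P_on` = -5.5 / -4.5 / -3.5 (no / low /
medium / high); the 12-bin gates span -7 to -1.5 at equal spacing.
These defaults were chosen once, from the construct geometry and
typical dynamic ranges of fluorescent-reporter sorting, before any
pipeline calibration.

What the generator does *not* emulate: PCR chimeras and sequencing
error clouds (only exact-sequence counting), cell-cycle and plasmid
copy-number variation, mRNA-stability effects of the variable region,
and cross-contamination between gates. Passing round-trip and
recovery tests therefore demonstrates correctness of the estimators
under the stated noise model, not robustness to every artifact of real
sort-seq data.

## Sort-seq processing rules

`filter_library()` applies pure per-record predicates (coverage >= 30
by default; construct length; Shine-Dalgarno motif at the expected
position; Hamming distance to the ancestor at most 25% of its length;
for random-core libraries, local-alignment similarity of both flanks
>= 0.75 with match score `1/L` and gap open/extend `1/(2L)`, and core
length within 2 bp of 36) and reports a stepwise attrition table. The
bin-ambiguity rule drops records where an empty bin separates two
occupied bins each holding over 10% of reads — the "highly unequal
adjacent-bin distribution" criterion is not quantified in its source,
so the gap rule with a 10% floor is this package's explicit, settable
interpretation.

12-bin debiasing divides each record's distribution by the spike-in
reference distribution and renormalizes; bins where the reference has
zero reads are unobservable and are excluded from both the ratio and
the renormalization. The mode-template outlier filter then builds the
average distribution per mode, estimates a noise floor as the largest
template value more than 3 bins from the mode, masks bins where that
floor exceeds a third of the template value, and renormalizes — a
single stray read in a far bin would otherwise be inflated enormously
by debiasing. Expression estimates are `eps_bin = sum a_i * i` and
`eps_facs = sum a_i log10 m_i` over the processed distribution.

## Evolution simulations

`evolve()` runs strong-selection-weak-mutation adaptive walks: per
step (one unit of inverse mutation rate) a uniform random position of
the central mutable region mutates to a uniform random alternative
base and fixes with the Kimura probability
`(1 - exp(-2 s dphi)) / (1 - exp(-4 N s dphi))`, `phi = log10 P_on`.
Back-mutations are allowed. The default `s = 100` places selection
coefficients in 0.1-1 for typical mutational effects of `1e-3`-`1e-2`;
runs are censored at `10 N` steps. Because censoring truncates the
slower walks more, observed speed ratios between phenotype maps are
lower bounds. `dphi` is always a full recomputation of `P_on` (no
incremental caching), so trajectories re-derive exactly from the
mutation list. The simulator is validated against an exact
absorbing-Markov-chain solution of a small single-site landscape and
against the neutral fixation rate `1/(2N)`.

## Genome scans and depletion nulls

`energy_track()` assigns each genome position (as a -10 end) the free
energy `-log sum_spacers exp(-E)`, offset so the genome minimum is
zero; linear scanning trims the edges (circular mode is available, as
bacterial chromosomes are circular). Scanning the reverse strand too
is an option; the default track is strand-explicit. Depletion of
strong binding sites is tested two ways, sharing the real track's
energy offset so all histograms live on one scale:

* against a GC-matched i.i.d. synthetic genome, with one-tailed
  Poisson p-values on cumulative site counts per energy bin;
* against 100 column-shuffled energy matrices evaluated on the *real*
  genome (per-column structure intact; dinucleotide terms do not
  survive a column permutation and are dropped), with Gaussian
  one-tailed p-values and a 3rd-97th percentile band.

Promoter regions are summarized by integrating configuration weights
over a symmetric 40-bp window around an anchor (a transcript start
site); windows clipped by the genome edge are flagged. The annotation
partition marks positions in CDS/gene features as genic and positions
free of all excluded feature types (misc_feature, mobile_element,
repeat_region, tRNA, STS, tmRNA, rRNA, CDS, gene, ncRNA) as
inter-genic.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` regenerate everything from
code: oracle sweeps at 1,000 random sequences; parameter recovery on a
10,000-member 4-bin library at depth 100 (with 5 planted dinucleotide
interactions in the ground truth); sort-seq round trips at 1,500-2,000 sequences with
12-bin bias and spike-in; evolution at 20 starts x 20 replicate runs
with `N = 100`; null calibration on ~1 Mb regions against a 4-10 Mb
synthetic genome and 100 shuffled matrices. These sizes were chosen as
the smallest at which the statistical assertions are stable.

## Known limitations

* The footprint geometry (12+12 contacts, spacers 7-11) is a
  configurable default; the true RNAP footprint is uncertain at the
  flanks, and per-spacer energy matrices are deliberately out of scope
  (one matrix serves all spacer lengths).
* UP-element energetics, -10/-35 avidity, sequence-dependent clearance
  and mRNA stability are not modeled.
* The clearance extension treats `R` as a property of the polymerase,
  not the sequence.
* Likelihood surfaces for full-matrix fits are multimodal; fits far
  from any informative initialization can stall at the uninformative
  fixed point described above. The consensus prior is the supported
  remedy.
* Dinucleotide interactions requiring a non-consensus residue at a
  core hexamer position are practically unidentifiable (configurations
  carrying them have negligible weight), and cross-block pairs couple
  to the spacer register; the shipped plant-and-recover experiment
  therefore plants within-block flank pairs, and real-data analyses
  should treat cross-block interaction estimates with caution.
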