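---
title: "Mutational signature analysis with sigtool: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational signature analysis with sigtool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigtool)
```

This vignette is the package's account of its science: the models it
fits, the conventions it freezes, the tunable parameters that matter,
what the synthetic-data generator does and does not emulate, and the
design choices made where more than one defensible option existed.

## 1. Mutation classification

### Substitutions

Every single-base substitution is represented by the pyrimidine member
of the mutated base pair: a `G>A` change is recorded as `C>T` on the
opposite strand, with its context reverse-complemented. This collapses
the 192 strand-specific trinucleotide changes onto 96 classes
(`A[C>A]A` … `T[T>G]T`). Class order is frozen: substitution type major
(`C>A, C>G, C>T, T>A, T>C, T>G`), then 5′ base, then 3′ base, each
ordered `A < C < G < T`. The pentanucleotide scheme (SBS1536) adds one
more base on each side; dropping the outer bases projects it exactly
16-to-1 onto SBS96.

The stranded scheme (SBS192) is defined only inside annotated
transcripts: a substitution is `Transcribed` when the pyrimidine of the
mutated pair lies on the template (transcribed) strand of the covering
gene, `Untranscribed` when it lies on the coding strand. Positions
covered by genes on both strands, or by none, carry no strand
information and are dropped (logged, not silently). This convention — a
choice the class labels themselves cannot express — is fixed here and
used consistently by `classify_sbs_stranded()` and `build_catalogue()`.

### Doublets

A doublet substitution replaces two adjacent bases, both changing. Each
doublet and its reverse complement are the same biological event, so
classes are reverse-complement equivalence pairs. The canonical member
is chosen by rule: the pair member whose reference dinucleotide is
lexicographically smaller; for palindromic references (`AT`, `TA`,
`CG`, `GC`), the lexicographically smaller alternate. Exhaustive
enumeration of all 144 raw doublets yields exactly 78 canonical classes,
and the test suite verifies the collapse is idempotent.

### Indels

The 83 indel classes follow a binning grid over event length, repeat
context and microhomology:

* 1-bp deletions and insertions, split by the pyrimidine of the affected
  base (`C`/`T`, with `A`/`G` collapsed): deletions binned by the total
  homopolymer run length in the reference *including* the deleted base
  (1…6+); insertions by the longer flanking run of the inserted base
  (0…5+). 2 × 6 + 2 × 6 = 24 classes.
* Longer events (length bins 2, 3, 4, 5+) binned by the number of
  tandem copies of the event motif in the reference — including the
  deleted copy for deletions (1…6+), excluding the inserted one for
  insertions (0…5+). 24 + 24 classes.
* Deletions at repeat count 1 whose motif shares ≥ 1 bp with the
  flanking sequence are microhomology classes, binned by microhomology
  length: 1 bin at length 2, 2 at length 3, 3 at length 4, 5 at length
  5+; 11 classes. Microhomology is the longer of the shared prefix with
  the following sequence and the shared suffix with the preceding
  sequence (ties resolved by taking the maximum).

12 + 12 + 24 + 24 + 11 = 83. Indels are left-normalized (shifted to
their leftmost equivalent position) before any counting; for insertions
the flanking-run question (count one side or both) is resolved as the
maximum of the two adjacent runs, a documented choice.

Records whose alleles contain `N`, complex multi-nucleotide variants
(≥ 3 bases substituted — observed in real tumours but with no class
scheme here), events too close to a contig edge, and records of the
wrong kind for the requested schema are excluded with a logged reason,
so per sample the catalogue column sum plus the skip count always equals
the input count. A call whose reference allele contradicts the supplied
genome is an error, not a skip: that is a data-integrity problem.

## 2. De novo extraction: bootstrapped KL-NMF with consensus clustering

`nmf_kl()` minimizes the generalized Kullback–Leibler divergence

$$D(V \,\|\, WH) = \sum_{ij} \Big( V_{ij}\log\frac{V_{ij}}{(WH)_{ij}} - V_{ij} + (WH)_{ij} \Big)$$

by multiplicative updates, which keep factors nonnegative and never
increase the objective (asserted, to numerical epsilon, on every tested
instance). This is the natural likelihood for count data: maximizing a
Poisson likelihood with mean `WH` is exactly minimizing this divergence.
A floor of 1e-16 inside divisions avoids 0/0; convergence is declared
when the relative objective change over 10 iterations falls below `tol`
(default 1e-8, capped at `max_iter = 10000`). The inner loop is compiled
(RcppArmadillo), as is usual for NMF codes.

A single NMF run is a local optimum of a non-convex problem, and the
counts themselves are noisy. `extract_signatures()` therefore factorizes
`n_iterations` (default 1,024) bootstrap resamples of the catalogue —
each sample column redrawn multinomially with its own total and
empirical class proportions, preserving per-sample burdens exactly (the
resampling distribution is configurable; Poisson per cell is the
alternative) — and pools the resulting signature vectors. The pooled
vectors are clustered into `k` consensus signatures under cosine
distance, with the constraint that each iteration contributes exactly
one signature per cluster, enforced by optimal (Hungarian) matching of
each iteration's signatures to the current centroids; this prevents
cluster collapse when two true signatures are similar. Stability is the
mean silhouette of the clustered vectors (for `k = 1`, the mean cosine
to the centroid). Consensus exposures re-attribute the *original*
catalogue by nonnegative least squares.

Rank selection is advisory by design: in practice the number of
signatures is determined by human assessment of the stability/accuracy
trade-off, so the package reports the full per-rank table (`glance()`) and flags the largest rank with
stability ≥ `stability_min` (default 0.8) whose relative KL improvement
over the previous rank is ≥ `gain_min` (default 2%). These two defaults
encode the usual reading of the stability/accuracy plot; they are
parameters, not truths.

`hierarchical_extract()` addresses signatures that generate few
mutations or occur in few samples: after a level of extraction, samples
whose reconstruction cosine falls below `recon_threshold` (default
0.95) form the next level's input, and newly found signatures are
appended when novel (maximum cosine to the existing set below
`novelty_max`, default 0.9). Levels stop when no sample fails or
`max_levels` is reached.

Reproducibility: one master seed; per-iteration seeds are derived
deterministically by counter, and all random number generation happens
in R (the compiled code receives initial matrices), so identical seeds
give bitwise-identical consensus signatures.

## 3. Bayesian extraction: automatic relevance determination

`ard_nmf()` places per-component priors on the columns of `W` and rows
of `H` — exponential (L1) by default, half-normal (L2) as an option — with a
shared scale `λ_k` per component and an inverse-gamma(a, b) hyperprior
(the ARD-NMF model family; the exact prior variant differs between
implementations, so both are exposed).
The `λ_k` updates are closed-form; components that the data do not need
see their scale, and hence their mass, collapse. After convergence,
components whose relevance (share of reconstructed mass) falls below
1e-2 of the maximum are pruned; the surviving count is the inferred
number of signatures. Because the search is stochastic, `n_restarts`
runs (default 10) are performed and
the solution with the highest posterior is kept.

Hyperparameter defaults: `a = 10`; `b` is data-scaled
(`sqrt((a-1)(a-2) mean(V) / K)` for the exponential prior), following
the standard heuristic for this model family. Both are exposed.

### The two-step hypermutator strategy

Hypermutated tumours (mismatch-repair deficient, POLE-mutant,
UV-exposed, temozolomide-treated) contribute so many mutations that a
joint factorization lets them distort every signature. Step 1 therefore
extracts from low-burden samples only; step 2 re-runs the ARD updates on
the hypermutated catalogue with the step-1 columns held fixed and
`k_extra` free columns. Which samples count as hypermutated is a
biological decision the caller supplies; `split_by_burden()` is a
clearly-labelled quantile heuristic for exploration only.

One behaviour discovered during development is worth documenting: at
extreme burdens (10^5+ mutations), the Poisson likelihood is so sharp
that a free column can profitably re-learn an already-fixed profile —
the tiny finite-sample error in a fixed signature outweighs the
relevance penalty. A surviving free column is therefore labelled
hyper-only only when it is *novel* (maximum cosine to every step-1
signature below `novelty_max = 0.9`); duplicates have their activity
folded back into the matching fixed signature, and near-duplicate novel
columns are merged greedily in order of decreasing activity. Hyper-only
signatures are never offered when attributing low-burden samples.

## 4. Attribution

Given fixed signatures, per-sample exposures solve the convex problem
`min ||v - W a||₂` subject to `a ≥ 0`, via active-set nonnegative least
squares; the optimum is solver-independent, so the choice of solver is
an implementation detail (tested against an exhaustive support-
enumeration oracle). Exposures are reported on the mutation-count scale
and, by default, unscaled — the fitted total may differ slightly from
the observed total; `renormalize = TRUE` rescales to the observed count.

Sparsification is backward elimination: starting from the dense
solution, repeatedly drop the active signature whose removal costs the
least reconstruction cosine, while the total drop stays within
`drop_tol` (default 0.01), refitting after each removal. This encodes
the parsimony intent of attribution rule sets without hard-coding any
biology. Biological allow-lists — e.g. restricting a smoking-associated
signature to lung and head-and-neck tumours — are supplied as
configuration (`allow_mask_from_rules()`, YAML or list), producing the
binary signature-by-sample matrix `Z`; `attribute_ard()` multiplies `H`
by `Z` at every update so disallowed exposures are identically zero.

Per-class signature probabilities follow from the fitted mixture:
`P[i,k] = W[i,k] h[k] / Σ_k' W[i,k'] h[k']`, with rows of zero
reconstructed mass flagged undefined rather than silently zeroed.

## 5. Clustered mutations

Substitutions are clustered when their distance to the nearest other
substitution of the same sample on the same chromosome is strictly
below 1,000 bp; the partition is exhaustive and disjoint, verified
against a quadratic all-pairs oracle. The clustered subset forms its own
catalogue for separate extraction. Doublet records are excluded from the
clustering input (the distance rule concerns independent substitutions).
`expected_adjacent_pairs(n, L) = C(n,2) · 2(L-1)/L²` is the expected
number of immediately adjacent pairs when `n` positions fall uniformly
on a length-`L` sequence — a null baseline of this package (labelled
heuristic), useful for judging whether doublets exceed random adjacency.

## 6. Comparison and age statistics

Signature sets are compared by cosine similarity; one-to-one matching
between sets maximizes total cosine by the Hungarian algorithm (exact,
verified against exhaustive search), and `set_separation()` summarizes
a set's internal distinguishability as the median of its pairwise
cosines. The shift test between two similarity distributions is a
two-sided Mann–Whitney U by default, with a permutation test on the
median difference as the alternative.

`age_scan()` proceeds per (signature, cancer type)
stratum, outliers — values more than three standard deviations from the
mean, computed in a single pass — are removed from age and exposure
(union of removals; the boundary value itself is kept, a documented
choice where the rule's strictness is unstated); the regression of
exposure on age is iteratively reweighted least squares with Tukey
bisquare weights (tuning constant 4.685) and MAD scale (1.4826 × median
absolute residual), the classic `robustfit` defaults; the slope's F test
uses the M-estimation variance (ψ-based sandwich with the standard
small-sample correction) rather than the naive weighted residual sum —
the naive version is measurably anticonservative (≈ 8.6% type-I error at
n = 200 in our calibration), while the corrected test holds 5% within
Monte-Carlo error. All p-values across strata and signatures form one
Benjamini–Hochberg family: the discoveries being controlled are
(signature, cancer type) associations, so the family is the whole scan. Strata with fewer than 4 usable
samples are skipped and logged.

## 7. The synthetic-data generator

`simulate_catalogue()` emulates the features of real cohorts that
matter for validating this method family:

* per-sample burdens spanning orders of magnitude (log-uniform, default
  10²–10⁴ mutations, matching the spread seen across tumour types);
* heterogeneous signature mixtures (Dirichlet weights);
* an optional hypermutated subpopulation (default multiplier ×100);
* count noise: Poisson per cell (default) or multinomial at fixed
  burden — both are defensible models of a sequenced spectrum, so both
  are offered; "none" rounds the expected spectra.

`scenario_suite()` uses a crossed evaluation design: two distinct
profile sets, each paired with both exposure
models, four scenarios in total, at "desk" scale (150 samples each) so
the full simulate–extract–attribute loop runs in minutes on one CPU;
"full" scale enlarges cohorts proportionally (5,800 samples) for
offline study. The shipped fixture profiles are synthetic — sparse,
peaked, with controlled pairwise cosines (≤ 0.25) — so no external
download is ever required; `read_signatures_csv()` loads real profile
CSVs for users who want faithful realism.

What the generator does *not* emulate, and what passing tests therefore
do not show: real signatures are flatter and more mutually similar than
the synthetic fixtures (COSMIC sets have median pairwise cosines of
0.1–0.24, and hard pairs exceed 0.9); real cohorts mix tumour types
with structured, non-Dirichlet exposure patterns; sequencing artefacts,
copy-number variation and subclonality perturb real spectra. Recovery
at cosine ≥ 0.95 on the desk suite demonstrates correctness of the
machinery, not that every real signature is recoverable — recovery
degrades for similar, low-activity signatures on realistic data, and
the same is expected here.

`simulate_genome_and_vcf()` builds a random contig and places
non-overlapping substitution, doublet and indel events with margins
large enough for every classification context; each event's true class
is computed at generation time (after left normalization), so
`build_catalogue()` on the emitted VCF + FASTA must reproduce the truth
table *exactly* — an end-to-end test of parsing, normalization, context
extraction and classification with no tolerance at all.

## 8. Numerical choices and degenerate inputs

* Divisions and logarithms are floored at 1e-16 (NMF) / 1e-300 (cosine
  guards); the KL objective treats `V = 0` cells as contributing `R`.
* NMF convergence: relative objective change below 1e-8 (checked every
  10 iterations), `max_iter` 10,000. The acceptance-scale simulations
  use 1e-6/2,000 — at planted-scenario separations the consensus is
  insensitive to the tail of the optimization.
* All-zero sample columns are rejected with instructions (a sample with
  no mutations cannot be factorized); all-zero spectra in attribution
  warn and return zero exposures.
* Ties in the Hungarian assignment resolve by index order,
  deterministically.
* Problem sizes in the test and acceptance runs (96 classes, 60–200
  samples, 8–64 bootstrap iterations, 20 seeds) are the package's
  chosen desk scale: large enough that recovery statistics are stable,
  small enough to iterate on quickly.

## 9. Known limitations

* The transcribed-strand convention requires a strand-resolved
  annotation; overlapping antisense transcription simply drops sites.
* The COMPOSITE concatenation applies no per-block weighting — SBS1536
  features dominate the divergence simply by count; any reweighting would be a modelling choice this
  package deliberately does not make.
* Doublet calls adjacent to a third substitution are still classified
  as doublets; no adjacency filter is applied.
* `expected_adjacent_pairs()` assumes uniform placement; real genomes
  have strong regional rate variation, so it is a lower bound on
  adjacency under heterogeneity.
* Aetiology assignment — naming a recovered signature after a known
  process — is out of scope; `match_signatures()` reports nearest
  matches, nothing more.
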