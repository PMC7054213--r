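# sigtool

Mutational signature analysis for somatic variant calls: catalogue
construction, de novo signature extraction, per-sample attribution, and
the statistics around them — with a fully ground-truthed synthetic-data
harness so every step can be validated without any external download.

## The problem

Somatic mutations in a cancer genome are the cumulative imprint of the
mutational processes the cell lineage experienced — UV light, tobacco
carcinogens, defective repair pathways, endogenous deamination, and many
more. Each process leaves a characteristic *mutational signature*: a
probability distribution over mutation classes. Given a cohort of tumour
genomes summarized as a nonnegative count matrix `V` (mutation classes ×
samples), signature analysis factorizes

```
V  ≈  W · H
```

where the columns of `W` are signatures (each sums to 1 over classes)
and `H` holds the *exposures* — the number of mutations each signature
contributed to each sample. `sigtool` is aimed at analysts who have
curated somatic calls (VCF/MAF) and want to go from raw calls to
signatures, exposures and downstream statistics in R.

## What is implemented

* **Classification** — single-base substitutions in trinucleotide
  (SBS96), pentanucleotide (SBS1536) and transcription-strand-resolved
  (SBS192) context; doublet-base substitutions (DBS78, reverse-complement
  canonicalized); small indels (ID83, binned by length, homopolymer/
  repeat context and flanking microhomology). `build_catalogue()` turns a
  mutation table plus reference FASTA into a counts matrix, logging every
  excluded record with a reason; a COMPOSITE 1,697-feature matrix (1,536
  SBS + 78 DBS + 83 ID) is available via `composite_matrix()`.
* **De novo extraction** — `extract_signatures()`: multiplicative-update
  NMF under generalized Kullback–Leibler divergence on bootstrap
  resamples of the catalogue (1,024 iterations by default), consensus
  clustering of the pooled solutions under cosine distance with
  per-iteration optimal matching, silhouette-based stability, and an
  advisory rank selection (the full stability/accuracy table is always
  reported for human review). `hierarchical_extract()` re-runs extraction
  on poorly reconstructed samples to find rare signatures.
* **Bayesian extraction** — `ard_nmf()`: Poisson-likelihood NMF with
  automatic relevance determination, which infers the number of
  signatures by pruning components whose relevance collapses; 10 random
  restarts by default, keeping the highest-posterior solution.
  `two_step_extract()` implements the hypermutator strategy: extract from
  low-burden samples first, then let additional free components explain
  hypermutated samples while the step-1 signatures stay fixed.
* **Attribution** — `attribute_sample()` / `attribute_catalogue()`:
  nonnegative least squares per sample, with optional backward-elimination
  sparsification and biological allow-lists; `attribute_ard()` runs the
  masked ARD updates on `H` with `W` fixed (the `Z` indicator matrix
  zeroes disallowed signature/sample pairs at every update);
  `mutation_probabilities()` gives per-class signature probabilities.
* **Clustered mutations** — `find_clustered()` partitions substitutions
  by the < 1,000 bp intermutation-distance rule (kataegis-style);
  `clustered_catalogue()` feeds the clustered subset back into
  extraction; `expected_adjacent_pairs()` is a null baseline for doublet
  enrichment.
* **Comparison & statistics** — cosine similarity, optimal one-to-one
  signature matching (Hungarian algorithm), set-separation summaries and
  a rank-based shift test; `age_scan()` associates exposures with age of
  diagnosis per cancer type using 3-standard-deviation outlier removal,
  robust (bisquare IRLS) regression with a slope F test, and joint
  Benjamini–Hochberg correction.
* **Synthetic data** — `simulate_catalogue()` draws cohorts from known
  signatures with log-uniform burdens, Dirichlet mixtures, an optional
  hypermutated subpopulation and Poisson/multinomial noise;
  `simulate_genome_and_vcf()` writes a toy genome + VCF whose true class
  tallies are known exactly, so the whole classification stack is tested
  against generator ground truth.

Everything is tibble-friendly: results have `tidy()`/`glance()` methods
and `autoplot()` visualizations, and a thin command-line wrapper lives at
`inst/cli/sigtool.R`.

## Worked example

```r
library(sigtool)

# a toy genome + VCF with known ground truth, then a catalogue
sim <- simulate_genome_and_vcf(30000, n_sbs = 150, n_dbs = 10, n_indels = 20,
                               seed = 7, fasta_path = "scratch/genome.fa",
                               vcf_path = "scratch/calls.vcf")
muts <- read_vcf_mutations("scratch/calls.vcf")
ct <- build_catalogue(muts, read_reference_fasta("scratch/genome.fa"), "SBS96")
ct
#> <mutation_catalogue> schema SBS96 - 96 classes x 1 samples; 150 mutations, 30 skipped
```

The 30 skipped records are the doublets and indels, which do not belong
in an SBS96 catalogue; the skip log (`ct$skipped`) names each with its
reason.

```r
# a synthetic 120-sample cohort from 3 known signatures, then extraction
sigs <- synthetic_signatures("SBS96", k = 3, seed = 42, max_pairwise = 0.25)
cohort <- simulate_catalogue(
  simulation_scenario(sigs, n_samples = 120, burden_range = c(1e3, 1e4),
                      noise = "poisson", seed = 42))
ex <- extract_signatures(cohort$catalogue, k_range = 2:4, n_iterations = 32,
                         seed = 42, tol = 1e-6, max_iter = 2000)
glance(ex)
#> # A tibble: 3 × 6
#>       k stability kl_error frob_error relative_gain selected
#>   <int>     <dbl>    <dbl>      <dbl>         <dbl> <lgl>
#> 1     2     0.664   60017.      5824.     Inf       FALSE
#> 2     3     1.000    5822.       608.       0.903   TRUE
#> 3     4     0.520    5841.       596.      -0.00326 FALSE
```

Rank 3 is the only candidate that is both stable (mean silhouette 1.00)
and still improves the reconstruction (90% relative KL gain); at rank 4
stability collapses and the fit stops improving, the classic
overfactorization pattern. The recovered signatures match the planted
ones essentially exactly:

```r
match_signatures(solution_at(ex)$signatures, sigs)
#> # A tibble: 3 × 3
#>   signature_a signature_b cosine
#> 1 Sig1        SynSig3      1.000
#> 2 Sig2        SynSig2      1.000
#> 3 Sig3        SynSig1      1.000

glance(attribute_catalogue(cohort$catalogue, solution_at(ex)$signatures))
#> # A tibble: 1 × 5
#>   n_samples median_cosine min_cosine total_mutations total_attributed
#> 1       120         0.999      0.991          500963          500929.
```

A median per-sample reconstruction cosine of 0.999 means the three
extracted signatures explain the cohort's spectra almost perfectly.

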