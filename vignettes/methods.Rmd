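---
title: "Methods: chimera-aware amplicon haplotyping and Q+K association in diploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chimera-aware amplicon haplotyping and Q+K association in diploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the choices
behind them. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## 1. What is being modelled

A candidate-gene association study in a diploid outcrossing plant:
overlapping PCR amplicons (~290–650 bp) tile a handful of gene regions
("contigs"), each individual's amplicons carry an 8-bp tag inside a
self-annealing hairpin adapter (`tag + GCCCGGGC + revcomp(tag)`), and the
pooled library is sequenced to roughly 100× per amplicon with ~453 bp
reads. Re-amplification makes PCR template switching common, so a diploid
individual shows more than two SNP combinations per amplicon; the extra
combinations are chimeras. Downstream, the cohort is structured
(subspecies and subgroups), so marker–trait tests must condition on both a
structure matrix Q and a kinship matrix K.

## 2. The synthetic-data generator

The generator exists so that every pipeline stage can be tested against
known truth. Its components and defaults:

* **Haplotypes.** Standard Kingman n-coalescent per contig, exponential
  coalescence times, no recombination within a contig (so phase across
  amplicon overlaps has a well-defined truth), infinite-sites mutations
  placed on branches at rate θL/2 per lineage per unit time and assigned
  to distinct uniform sites. Ancestral bases i.i.d. uniform over
  {A,C,G,T}; each mutation substitutes a uniformly chosen different base.
  Consequences used by the tests: E[S] = θLa₁ and E[π] = θ.
* **θ per site = 0.0142** — the cross-contig average Watterson estimate of
  the study system this package models; with it, simulated contigs carry
  realistic SNP densities (~1 per 70 bp).
* **Reads.** Per amplicon and individual, Poisson(coverage) reads; each
  read is one of the two haplotypes or, with probability `chimera_rate`, a
  single-crossover chimera of both at a uniform internal breakpoint
  (template switching happens within one individual's PCR, so parents are
  never mixed across individuals). Reads are truncated to
  Normal(453, 30) bp from a uniformly chosen end, then per-base
  substitution errors (default 0.005), then single-base indels per
  homopolymer run of length ≥ 3 (default 0.01 per run), then the 24-bp tag
  adapter. The error and chimera defaults are placeholders for sensitivity
  sweeps — the sequencing platform's true rates are not identifiable from
  the published tables — but they are of the right order for pyrosequencing
  chemistry.
* **Amplicon layout.** Default desk-scale layout: contigs of 700 bp tiled
  by two 450 bp amplicons overlapping by 200 bp (the midpoint of the
  published 77–327 bp range). `study_contigs()` rebuilds the full
  seven-contig / sixteen-amplicon candidate-gene panel from the packaged
  summary table.
* **SSR genotypes.** Global allele frequencies per locus from a flat
  Dirichlet; subpopulation frequencies from a Dirichlet centred on them
  with concentration (1−F)/F, which makes the expected Weir–Cockerham
  differentiation ≈ F (checked against an independent Weir–Cockerham
  oracle in the tests). Individuals draw two allele copies independently;
  admixed rows of Q_true mix source populations per copy.
* **Phenotype.** y = Q·v + g + β·dosage + e with
  g ~ MVN(0, σ²g·2K) and e i.i.d. N(0, σ²ₙ); σ²g is set from the polygenic
  heritability h² as σ²g = h²σ²ₙ / ((1−h²)·mean diag 2K). The truncated
  kinship matrix need not be positive semidefinite, so the polygenic draw
  uses an eigendecomposition with negative eigenvalues clipped at zero
  rather than a Cholesky factor.

**What the generator does not emulate:** recombination within contigs,
selection and demography, base-quality-aware error profiles, tetraploid
genotypes, genotyping (allele-calling) error in SSRs, and
linkage between SSR loci (simulated loci are unlinked, which is exactly
what the LD null-calibration tests require). Passing tests therefore
demonstrate correctness of the estimators and the resolution logic under
the stated model, not robustness to every artefact of real libraries.

## 3. Read processing and haplotype resolution

* **Demultiplexing.** A read is assigned to the unique tag whose leading
  8-mer matches within `max_mismatch` (default 0); ties and non-matches go
  to the unassigned bin, and the 24 adapter bases are trimmed.
* **Alignment.** Each read is anchored to its amplicon and first tried as
  an ungapped end-anchored placement (reads are end-truncated, so an
  indel-free read sits flush with one amplicon end); placements reaching
  90% identity are accepted. Remaining reads go through a compiled
  fitting alignment (read global, reference interval local; match +1,
  mismatch −1, gap of length ℓ costs 3 + ℓ), whose scores are asserted in
  the tests to agree exactly with `Biostrings::pairwiseAlignment` under
  the same scoring. Reads below 70% identity are discarded with a warning.
* **Variant calling is per individual.** At each pileup column, allele
  frequencies are read frequencies; alleles under 0.05 are eliminated as
  sequencing error (this is the correct scale for the filter: within one
  individual a true heterozygous allele sits near 0.5 while polymerase and
  homopolymer errors sit near the per-base error rate). Columns retaining
  two or more alleles are variants; the consensus takes the IUPAC code of
  the retained bases, `-` where a deletion is the lone retained allele and
  `N` at zero depth. The population-level MAF > 0.05 filter is applied
  separately in `genotype_matrix`, over the sample's 2n alleles.
* **Top-two resolution.** Within an amplicon, reads covering all of the
  amplicon's heterozygous sites are grouped by allele vector; the two most
  frequent vectors are the parents, everything else is chimera or residual
  error. Ties for the second slot break to the lexicographically smallest
  vector (deterministic; the choice is arbitrary but logged by the
  support counts). The tests verify equality with exhaustive enumeration
  on all instances with ≤ 6 heterozygous sites.
* **Chaining.** Amplicon pairs are chained across each overlap by
  maximising agreement at shared heterozygous sites. A junction with no
  shared heterozygous site is *unidentifiable* from amplicon-length reads:
  it is flagged `ambiguous` and joined by support rank. This is the one
  place the pipeline must guess, and the flag is the honest record of it —
  with 200 bp overlaps and θ = 0.0142, roughly 6% of simulated junctions
  are ambiguous, which bounds exact-pair recovery accordingly. Per-amplicon
  phase is exact (zero noise) regardless.
* **Coverage flags.** Contigs with mean depth < 35 are flagged
  `low_coverage` (haplotypes still emitted; 35 reads is where chimera and
  error vectors stop being confusable with parents), `missing` with no
  reads.

## 4. Diversity statistics

Columns containing any gap, N or ambiguity code are excluded from all
statistics ("complete deletion", the default of the classic DnaSP-style
workflow); `nucleotide_diversity` optionally supports pairwise deletion.
Tajima's D uses the 1989 constants; its p-value uses the beta
approximation over [D_min, D_max] by default. That approximation is known
to be mildly conservative in the tails (the acceptance suite measures a
rejection rate slightly under the nominal 0.05 under the neutral null), so
the package also provides the calibrated alternative: `tajima_null_d()`
simulates the null of D conditional on S (coalescent genealogy, S
mutations placed branch-length-proportionally) and `tajima_sim_pvalue()`
gives the equal-tail p-value with add-one correction; its rejection rate
is asserted to sit at 0.05 within Monte-Carlo error. Haplotype diversity
uses Hd = n(1 − Σp²)/(n−1) and Nei's sampling variance for the SD.
Sliding windows default to 100 bp / 25 bp (unstated in the workflow this
mirrors; the default is a round choice at amplicon scale), and windows
with S = 0 are reported as not computable rather than zero.

## 5. Linkage disequilibrium

SSR LD uses the genotypic contingency-table G statistic with a
straight permutation test (default 10,000 permutations, seeded) instead of
a Markov-chain exact test: the two have the same null, and a permutation
test is verifiable against exhaustive enumeration (done in the tests at
n = 6). The p-value uses the add-one estimator, so it can never be zero;
ties in G are counted as "as extreme", which keeps the test valid though
slightly conservative for sparse tables. Only same-chromosome pairs with
map positions are tested (distances in Mb); configured pair exclusions are
honoured and logged. SNP LD is the squared Pearson correlation of 0/1/2
dosages over pairwise-complete individuals (invariant to allele-label
swaps), with distances in bp and a 50 bp-binned decay summary against the
conventional r² = 0.1 threshold.

## 6. Kinship and the mixed model

The Ritland moment estimator is computed exactly as defined, with locus
weights A_l − 1 (the estimator's information weight; the original software
this mirrors does not document its weighting, so the convention is stated
here and covered by ordering-invariance tests). Allele frequencies default
to full-sample estimates. Negative pairwise estimates are truncated to
zero before use in the mixed model, and the model covariance is 2K with
the diagonal floored at 1 — the unified model expects a unit-scale
relationship matrix, and self-kinship of an outbred diploid is 1/2.

The per-marker model y = μ + marker + Qv + u + e, u ~ N(0, σ²g·2K),
e ~ N(0, σ²ₑI) is fitted by full REML per marker via one spectral
decomposition of 2K and a one-dimensional profiled-likelihood search in
log δ (δ = σ²ₑ/σ²g) over [1e−5, 1e5]; a grid-search oracle in the tests
confirms the optimum to 0.01 in log δ. Markers are tested by Wald F with
denominator df = n − rank(fixed effects); marker R² is the marker's
whitened sum of squares over the whitened total (intercept-only) sum of
squares. One Q column is always dropped against the intercept (the first;
recorded in the design). With 2K = 0 the whole machinery collapses
algebraically to ordinary least squares, asserted to 1e−8 against
`anova(lm(...))`. Default marker encoding is genotype-class (captures
heterozygote effects); additive dosage is available, and SSR markers can
pool rare classes into "other". Classes under `min_class_size = 3` are
otherwise dropped. FDR families are per-trait by default, global
optionally — the right family is study-specific and both are supported
deliberately.

## 7. Multiplicity

Storey q-values with the smoother π₀ estimate: π₀(λ) over
λ = 0.05…0.90, cubic smoothing spline with 3 df evaluated at λ = 0.90,
clamped to [0, 1]. For families under 100 p-values the spline is unstable
and π₀ falls back to 1, making the q-values exactly Benjamini–Hochberg
(asserted against `p.adjust(..., "BH")` to 1e−12). Empirical FDR control
at q < 0.05 is checked over 200 simulated replicates with 10% true
effects.

## 8. Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally; all I/O reports 1-based
positions (VCF convention). Zero-depth columns are `N`; S = 0 alignments
raise an explicit "undefined statistic" error rather than returning 0 for
D; single-class markers and constant phenotypes raise errors rather than
NaNs; zero-variance SNPs are skipped in r²; pairs with no shared typed
SSR loci get kinship 0 with a warning. One master seed drives everything;
stages derive sub-streams via `derive_seed(seed, label)` so toggling one
stage never perturbs another.

## 9. Problem sizes

The test and acceptance workloads are sized for a single CPU: 2000
coalescent replicates (n = 20, θL = 10) for estimator recovery; 200
diploids at coverage 100, substitution error 0.005 and chimera rate 0.2
for haplotyper recovery; 500 permutation LD tests and 1000 mixed-model
fits for calibration; 200 replicates of m = 2000 p-values for FDR
control. The default `sim_config()` (24 individuals, 2 contigs × 2
amplicons) is the deliberate desk-scale counterpart of the full 72 × 16
study layout available through `study_contigs()`.

## 10. Known limitations

* Ambiguous junctions (overlap without a shared heterozygous site) are
  joined by support rank; their phase is a coin flip and is flagged, not
  hidden. Longer overlaps or higher diversity reduce their frequency.
* The beta-approximation p-value for D is mildly conservative; use the
  simulation null when calibration matters.
* Indels participate in consensus and the variant table but not in
  haplotype allele vectors (association and LD use SNPs only).
* Nonsynonymous/synonymous partitioning is out of scope — reading frames
  are not part of the inputs.
* The aligner assumes reads are end-truncated amplicon copies; it is not
  a general-purpose long-read aligner.
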