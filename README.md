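# amplipop

Amplicon haplotype calling and population-genetic association analysis for
diploid outcrossing plants.

## The problem

Candidate-gene association mapping in an outcrossing diploid (here modelled
on wild diploid alfalfa, *Medicago sativa* subsp. *caerulea*, *falcata* and
their hybrid *hemicycla*) starts from tagged amplicon resequencing of a few
genes across a structured cohort and ends at marker–trait tests that must
not be fooled by population structure or kinship. Between those ends sit
several steps that each have sharp statistical contracts:

1. **Read processing** — demultiplex 8-bp hairpin tags
   (`tag + GCCCGGGC + revcomp(tag)`), align reads to their amplicon's
   reference interval, and call SNPs/indels per individual with the classic
   "<0.05 read frequency" filter that removes 454-style homopolymer noise.
2. **Diploid haplotype resolution** — re-amplified PCR pools are full of
   chimeras, so each individual shows more than two SNP combinations per
   amplicon. The two *most frequent* allele vectors are taken as the true
   haplotypes and chained across overlapping amplicons via shared
   heterozygous sites; junctions with no shared heterozygous site are
   flagged `ambiguous`, not guessed.
3. **Diversity** — per-site heterozygosity π, Watterson's
   θ̂<sub>W</sub> = S/(a₁·L), Tajima's
   D = (k − S/a₁)/√(e₁S + e₂S(S−1)) with both the beta-approximation
   p-value and a coalescent simulation null conditioned on S, haplotype
   diversity Hd = n(1 − Σp²)/(n − 1) with Nei's sampling SD.
4. **Linkage disequilibrium** — genotypic log-likelihood-ratio (G)
   permutation tests between multi-allelic SSR pairs on the same
   chromosome, and r² (squared dosage correlation) between unphased SNP
   pairs within genes, with 50-bp-binned decay against the r² = 0.1
   convention.
5. **Kinship** — Ritland's moment estimator
   F<sub>ij,l</sub> = [Σ<sub>a</sub> x<sub>ia</sub>x<sub>ja</sub>/p<sub>a</sub> − 1]/(A<sub>l</sub> − 1),
   weighted across loci by A<sub>l</sub> − 1, with negative estimates
   truncated to zero.
6. **Association** — the unified mixed linear model
   y = μ + marker + Qv + u + e with u ~ N(0, 2K·σ²g), fitted per marker by
   spectral-decomposition REML, Wald-F marker tests, marker R² on the
   GLS-whitened scale, and QQ-plot data.
7. **Multiplicity** — Storey positive-FDR q-values with the smoother
   π₀ estimate (falling back to π₀ = 1, i.e. Benjamini–Hochberg, for small
   families).

Because the original reads, field phenotypes and genotype tables are not
shippable, the package carries a first-class synthetic-data generator
(neutral Kingman coalescent haplotypes, tagged reads with substitution /
homopolymer-indel / PCR-chimera channels, Balding–Nichols-style structured
SSR genotypes, and phenotypes with structure + polygenic + QTN components)
so every stage is testable end to end with known truth.

## Worked example

```r
library(amplipop)

cfg <- sim_config(n_individuals = 24, contigs = study_contigs(),
                  n_populations = 5, n_ssr_loci = 40, seed = 20260925)
st   <- simulate_study(cfg)
dm   <- demultiplex(st$reads, st$tags)
haps <- call_haplotypes(dm$assigned, st$references, st$design)
gm   <- genotype_matrix(haps, st$references)
ncol(gm$genotypes)
#> [1] 191
```

24 simulated diploids over the seven-contig, sixteen-amplicon
candidate-gene layout yield 191 SNPs with sample MAF > 0.05. Diversity over
the recovered haplotypes:

```r
# per-contig summaries, then the cross-contig averages
#> average pi = 0.0115, average theta = 0.0132 across 7 contigs
```

and the Q+K association scan (stage 5 of `analysis/`) reports for its top
marker the F statistic, p, Storey q, and marker R², plus the per-genotype
class means and subpopulation shares behind the effect.

The same chain is available as numbered drivers:

```sh
Rscript analysis/01_simulate.R     # inputs under results/pipeline/
Rscript analysis/02_haplotype.R    # haplotypes + SNP matrix + recovery
Rscript analysis/03_diversity.R    # pi, theta, Tajima's D, Hd per contig
Rscript analysis/04_linkage.R      # SSR permutation LD + SNP r^2 decay
Rscript analysis/05_association.R  # kinship + MLM scan + q-values
```

or as one call: `run_pipeline(cfg, "results/pipeline")`, which writes a
manifest of content hashes so a rerun with the same seed is byte-identical.

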