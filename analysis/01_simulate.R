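#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Builds a diploid amplicon-resequencing cohort over the published
# seven-contig / sixteen-amplicon candidate-gene layout: coalescent
# haplotypes per contig, tagged 454-style reads with substitution errors,
# homopolymer indels and PCR chimeras, SSR genotypes in five structured
# subpopulations, and a phenotype with structure + polygenic + QTN
# components. All downstream stages read from results/pipeline/.

library(amplipop)

cfg <- sim_config(n_individuals = 24, contigs = study_contigs(),
                  n_populations = 5, n_ssr_loci = 40, seed = 20260925)
print(cfg)

outdir <- "results/pipeline"
manifest <- run_pipeline(cfg, outdir, stages = "simulate")
cat("wrote", nrow(manifest), "input files to", outdir, "\n")

# stash the truth set for the recovery report in stage 2 (text only)
truth_dir <- file.path(outdir, "truth")
dir.create(truth_dir, showWarnings = FALSE)
st <- simulate_study(cfg)   # same seed: byte-identical regeneration
for (ct in names(st$truth$haplotypes)) {
  seqs <- unlist(st$truth$haplotypes[[ct]])
  names(seqs) <- paste(rep(names(st$truth$haplotypes[[ct]]), each = 2),
                       ct, c("hap1", "hap2"), sep = "|")
  write_fasta(seqs, file.path(truth_dir, paste0(ct, "_truth.fasta")))
}
cat("truth haplotypes written for", length(st$truth$haplotypes), "contigs\n")
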