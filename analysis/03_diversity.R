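#!/usr/bin/env Rscript
# Stage 3: sequence diversity per contig.
#
# Computes pi, Watterson's theta, Tajima's D (beta-approximation p-value),
# haplotype number and haplotype diversity +/- SD from the recovered
# haplotypes of stage 2, overall and within the most diverse contig a
# 100 bp / 25 bp sliding-window Tajima's D profile.

library(amplipop)

outdir <- "results/pipeline"
haps <- read_fasta(file.path(outdir, "haplotypes.fasta"))
meta <- do.call(rbind, strsplit(names(haps), "|", fixed = TRUE))
contig_of <- meta[, 2]

tabs <- list()
for (ct in unique(contig_of)) {
  seqs <- haps[contig_of == ct]
  # restore contig coordinates: stage 2 writes gap-stripped sequences, so
  # recompute on equal-length sets only
  if (length(unique(nchar(seqs))) != 1) {
    keep <- nchar(seqs) == as.numeric(names(which.max(table(nchar(seqs)))))
    seqs <- seqs[keep]
  }
  ds <- diversity_summary(seqs)
  ds$contig <- ct
  tabs[[ct]] <- ds
}
div <- do.call(rbind, tabs)
rownames(div) <- NULL
write_tsv2(div, file.path(outdir, "diversity.tsv"))
print(div[, c("contig", "n_sequences", "S", "pi", "theta_w", "tajima_d",
              "n_haplotypes", "hap_diversity")], digits = 3)
cat(sprintf("average pi = %.4f, average theta = %.4f across %d contigs\n",
            mean(div$pi), mean(div$theta_w), nrow(div)))

top <- div$contig[which.max(div$pi)]
sw <- sliding_tajima(haps[contig_of == top], window_bp = 100, step_bp = 25)
write_tsv2(sw, file.path(outdir, paste0("sliding_tajima_", top, ".tsv")))
cat("sliding-window D written for", top, "->",
    sum(!is.na(sw$D)), "computable windows\n")
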