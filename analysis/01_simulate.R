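#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study that the downstream stages analyse.
# Writes a toy genome with planted miRNA hairpins and decoy loci, three
# genotype small-RNA libraries, a transcriptome with planted cleavage sites,
# per-genotype degradome tables, reference FASTAs and the ground truth.

library(mirseek)

seed <- 42L
out <- "results/sim"

study <- simulate_study(out, seed = seed)

cat("Simulated study written to", out, "\n")
cat(sprintf("  genome: %d chromosomes, %s nt total\n",
            length(study$genome),
            format(sum(nchar(study$genome)), big.mark = ",")))
cat(sprintf("  planted miRNA precursors: %d (+ %d decoy loci)\n",
            nrow(study$truth), nrow(study$decoys)))
cat(sprintf("  small-RNA libraries: %s (clean reads: %s)\n",
            paste(study$genotypes, collapse = ", "),
            paste(study$denominators, collapse = ", ")))
cat(sprintf("  transcriptome: %d transcripts, %d with planted target sites\n",
            length(study$transcripts), nrow(study$targets)))
cat(sprintf("  degradome depth: ~%d reads/transcript, signal fraction %.1f\n",
            study$params$degradome_depth, study$params$signal_fraction))
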