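#!/usr/bin/env Rscript
# Stage 3: novel miRNA discovery. Maps tags to the genome, excises and folds
# candidate precursors, demands a sequenced miRNA-star forming a proper
# duplex, and requires mature-arm support in every genotype. Writes the
# novel-miRNA table and a text rendering of each fold-back.

library(mirseek)

sim <- "results/sim"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta(file.path(sim, "genome.fa"))
lib_files <- list.files(sim, "^lib_.*\\.fa$", full.names = TRUE)
libs <- lapply(lib_files, function(f) {
  read_collapsed_fasta(f, sub("^lib_(.*)\\.fa$", "\\1", basename(f)))
})

calls <- discover_novel(libs, genome, min_libraries = 3L, min_count = 5L)
write.table(calls, file.path(out, "novel_mirnas.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Novel miRNA calls:", nrow(calls), "\n")
print(calls[, c("seq_5p", "seq_3p", "dominant_arm", "chrom", "strand")])

hp_lines <- unlist(lapply(attr(calls, "hairpins"), function(h) {
  c(sprintf("> %s:%d-%d(%s) mature arm %s", h$locus$chrom, h$locus$start,
            h$locus$end, h$locus$strand, h$mature_arm),
    render_hairpin(h))
}))
writeLines(hp_lines, file.path(out, "hairpins.txt"))
cat("Fold-back renderings ->", file.path(out, "hairpins.txt"), "\n")

# recovery against the simulated truth
truth <- read_truth(file.path(sim, "truth.json"))$planted_mirnas
planted <- ifelse(truth$mature_arm == "5p", truth$seq_5p, truth$seq_3p)
called <- ifelse(calls$dominant_arm == "5p", calls$seq_5p, calls$seq_3p)
cat(sprintf("Recovered %d / %d planted miRNAs; %d decoy calls\n",
            sum(planted %in% called), length(planted),
            sum(!called %in% c(truth$seq_5p, truth$seq_3p))))
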