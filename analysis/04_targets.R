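#!/usr/bin/env Rscript
# Stage 4: degradome target identification. Scans every miRNA against the
# transcriptome with the wobble-aware mismatch score (max 4), tallies
# degradome 5'-ends at each site's expected cleavage position, and writes
# the per-genotype target report.

library(mirseek)

sim <- "results/sim"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

transcripts <- read_fasta(file.path(sim, "cdna.fa"))
mature <- read_fasta(file.path(sim, "mature.fa"))
mature <- mature[!grepl("\\*$", names(mature))]      # guide strands only
names(mature) <- sub("^msy-", "", names(mature))
deg_files <- list.files(sim, "^degradome_.*\\.tsv$", full.names = TRUE)
degradome <- lapply(deg_files, read_degradome)
names(degradome) <- sub("^degradome_(.*)\\.tsv$", "\\1", basename(deg_files))

sites <- find_sites_all(mature, transcripts, max_score = 4)
cat("Complementary sites (score <= 4):", nrow(sites), "\n")

report <- build_target_report(sites, degradome, min_valid = 5L)
report$percent_printed <- format_percent(report$percent)
write.table(report, file.path(out, "target_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Target report rows:", nrow(report), "-> target_report.tsv\n")
print(head(report, 9))

truth <- read_truth(file.path(sim, "truth.json"))$planted_targets
key <- unique(paste(report$mirna_id, report$target_gene))
truth_key <- paste(truth$mirna_id, truth$transcript_id)
cat(sprintf("Recovered %d / %d planted targets; %d decoy target genes\n",
            sum(truth_key %in% key), length(truth_key),
            sum(!key %in% truth_key)))
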