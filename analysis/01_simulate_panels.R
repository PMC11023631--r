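#!/usr/bin/env Rscript
# Step 1: build the synthetic study inputs.
#
# Two 50-sequence panels of 1 kb integrase-like genes emulate the contrast
# between sedentary chromosomal integron (SCI) integrases, which carry long
# homopolymers, and mobile integron (MI) integrases, whose homopolymers stay
# short (max run <= 5 by construction). A single 960 bp ORF-mode gene
# emulates the intIA layout itself: an 8xA run starting at position 58
# (57 bp after the A of the ATG), plus a 7-mer and a 6-mer, with the
# background capped at 5 so the planted runs are the largest homopolymers.

suppressPackageStartupMessages(library(homorun))
dir.create("results", showWarnings = FALSE)

sci <- generate_group_panel(50, length = 1000, policy = "SCI-like", seed = 20260901)
mi  <- generate_group_panel(50, length = 1000, policy = "MI-like",  seed = 20260902)
panel <- rbind(sci, mi)

write_fasta_panel(panel, "results/integrase_panels.fa")
write.table(panel[, c("id", "group")], "results/integrase_groups.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

gene <- simulate_integrase_gene(seed = 20260903)
write_fasta_panel(data.frame(id = "intIA_synthetic", seq = gene),
                  "results/intIA_synthetic.fa")

max_run <- function(s) max(split_runs(s)$length)
cat(sprintf("SCI-like panel: %d seqs, max run %d; MI-like panel: %d seqs, max run %d\n",
            nrow(sci), max(vapply(sci$seq, max_run, 1)),
            nrow(mi), max(vapply(mi$seq, max_run, 1))))
long <- subset(split_runs(gene), length >= 6)
cat("intIA-like gene long runs (start/base/length):\n")
print(long, row.names = FALSE)
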