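#!/usr/bin/env Rscript
# Stage 3: sustained-upregulation screen on the fibrosis course.
#
# Each treated timepoint is compared to its timepoint-matched control arm;
# a gene is SUSTAINED_UP only if FC >= 2 with Welch p < 0.01 at every
# treated timepoint ("upregulated throughout").

library(scarscreen)

src <- "scratch/analysis"
dir.create("results", showWarnings = FALSE)

em <- read_matrix(file.path(src, "fibrosis_matrix.tsv"),
                  file.path(src, "fibrosis_samples.tsv"))
crit <- screen_criteria()
prof <- compute_fold_changes(em, "matched_control", crit)
res <- classify_sustained_up(prof, crit)
write_results(res, file.path(src, "fibrosis_screen.tsv"), json = TRUE)

gates <- data.frame(gate = names(res$gate_counts),
                    genes = as.integer(res$gate_counts))
write.table(gates, "results/fibrosis_gate_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("gates:", paste(gates$gate, gates$genes, sep = "=", collapse = " -> "),
    "\n")
su <- res$genes[res$genes$class_label == "SUSTAINED_UP", ]
cat(sprintf("%d gene(s) upregulated throughout: %s\n", nrow(su),
            paste(su$gene_id, collapse = ", ")))
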