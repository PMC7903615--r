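#!/usr/bin/env Rscript
# Stage 2: transient-induction screen on the wound-healing course.
#
# Fold changes are computed against the 0 h baseline (geometric mean over
# replicates); a gene passes when FC >= 2 at both 12 h and 24 h with
# Welch p < 0.01, and its 72 h FC is back within +/-20% of baseline.
# Full per-gene table goes to scratch/; the gate counts and the top of the
# ranked transient list go to results/.

library(scarscreen)

src <- "scratch/analysis"
dir.create("results", showWarnings = FALSE)

em <- read_matrix(file.path(src, "wound_matrix.tsv"),
                  file.path(src, "wound_samples.tsv"))
crit <- screen_criteria()   # 2-fold, 12/24 h, +/-20% at 72 h, alpha 0.01
prof <- compute_fold_changes(em, "timepoint0", crit)
res <- classify_transient(prof, crit)
write_results(res, file.path(src, "wound_screen.tsv"), json = TRUE)

gates <- data.frame(gate = names(res$gate_counts),
                    genes = as.integer(res$gate_counts))
write.table(gates, "results/wound_gate_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- head(read_results(file.path(src, "wound_screen.tsv")), 25)
write.table(top, "results/wound_screen_top25.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("gates:", paste(gates$gate, gates$genes, sep = "=", collapse = " -> "),
    "\n")
tr <- res$genes[res$genes$class_label == "TRANSIENT_INDUCED", ]
cat(sprintf("%d transiently induced genes; top hit %s (max FC %.1f)\n",
            nrow(tr), tr$gene_id[1], tr$max_fold_change[1]))
truth <- read_truth(file.path(src, "wound_truth.tsv"))
tp <- truth$gene_id[truth$class_label == "TRANSIENT"]
cat(sprintf("recovery vs truth: sensitivity %.2f, precision %.2f\n",
            length(intersect(tr$gene_id, tp)) / length(tp),
            length(intersect(tr$gene_id, tp)) / nrow(tr)))
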