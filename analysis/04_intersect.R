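#!/usr/bin/env Rscript
# Stage 4: intersect the two screens to nominate candidates.
#
# The candidates are the genes transiently induced in scarless wound
# healing AND persistently upregulated in fibrosis -- the expression
# pattern that motivates follow-up validation.

library(scarscreen)

src <- "scratch/analysis"
dir.create("results", showWarnings = FALSE)

# rebuild ScreenResult-level calls from the stage outputs
wound <- read_results(file.path(src, "wound_screen.tsv"))
fib <- read_results(file.path(src, "fibrosis_screen.tsv"))
tr <- wound[wound$class_label == "TRANSIENT_INDUCED", ]
su <- fib[fib$class_label == "SUSTAINED_UP", ]
hit <- intersect(tr$gene_id, su$gene_id)
fc_cols <- setdiff(grep("^fc_", names(su), value = TRUE), "fc_0h")
min_fib_fc <- apply(su[match(hit, su$gene_id), fc_cols, drop = FALSE], 1, min)
out <- data.frame(gene_id = hit,
                  wound_class = rep("TRANSIENT_INDUCED", length(hit)),
                  fibrosis_class = rep("SUSTAINED_UP", length(hit)),
                  wound_max_fc = tr$max_fold_change[match(hit, tr$gene_id)],
                  fibrosis_min_fc = min_fib_fc)
out <- out[order(-out$wound_max_fc, out$gene_id), , drop = FALSE]
write.table(out, "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d candidate gene(s): %s\n", nrow(out),
            paste(out$gene_id, collapse = ", ")))
cat(sprintf("wound screen: %d transient; fibrosis screen: %d sustained\n",
            nrow(tr), nrow(su)))
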