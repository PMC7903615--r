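#!/usr/bin/env Rscript
# Stage 1: simulate the paired study datasets.
#
# Emulates the two time courses the screen consumes: a single-arm oral-wound
# healing course (0-240 h, n = 3, dense early sampling) and a two-arm
# control-vs-treated skin-fibrosis course (days 0/3/7/10). One gene, aliased
# "Areg", is planted with the candidate pattern: ~10-fold transient induction
# in the wound course, 10-fold sustained upregulation under treatment in the
# fibrosis course. 10% of genes are transient-only and 10% sustained-only
# distractors; the rest are flat. Replicate noise is log-normal with
# SD 0.2 on log2, a typical between-replicate spread for array data.
#
# Matrices are large, so they go to scratch/analysis/ (regenerable from this
# script); downstream stages read them from there.

library(scarscreen)

SEED <- 20260925
out <- "scratch/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

wcfg <- simulation_config(
  n_genes = 500,
  class_proportions = c(TRANSIENT = 0.1, SUSTAINED = 0.1, FLAT = 0.8),
  peak_folds = c(TRANSIENT = 10, SUSTAINED = 10, LATE = 5, REPRESSED = 5),
  timepoints_h = c(0, 6, 12, 24, 72, 120, 168, 240),
  n_replicates = 3, noise_log2_sd = 0.2, seed = SEED)
wsim <- generate_timecourse(wcfg, alias = c(G000001 = "Areg"))
write_matrix(wsim$matrix, file.path(out, "wound_matrix.tsv"),
             file.path(out, "wound_samples.tsv"))
write_truth(wsim$truth, file.path(out, "wound_truth.tsv"))

fcfg <- simulation_config(
  n_genes = 500, timepoints_h = c(0, 72, 168, 240),
  n_replicates = 3, noise_log2_sd = 0.2, seed = SEED + 1)
fsim <- generate_fibrosis_course(fcfg, wsim$truth,
                                 overlap_spec = c(Areg = "SUSTAINED"))
write_matrix(fsim$matrix, file.path(out, "fibrosis_matrix.tsv"),
             file.path(out, "fibrosis_samples.tsv"))
write_truth(fsim$truth, file.path(out, "fibrosis_truth.tsv"))

cat(sprintf("wound course:    %d genes x %d samples (%s)\n",
            nrow(wsim$matrix$values), ncol(wsim$matrix$values),
            paste(wcfg$timepoints_h, collapse = "/")))
cat(sprintf("fibrosis course: %d genes x %d samples (two arms at %s h)\n",
            nrow(fsim$matrix$values), ncol(fsim$matrix$values),
            paste(fcfg$timepoints_h, collapse = "/")))
cat(sprintf("planted: %d transient, %d sustained, 1 Areg-pattern overlap\n",
            sum(wsim$truth$class_label == "TRANSIENT"),
            sum(wsim$truth$class_label == "SUSTAINED")))
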