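two_group_em <- function(base, t24, tps = c(0, 24)) {
  nrep <- length(base)
  tp <- rep(tps, each = nrep)
  ss <- data.frame(sample_id = sprintf("s%d", seq_along(tp)),
                   condition = ifelse(tp == 0, "control", "injured"),
                   timepoint_h = tp, replicate = rep(seq_len(nrep), 2),
                   stringsAsFactors = FALSE)
  v <- matrix(c(base, t24), 1, dimnames = list("g1", ss$sample_id))
  expression_matrix(v, ss)
}

test_that("fold change is 1 when treated equals baseline, 10 for the Areg magnitude", {
  em <- two_group_em(c(100, 120, 90), c(100, 120, 90))
  prof <- compute_fold_changes(em)
  expect_equal(prof$fold_change, c(1, 1), tolerance = 1e-12)
  # tenfold induction: baseline {100,100,100}, 24 h {1000,1000,1000}
  em <- two_group_em(c(100, 100, 100), c(1000, 1000, 1000))
  prof <- compute_fold_changes(em)
  expect_equal(prof$fold_change[prof$timepoint_h == 24], 10,
               tolerance = 1e-12)
})

test_that("screen equals the per-gene scalar brute-force oracle", {
  sim <- generate_timecourse(simulation_config(n_genes = 20,
                                               noise_log2_sd = 0.4,
                                               seed = 7))
  prof <- compute_fold_changes(sim$matrix)
  orc <- oracle_profiles(sim$matrix)
  got <- prof[prof$timepoint_h > 0, ]
  key <- paste(got$gene_id, got$timepoint_h)
  okey <- paste(orc$gene_id, orc$timepoint_h)
  expect_setequal(key, okey)
  m <- match(key, okey)
  expect_equal(got$fold_change, orc$fold_change[m], tolerance = 1e-12)
  expect_equal(got$p_value, orc$p_value[m], tolerance = 1e-9)
})

test_that("transient classification implements the 2-fold / return-band / p-gate criterion", {
  crit <- screen_criteria()
  prof <- make_profiles(list(
    areg   = c(`0` = 1, `12` = 10, `24` = 10, `72` = 1.0),
    onetp  = c(`0` = 1, `12` = 10, `24` = 1.5, `72` = 1.0),
    band_in  = c(`0` = 1, `12` = 3, `24` = 3, `72` = 1.20),
    band_out = c(`0` = 1, `12` = 3, `24` = 3, `72` = 1.21),
    band_lo  = c(`0` = 1, `12` = 3, `24` = 3, `72` = 0.80),
    stillup  = c(`0` = 1, `12` = 5, `24` = 5, `72` = 4),
    flat   = c(`0` = 1, `12` = 1, `24` = 1, `72` = 1)))
  res <- classify_transient(prof, crit)
  lab <- setNames(as.character(res$genes$class_label), res$genes$gene_id)
  expect_equal(lab[["areg"]], "TRANSIENT_INDUCED")
  expect_equal(lab[["onetp"]], "NOT_INDUCED")       # fails the all-timepoints rule
  expect_equal(lab[["band_in"]], "TRANSIENT_INDUCED") # band closed at 1.20
  expect_equal(lab[["band_out"]], "INDUCED_NOT_RETURNED")
  expect_equal(lab[["band_lo"]], "TRANSIENT_INDUCED") # band closed at 0.80
  expect_equal(lab[["stillup"]], "SUSTAINED_INDUCED")
  expect_equal(lab[["flat"]], "NOT_INDUCED")
  # exactly one label per gene
  expect_equal(sort(names(lab)), sort(unique(prof$gene_id)))
  expect_equal(sum(res$gate_counts[["genes_in"]]), nrow(res$genes))

  # significance gate: induced by FC but p above alpha -> NOT_INDUCED
  p_bad <- list(areg = c(`0` = NA, `12` = 0.5, `24` = 1e-6, `72` = 1e-6))
  prof2 <- make_profiles(list(areg = c(`0` = 1, `12` = 10, `24` = 10,
                                       `72` = 1)), p_bad)
  res2 <- classify_transient(prof2, crit)
  expect_equal(as.character(res2$genes$class_label), "NOT_INDUCED")
  # ... unless the gate is off
  res3 <- classify_transient(prof2,
                             screen_criteria(require_significance = FALSE))
  expect_equal(as.character(res3$genes$class_label), "TRANSIENT_INDUCED")
  # missing criteria timepoint errors
  prof4 <- make_profiles(list(g = c(`0` = 1, `12` = 3, `24` = 3)))
  expect_error(classify_transient(prof4, crit), "missing timepoint")
})

test_that("sustained classification requires every treated timepoint to pass", {
  crit <- screen_criteria()
  prof <- make_profiles(list(
    allup  = c(`0` = 1, `72` = 5, `168` = 5, `240` = 5),
    flat   = c(`0` = 1, `72` = 1, `168` = 1, `240` = 1),
    lastdn = c(`0` = 1, `72` = 5, `168` = 5, `240` = 1.1)))
  res <- classify_sustained_up(prof, crit)
  lab <- setNames(as.character(res$genes$class_label), res$genes$gene_id)
  expect_equal(lab[["allup"]], "SUSTAINED_UP")
  expect_equal(lab[["flat"]], "NOT_SUSTAINED")
  expect_equal(lab[["lastdn"]], "NOT_SUSTAINED")  # fails "throughout"
})

test_that("intersection is the set of transient-in-wound, sustained-in-fibrosis genes", {
  wprof <- make_profiles(list(
    A = c(`0` = 1, `12` = 8, `24` = 8, `72` = 1),
    B = c(`0` = 1, `12` = 4, `24` = 4, `72` = 1),
    C = c(`0` = 1, `12` = 3, `24` = 3, `72` = 1),
    D = c(`0` = 1, `12` = 1, `24` = 1, `72` = 1)))
  fprof <- make_profiles(list(
    A = c(`0` = 1, `72` = 5, `168` = 5),
    B = c(`0` = 1, `72` = 1, `168` = 1),
    D = c(`0` = 1, `72` = 5, `168` = 5)))
  wres <- classify_transient(wprof)
  fres <- classify_sustained_up(fprof)
  hits <- intersect_screens(wres, fres)
  expect_equal(hits$gene_id, "A")
  expect_equal(hits$wound_class, "TRANSIENT_INDUCED")
  # disjoint sets -> empty
  fprof2 <- make_profiles(list(D = c(`0` = 1, `72` = 5, `168` = 5)))
  hits2 <- intersect_screens(wres, classify_sustained_up(fprof2))
  expect_equal(nrow(hits2), 0)
})

test_that("thresholds are monotone: tightening never adds transient calls", {
  prof <- random_profiles(50, seed = 17)
  base <- transient_set(classify_transient(prof, screen_criteria()))
  tighter <- list(
    screen_criteria(induction_fold = 3),
    screen_criteria(return_band = 0.1),
    screen_criteria(alpha = 0.001))
  for (crit in tighter) {
    got <- transient_set(classify_transient(prof, crit))
    expect_true(all(got %in% base))
  }
  # and loosening the band never removes calls
  wider <- transient_set(classify_transient(prof,
                                            screen_criteria(return_band = 0.3)))
  expect_true(all(base %in% wider))
})

test_that("labels are invariant under row and column permutation", {
  sim <- generate_timecourse(simulation_config(
    n_genes = 30,
    class_proportions = c(TRANSIENT = 0.2, SUSTAINED = 0.2, FLAT = 0.6),
    noise_log2_sd = 0.2, seed = 19))
  em <- sim$matrix
  res <- classify_transient(compute_fold_changes(em))
  set.seed(1)
  gperm <- sample(nrow(em$values))
  sperm <- sample(ncol(em$values))
  em2 <- expression_matrix(em$values[gperm, sperm],
                           em$samples[sperm, ])
  res2 <- classify_transient(compute_fold_changes(em2))
  lab1 <- setNames(as.character(res$genes$class_label), res$genes$gene_id)
  lab2 <- setNames(as.character(res2$genes$class_label), res2$genes$gene_id)
  expect_identical(lab1, lab2[names(lab1)])
})

test_that("degenerate tests never crash the screen and fail the gate", {
  # single replicate per group: significance unavailable
  em <- two_group_em(100, 1000)
  prof <- compute_fold_changes(em)
  expect_true(all(prof$degenerate[prof$timepoint_h > 0]))
  expect_true(all(is.na(prof$p_value[prof$timepoint_h > 0])))
  # zero variance, unequal means: p = 0 with flag (still significant)
  em <- two_group_em(c(100, 100, 100), c(1000, 1000, 1000))
  prof <- compute_fold_changes(em)
  expect_equal(prof$p_value[prof$timepoint_h == 24], 0)
  expect_true(prof$degenerate[prof$timepoint_h == 24])
})

test_that("non-positive values are floored and flagged, not fatal", {
  em <- two_group_em(c(100, 100, 100), c(0, 1000, 1000))
  prof <- compute_fold_changes(em)
  expect_equal(attr(prof, "n_floored"), 1)
  expect_true(all(is.finite(prof$fold_change)))
  expect_match(paste(attr(prof, "notes"), collapse = " "), "floored")
})

test_that("two-arm fold changes use matched controls with pooled fallback", {
  tp <- rep(c(0, 72, 168), each = 4)
  arm <- rep(rep(c("control", "treated"), each = 2), 3)
  ss <- data.frame(sample_id = sprintf("s%d", seq_along(tp)),
                   condition = arm, timepoint_h = tp,
                   replicate = rep(1:2, 6), stringsAsFactors = FALSE)
  v <- matrix(rep(c(100, 100, 300, 300), 3), 1,
              dimnames = list("g1", ss$sample_id))
  em <- expression_matrix(v, ss)
  prof <- compute_fold_changes(em, "matched_control")
  expect_equal(prof$fold_change, rep(3, 3), tolerance = 1e-12)
  # drop the 168 h control group: falls back to pooled control, noted
  keep <- !(ss$timepoint_h == 168 & ss$condition == "control")
  em2 <- expression_matrix(v[, keep, drop = FALSE], ss[keep, ])
  prof2 <- compute_fold_changes(em2, "matched_control")
  expect_equal(prof2$fold_change[prof2$timepoint_h == 168], 3,
               tolerance = 1e-12)
  expect_match(paste(attr(prof2, "notes"), collapse = " "),
               "pooled control")
})

test_that("Benjamini-Hochberg option only ever weakens per-gene significance", {
  sim <- generate_timecourse(simulation_config(n_genes = 40,
                                               noise_log2_sd = 0.3,
                                               seed = 23))
  raw <- compute_fold_changes(sim$matrix, criteria = screen_criteria())
  adj <- compute_fold_changes(sim$matrix,
                              criteria = screen_criteria(p_adjust = "BH"))
  ok <- !is.na(raw$p_value)
  expect_true(all(adj$p_value[ok] >= raw$p_value[ok] - 1e-12))
})
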