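# Independent scalar oracles used to cross-check the screen. Deliberately
# library-free (no t.test/wilcox.test) and written as per-element loops so
# they share no code path with the implementation.

# Welch's unequal-variance t, two-sided, by the textbook formula.
oracle_welch_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  va <- sum((a - ma)^2) / (na - 1); vb <- sum((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  if (se2 == 0) return(if (ma == mb) 1 else 0)
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  2 * stats::pt(-abs(tt), df)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n+m, n) rank assignments.
oracle_mw_p <- function(a, b) {
  x <- c(a, b); n <- length(a); N <- length(x)
  r <- rank(x)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(N, n)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Geometric-mean fold change by scalar arithmetic.
oracle_fc <- function(treated, baseline) {
  gm <- function(v) {
    s <- 0
    for (vi in v) s <- s + log(vi)
    exp(s / length(v))
  }
  gm(treated) / gm(baseline)
}

# Per-gene, per-timepoint brute-force re-implementation of the screen's
# fold-change/p computation for a single-arm (timepoint-0 baseline) course.
oracle_profiles <- function(em) {
  meta <- em$samples
  tps <- sort(unique(meta$timepoint_h))
  base_cols <- meta$sample_id[meta$timepoint_h == 0]
  out <- list()
  for (g in rownames(em$values)) {
    for (t in tps[tps > 0]) {
      tcols <- meta$sample_id[meta$timepoint_h == t]
      treated <- em$values[g, tcols]
      base <- em$values[g, base_cols]
      out[[length(out) + 1]] <- data.frame(
        gene_id = g, timepoint_h = t,
        fold_change = oracle_fc(treated, base),
        p_value = oracle_welch_p(log2(treated), log2(base)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Hand-built profile table for classifier tests: fc/p given per gene as
# named vectors over timepoints (hours as names).
make_profiles <- function(fc_by_gene, p_by_gene = NULL) {
  rows <- list()
  for (g in names(fc_by_gene)) {
    fc <- fc_by_gene[[g]]
    p <- if (!is.null(p_by_gene)) p_by_gene[[g]] else
      setNames(rep(1e-6, length(fc)), names(fc))
    for (t in names(fc)) {
      th <- as.numeric(t)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g, timepoint_h = th,
        fold_change = unname(fc[t]),
        p_value = if (th == 0) NA_real_ else unname(p[t]),
        n_treated = 3L, n_baseline = 3L, degenerate = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  prof <- do.call(rbind, rows)
  structure(prof, class = c("gene_time_profiles", "data.frame"))
}

# Random profile set over the default timepoint grid, for the threshold
# monotonicity properties.
random_profiles <- function(n_genes, seed) {
  set.seed(seed)
  tps <- c(0, 12, 24, 72)
  fc <- list(); p <- list()
  for (i in seq_len(n_genes)) {
    g <- sprintf("R%03d", i)
    fc[[g]] <- setNames(c(1, 2^rnorm(2, 1.0, 1.2), 2^rnorm(1, 0, 0.5)),
                        tps)
    p[[g]] <- setNames(c(NA, 10^(-runif(3, 0, 4))), tps)
  }
  make_profiles(fc, p)
}

transient_set <- function(result) {
  as.character(result$genes$gene_id[
    result$genes$class_label == "TRANSIENT_INDUCED"])
}
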