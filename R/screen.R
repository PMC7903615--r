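#' Per-gene fold changes and significance versus baseline
#'
#' The screen's primitive: for every gene and timepoint, the linear-scale
#' fold change FC(t) = central abundance at t / central abundance at
#' baseline, with a two-sided p-value comparing the log2 replicate values.
#' Central abundance is the geometric mean of replicates (arithmetic mean
#' in log2), the natural choice under a multiplicative noise model.
#'
#' Baseline selection:
#' * `"timepoint0"` — single-arm course; the 0 h group is the baseline for
#'   every timepoint (FC(0) = 1 by definition, no test at 0 h).
#' * `"matched_control"` — two-arm course; each treated timepoint is
#'   compared to its timepoint-matched control group, falling back to the
#'   pooled control arm for timepoints with no matched control (the
#'   fallback is recorded in the `notes` attribute).
#' * `"pooled_control"` — each treated timepoint versus all control
#'   samples.
#'
#' Values at or below zero are raised to half the smallest positive value
#' in the matrix before the log transform; the number of floored cells is
#' recorded in the `n_floored` attribute. Groups with fewer than 2
#' replicates (or zero variance under Welch's t) never error: the test is
#' marked degenerate, its p-value is `NA`, and the gene fails the
#' significance gate downstream.
#'
#' @param em An [expression_matrix()].
#' @param baseline Baseline selector, see above.
#' @param criteria A [screen_criteria()]; supplies `test_method` and the
#'   optional Benjamini-Hochberg adjustment.
#' @return A data frame of class `gene_time_profiles` with columns
#'   `gene_id`, `timepoint_h`, `fold_change`, `p_value`, `n_treated`,
#'   `n_baseline`, `degenerate`.
#' @export
#' @examples
#' sim <- generate_timecourse(simulation_config(n_genes = 10, seed = 1))
#' prof <- compute_fold_changes(sim$matrix)
#' head(prof)
compute_fold_changes <- function(em,
                                 baseline = c("timepoint0", "matched_control",
                                              "pooled_control"),
                                 criteria = screen_criteria()) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  baseline <- match.arg(baseline)
  vals <- em$values
  notes <- character()
  n_floored <- sum(vals <= 0)
  if (n_floored > 0) {
    floor_val <- min(vals[vals > 0]) / 2
    vals[vals <= 0] <- floor_val
    notes <- c(notes, sprintf("floored %d non-positive value(s) to %.6g",
                              n_floored, floor_val))
  }
  l2 <- log2(vals)
  meta <- em$samples
  tps <- sort(unique(meta$timepoint_h))
  is_control <- meta$condition == "control"

  if (baseline == "timepoint0") {
    base_cols <- which(meta$timepoint_h == 0)
    if (!length(base_cols))
      stop("no baseline samples: no samples at timepoint 0", call. = FALSE)
  } else {
    if (!any(is_control))
      stop("no baseline samples: no control-condition samples", call. = FALSE)
  }

  gid <- rownames(vals)
  if (is.null(gid)) gid <- character(0)
  rows <- vector("list", length(tps))
  for (k in seq_along(tps)) {
    t <- tps[k]
    if (baseline == "timepoint0") {
      tcols <- which(meta$timepoint_h == t)
      bcols <- base_cols
      if (t == 0) {                       # baseline vs itself: FC = 1
        ng <- nrow(vals)
        rows[[k]] <- data.frame(gene_id = gid,
                                timepoint_h = rep(t, ng),
                                fold_change = rep(1, ng),
                                p_value = rep(NA_real_, ng),
                                n_treated = rep(length(tcols), ng),
                                n_baseline = rep(length(bcols), ng),
                                degenerate = rep(FALSE, ng),
                                stringsAsFactors = FALSE)
        next
      }
    } else {
      tcols <- which(meta$timepoint_h == t & !is_control)
      bcols <- which(meta$timepoint_h == t & is_control)
      if (!length(tcols)) {
        # control-only timepoint (or absent treated group): skip silently
        # only if no treated samples exist anywhere at t
        rows[[k]] <- NULL
        next
      }
      if (!length(bcols)) {
        if (baseline == "matched_control") {
          bcols <- which(is_control)
          notes <- c(notes, sprintf(
            "timepoint %g h: no matched control, compared to pooled control arm", t))
        }
      }
      if (baseline == "pooled_control") bcols <- which(is_control)
    }
    if (!length(tcols))
      stop(sprintf("missing group: no samples at timepoint %g h", t),
           call. = FALSE)
    fc <- 2^(rowMeans(l2[, tcols, drop = FALSE]) -
               rowMeans(l2[, bcols, drop = FALSE]))
    nt <- length(tcols); nb <- length(bcols)
    p <- rep(NA_real_, nrow(vals)); degen <- rep(TRUE, nrow(vals))
    min_n <- if (criteria$test_method == "welch_t") 2L else 1L
    if (nt >= min_n && nb >= min_n) {
      for (i in seq_len(nrow(vals))) {
        gc <- group_compare(l2[i, tcols], l2[i, bcols], criteria$test_method)
        p[i] <- gc$p_value
        degen[i] <- gc$degenerate
      }
    }
    ng <- nrow(vals)
    rows[[k]] <- data.frame(gene_id = gid,
                            timepoint_h = rep(t, ng),
                            fold_change = fc, p_value = p,
                            n_treated = rep(nt, ng),
                            n_baseline = rep(nb, ng),
                            degenerate = degen, stringsAsFactors = FALSE)
  }
  prof <- do.call(rbind, rows)
  rownames(prof) <- NULL
  if (criteria$p_adjust == "BH") {
    for (t in unique(prof$timepoint_h)) {
      sel <- prof$timepoint_h == t & !is.na(prof$p_value)
      prof$p_value[sel] <- p.adjust(prof$p_value[sel], method = "BH")
    }
    notes <- c(notes, "p-values Benjamini-Hochberg adjusted per timepoint")
  }
  structure(prof,
            class = c("gene_time_profiles", "data.frame"),
            timepoints = if (nrow(prof)) sort(unique(prof$timepoint_h)) else tps,
            baseline = baseline, test_method = criteria$test_method,
            n_floored = n_floored, notes = notes)
}

# Wide lookup: genes x timepoints matrices of FC and p.
.profile_wide <- function(profiles) {
  genes <- unique(profiles$gene_id)
  tps <- attr(profiles, "timepoints")
  if (is.null(tps)) tps <- sort(unique(profiles$timepoint_h))
  fc <- matrix(NA_real_, length(genes), length(tps),
               dimnames = list(genes, as.character(tps)))
  p <- fc
  gi <- match(profiles$gene_id, genes)
  ti <- match(profiles$timepoint_h, tps)
  fc[cbind(gi, ti)] <- profiles$fold_change
  p[cbind(gi, ti)] <- profiles$p_value
  list(genes = genes, tps = tps, fc = fc, p = p)
}

.require_timepoints <- function(have, need, what) {
  miss <- setdiff(need, have)
  if (length(miss))
    stop(sprintf("missing timepoint(s) in profiles for %s: %s h", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

.new_screen_result <- function(genes_df, profiles, criteria, screen_type,
                               gate_counts, label_levels) {
  genes_df$class_label <- factor(genes_df$class_label, levels = label_levels)
  ord <- order(genes_df$class_label, -genes_df$max_fold_change,
               genes_df$gene_id)
  genes_df <- genes_df[ord, , drop = FALSE]
  rownames(genes_df) <- NULL
  structure(list(genes = genes_df, profiles = profiles, criteria = criteria,
                 screen_type = screen_type, gate_counts = gate_counts),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf("ScreenResult (%s screen): %d genes\n", x$screen_type,
              nrow(x$genes)))
  print(table(x$genes$class_label))
  cat("gates:", paste(names(x$gate_counts), x$gate_counts, sep = "=",
                      collapse = " -> "), "\n")
  invisible(x)
}

#' Classify transient induction in a post-injury course
#'
#' Applies the transient-induction criterion to per-gene profiles: a gene
#' is `TRANSIENT_INDUCED` when its fold change is >= `induction_fold` at
#' the induction timepoints (all of them under the default `"all"` policy),
#' significant at `alpha` at each of those timepoints (when the
#' significance gate is on), and back within the return band
#' (FC within `[1 - band, 1 + band]`, both ends inclusive) at the return
#' timepoint. A gene passing induction whose return-timepoint FC is still
#' >= `induction_fold` is `SUSTAINED_INDUCED`; passing induction but
#' outside the band (and below the fold threshold) is
#' `INDUCED_NOT_RETURNED`; everything else is `NOT_INDUCED`. Every gene
#' receives exactly one label.
#'
#' @param profiles A `gene_time_profiles` data frame from
#'   [compute_fold_changes()].
#' @param criteria A [screen_criteria()].
#' @return A `ScreenResult`: ranked gene table (`gene_id`, `class_label`,
#'   `max_fold_change`), the profiles, the criteria and per-gate counts.
#' @export
classify_transient <- function(profiles, criteria = screen_criteria()) {
  w <- .profile_wide(profiles)
  need <- c(criteria$induction_timepoints_h, criteria$return_timepoint_h)
  .require_timepoints(w$tps, need, "transient classification")
  ind_t <- as.character(criteria$induction_timepoints_h)
  ret_t <- as.character(criteria$return_timepoint_h)

  fc_ind <- w$fc[, ind_t, drop = FALSE]
  p_ind <- w$p[, ind_t, drop = FALSE]
  pass_fc <- fc_ind >= criteria$induction_fold
  agg <- if (criteria$induction_policy == "all") function(m) rowSums(!m) == 0
         else function(m) rowSums(m, na.rm = TRUE) > 0
  induced_fc <- agg(pass_fc)
  if (criteria$require_significance) {
    pass_p <- !is.na(p_ind) & p_ind < criteria$alpha
    # significance must hold wherever induction is claimed; under "all"
    # that is every induction timepoint
    sig_ok <- if (criteria$induction_policy == "all") rowSums(!pass_p) == 0
              else agg(pass_fc & pass_p)
  } else sig_ok <- rep(TRUE, length(induced_fc))
  induced <- induced_fc & sig_ok
  fc_ret <- w$fc[, ret_t]
  in_band <- fc_ret >= 1 - criteria$return_band &
             fc_ret <= 1 + criteria$return_band
  still_up <- fc_ret >= criteria$induction_fold

  label <- rep("NOT_INDUCED", length(w$genes))
  label[induced & in_band] <- "TRANSIENT_INDUCED"
  label[induced & !in_band & still_up] <- "SUSTAINED_INDUCED"
  label[induced & !in_band & !still_up] <- "INDUCED_NOT_RETURNED"

  post <- w$tps > 0
  max_fc <- if (length(w$genes))
    apply(w$fc[, post, drop = FALSE], 1, max) else numeric(0)
  genes_df <- data.frame(gene_id = w$genes, class_label = label,
                         max_fold_change = max_fc, stringsAsFactors = FALSE)
  gates <- c(genes_in = length(w$genes),
             induced = sum(induced_fc),
             significant = sum(induced),
             returned = sum(induced & in_band))
  .new_screen_result(genes_df, profiles, criteria, "wound", gates,
                     WOUND_LABELS)
}

#' Classify sustained upregulation in a treated-vs-control course
#'
#' A gene is `SUSTAINED_UP` ("upregulated throughout") when its fold
#' change is >= `sustained_fold`, with `p < alpha` when the significance
#' gate is on, at every treated timepoint (> 0 h; the 0 h point, where
#' treated and control arms are both pre-treatment, is reported but not
#' gating). Otherwise `NOT_SUSTAINED`.
#'
#' @inheritParams classify_transient
#' @return A `ScreenResult` over labels `SUSTAINED_UP` / `NOT_SUSTAINED`.
#' @export
classify_sustained_up <- function(profiles, criteria = screen_criteria()) {
  w <- .profile_wide(profiles)
  post <- w$tps > 0
  if (!any(post))
    stop("missing timepoint(s): no treated timepoints > 0 h", call. = FALSE)
  fc <- w$fc[, post, drop = FALSE]
  p <- w$p[, post, drop = FALSE]
  pass_fc <- rowSums(fc < criteria$sustained_fold) == 0
  if (criteria$require_significance) {
    pass_p <- rowSums(!(!is.na(p) & p < criteria$alpha)) == 0
  } else pass_p <- rep(TRUE, length(pass_fc))
  up <- pass_fc & pass_p
  label <- ifelse(up, "SUSTAINED_UP", "NOT_SUSTAINED")
  rng <- function(f) if (length(w$genes)) apply(fc, 1, f) else numeric(0)
  genes_df <- data.frame(gene_id = w$genes, class_label = label,
                         max_fold_change = rng(max),
                         stringsAsFactors = FALSE)
  genes_df$min_fold_change <- rng(min)
  gates <- c(genes_in = length(w$genes), fold_pass = sum(pass_fc),
             sustained = sum(up))
  .new_screen_result(genes_df, profiles, criteria, "fibrosis", gates,
                     FIBROSIS_LABELS)
}

#' Intersect the wound and fibrosis screens
#'
#' The discovery step: candidate fibrosis drivers are the genes labeled
#' `TRANSIENT_INDUCED` in the wound screen AND `SUSTAINED_UP` in the
#' fibrosis screen (the amphiregulin pattern). Intersection is over shared
#' gene ids; empty inputs give an empty candidate list.
#'
#' @param wound_result `ScreenResult` from [classify_transient()].
#' @param fibrosis_result `ScreenResult` from [classify_sustained_up()].
#' @return A data frame of class `CandidateHits`, ordered by descending
#'   wound fold change then gene id, with columns `gene_id`,
#'   `wound_class`, `fibrosis_class`, `wound_max_fc`, `fibrosis_min_fc`.
#' @export
intersect_screens <- function(wound_result, fibrosis_result) {
  stopifnot(inherits(wound_result, "ScreenResult"),
            inherits(fibrosis_result, "ScreenResult"))
  wg <- wound_result$genes
  fg <- fibrosis_result$genes
  tr <- wg$gene_id[wg$class_label == "TRANSIENT_INDUCED"]
  su <- fg$gene_id[fg$class_label == "SUSTAINED_UP"]
  hit <- intersect(tr, su)
  out <- data.frame(
    gene_id = hit,
    wound_class = rep("TRANSIENT_INDUCED", length(hit)),
    fibrosis_class = rep("SUSTAINED_UP", length(hit)),
    wound_max_fc = wg$max_fold_change[match(hit, wg$gene_id)],
    fibrosis_min_fc = fg$min_fold_change[match(hit, fg$gene_id)],
    stringsAsFactors = FALSE)
  out <- out[order(-out$wound_max_fc, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("CandidateHits", "data.frame")
  out
}
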