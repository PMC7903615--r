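#' Temporal templates for simulated genes
#'
#' Expected fold-change multipliers (linear scale, relative to the 0 h
#' baseline) for each planted temporal class, evaluated on an arbitrary
#' timepoint grid. The contract-bearing anchors are:
#'
#' * `TRANSIENT`: multiplier = `peak_fold` at 12 h and 24 h, exactly 1 at
#'   0 h and at every timepoint >= 72 h (the amphiregulin shape in scarless
#'   wound healing); log-linear interpolation between anchors.
#' * `SUSTAINED`: multiplier = `peak_fold` at every post-injury timepoint
#'   (the persistent-fibrosis shape), 1 at 0 h.
#' * `LATE`: 1 up to 24 h, rising log-linearly to `peak_fold` at 72 h and
#'   beyond.
#' * `REPRESSED`: `1 / peak_fold` at every post-injury timepoint.
#' * `FLAT`: 1 everywhere.
#'
#' @param class_label One of `"TRANSIENT"`, `"SUSTAINED"`, `"LATE"`,
#'   `"REPRESSED"`, `"FLAT"`.
#' @param peak_fold Positive multiplier at the template's peak (e.g. 10 for
#'   an Areg-like gene). Ignored for `FLAT`.
#' @param timepoints_h Numeric vector of hours (>= 0) at which to evaluate
#'   the template.
#' @return Numeric vector of multipliers (> 0), one per timepoint.
#' @export
#' @examples
#' temporal_template("TRANSIENT", 10, c(0, 6, 12, 24, 72, 120))
temporal_template <- function(class_label, peak_fold, timepoints_h) {
  class_label <- match.arg(class_label, TEMPLATE_CLASSES)
  if (class_label != "FLAT" && (!is.finite(peak_fold) || peak_fold <= 0))
    stop("peak_fold must be a positive real", call. = FALSE)
  l2 <- log2(peak_fold)
  lmult <- switch(class_label,
    FLAT      = rep(0, length(timepoints_h)),
    SUSTAINED = ifelse(timepoints_h > 0, l2, 0),
    REPRESSED = ifelse(timepoints_h > 0, -l2, 0),
    TRANSIENT = approx(x = c(0, 12, 24, 72), y = c(0, l2, l2, 0),
                       xout = timepoints_h, rule = 2)$y,
    LATE      = approx(x = c(0, 24, 72), y = c(0, 0, l2),
                       xout = timepoints_h, rule = 2)$y)
  2^lmult
}

#' Simulation configuration
#'
#' Parameters of the synthetic time-course generator. Defaults emulate a
#' microarray wound-healing course: log2 baseline intensities ~
#' Normal(`baseline_log2_mean`, `baseline_log2_sd`), multiplicative
#' log-normal replicate noise (additive Gaussian in log2 with SD
#' `noise_log2_sd`), three replicates per group, and a dense early grid
#' (0/6/12/24 h) with later follow-up points (72/120/168/240 h).
#'
#' @param n_genes Number of genes (> 0).
#' @param class_proportions Named numeric vector over the template classes;
#'   must sum to 1 (within 1e-9). Realized counts use largest-remainder
#'   apportionment so they sum exactly to `n_genes`.
#' @param timepoints_h Strictly increasing hours, first element 0.
#' @param n_replicates Replicates per (timepoint, condition), >= 1.
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline abundance
#'   distribution (log2 scale).
#' @param noise_log2_sd Replicate measurement noise SD (log2 scale), >= 0.
#' @param peak_folds Named vector of peak fold changes per non-flat class.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 1000,
                              class_proportions = c(TRANSIENT = 0.05,
                                                    SUSTAINED = 0.05,
                                                    LATE = 0.05,
                                                    REPRESSED = 0.05,
                                                    FLAT = 0.80),
                              timepoints_h = c(0, 6, 12, 24, 72, 120, 168, 240),
                              n_replicates = 3,
                              baseline_log2_mean = 7,
                              baseline_log2_sd = 1.5,
                              noise_log2_sd = 0.2,
                              peak_folds = c(TRANSIENT = 10, SUSTAINED = 10,
                                             LATE = 5, REPRESSED = 5),
                              seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    stop("invalid configuration: n_genes must be a positive integer",
         call. = FALSE)
  if (length(timepoints_h) == 0)
    stop("invalid configuration: timepoints_h must be non-empty",
         call. = FALSE)
  if (timepoints_h[1] != 0 || is.unsorted(timepoints_h, strictly = TRUE))
    stop("invalid configuration: timepoints_h must be strictly increasing and start at 0",
         call. = FALSE)
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% TEMPLATE_CLASSES))
    stop("class_proportions must be named with template classes",
         call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("invalid configuration: class_proportions must sum to 1",
         call. = FALSE)
  if (n_replicates < 1)
    stop("invalid configuration: n_replicates must be >= 1", call. = FALSE)
  if (noise_log2_sd < 0)
    stop("invalid configuration: noise_log2_sd must be >= 0", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 class_proportions = class_proportions,
                 timepoints_h = as.numeric(timepoints_h),
                 n_replicates = as.integer(n_replicates),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_log2_sd = noise_log2_sd,
                 peak_folds = peak_folds,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Largest-remainder apportionment: counts sum exactly to n, ties broken by
# the order classes appear in `props`.
apportion_classes <- function(n, props) {
  quota <- n * props
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- quota - counts
    top <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  setNames(as.integer(counts), names(props))
}

# Deterministic per-gene seed, split from the dataset seed and a stream id
# so that (a) the two courses of a paired simulation draw independently and
# (b) adding genes never perturbs earlier genes' draws. Kept within 31 bits.
.gene_seed <- function(seed, stream, index) {
  as.integer((as.double(seed) %% 65536 * 2654435 + stream * 1299709 +
                index * 104729) %% 2147483647)
}

# Shared worker: one row of expression values for one gene.
.simulate_gene <- function(cfg, stream, index, log2mult_per_sample) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(.gene_seed(cfg$seed, stream, index))
  base_l2 <- rnorm(1, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  eps <- if (cfg$noise_log2_sd > 0)
    rnorm(length(log2mult_per_sample), 0, cfg$noise_log2_sd) else
      numeric(length(log2mult_per_sample))
  2^(base_l2 + log2mult_per_sample + eps)
}

.gene_ids <- function(n) sprintf("G%06d", seq_len(n))

# Hour label safe for sample ids (handles non-integer hours).
.tp_label <- function(t) gsub("\\.", "p", formatC(t, format = "g"))

#' Simulate a single-arm post-injury time course with planted classes
#'
#' Generates a genes x samples matrix emulating a wound-healing series:
#' every sample is from the injured tissue, the 0 h group is the unwounded
#' baseline. Each gene is assigned a temporal class per
#' `config$class_proportions` (largest-remainder counts) and follows its
#' [temporal_template()] multiplied by a gene-specific baseline and
#' log-normal replicate noise. Identical configs (including `seed`) give
#' bit-identical output; each gene draws from its own deterministic
#' substream, so growing `n_genes` leaves earlier genes unchanged.
#'
#' @param config A [simulation_config()].
#' @param alias Optional named character vector renaming synthetic gene ids
#'   for readability, e.g. `c(G000001 = "Areg")`.
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (data frame `gene_id`, `class_label`, `peak_fold`).
#' @export
#' @examples
#' sim <- generate_timecourse(simulation_config(n_genes = 20, seed = 42))
#' dim(sim$matrix)
generate_timecourse <- function(config, alias = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  counts <- apportion_classes(config$n_genes, config$class_proportions)
  classes <- rep(names(counts), counts)
  gid <- .gene_ids(config$n_genes)
  peak <- ifelse(classes == "FLAT", 1,
                 unname(config$peak_folds[classes]))
  tp <- config$timepoints_h
  nrep <- config$n_replicates
  tp_per_sample <- rep(tp, each = nrep)
  sample_id <- sprintf("W_t%s_r%d", rep(.tp_label(tp), each = nrep),
                       rep(seq_len(nrep), length(tp)))
  samples <- data.frame(sample_id = sample_id,
                        condition = ifelse(tp_per_sample == 0, "control",
                                           "injured"),
                        timepoint_h = tp_per_sample,
                        replicate = rep(seq_len(nrep), length(tp)),
                        stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, config$n_genes, length(sample_id),
                 dimnames = list(gid, sample_id))
  for (i in seq_len(config$n_genes)) {
    mult <- temporal_template(classes[i], peak[i], tp)
    vals[i, ] <- .simulate_gene(config, stream = 1L, index = i,
                                log2mult_per_sample = log2(rep(mult, each = nrep)))
  }
  truth <- data.frame(gene_id = gid, class_label = classes,
                      peak_fold = peak, stringsAsFactors = FALSE)
  if (!is.null(alias)) {
    unknown <- setdiff(names(alias), gid)
    if (length(unknown))
      stop("alias names unknown gene(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    idx <- match(names(alias), gid)
    rownames(vals)[idx] <- alias
    truth$gene_id[idx] <- alias
  }
  list(matrix = expression_matrix(vals, samples), truth = truth)
}

#' Simulate a two-arm (control vs treated) fibrosis time course
#'
#' Generates a paired fibrosis course over the same gene universe as a
#' wound-course simulation: at every timepoint both a control arm (e.g.
#' PBS) and a treated arm (e.g. bleomycin) are sampled with
#' `config$n_replicates` replicates each. Genes named in `overlap_spec`
#' carry the assigned fibrosis-course class in the treated arm (the
#' Areg pattern is `"SUSTAINED"` here for a gene that was `"TRANSIENT"` in
#' the wound course); all other genes are `FLAT`. The control arm is always
#' flat. Baselines and noise are drawn from a substream independent of the
#' wound course's.
#'
#' @param config A [simulation_config()]; its `timepoints_h` is the
#'   fibrosis grid (0 h is the pre-treatment point).
#' @param shared_truth The `truth` data frame of the paired wound-course
#'   simulation; defines the gene universe.
#' @param overlap_spec Named character vector `gene_id -> class_label`
#'   assigning fibrosis-course classes; may be empty (all genes flat).
#' @param peak_folds Named vector of treated-arm peak folds per class.
#' @return A list with `matrix` (an [expression_matrix()]) and `truth`
#'   (fibrosis-course classes).
#' @export
generate_fibrosis_course <- function(config, shared_truth,
                                     overlap_spec = character(),
                                     peak_folds = c(SUSTAINED = 10,
                                                    TRANSIENT = 10,
                                                    LATE = 5, REPRESSED = 5)) {
  stopifnot(inherits(config, "SimulationConfig"))
  gid <- shared_truth$gene_id
  if (length(overlap_spec)) {
    if (is.null(names(overlap_spec)))
      stop("overlap_spec must be a named vector (gene_id -> class)",
           call. = FALSE)
    unknown <- setdiff(names(overlap_spec), gid)
    if (length(unknown))
      stop("unknown gene(s) in overlap_spec: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bad <- setdiff(unname(overlap_spec), TEMPLATE_CLASSES)
    if (length(bad))
      stop("unknown class in overlap_spec: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  classes <- setNames(rep("FLAT", length(gid)), gid)
  classes[names(overlap_spec)] <- unname(overlap_spec)
  peak <- ifelse(classes == "FLAT", 1, unname(peak_folds[classes]))
  tp <- config$timepoints_h
  nrep <- config$n_replicates
  arm <- function(prefix) sprintf("%s_t%s_r%d", prefix,
                                  rep(.tp_label(tp), each = nrep),
                                  rep(seq_len(nrep), length(tp)))
  sample_id <- c(arm("PBS"), arm("BLM"))
  tp_all <- rep(rep(tp, each = nrep), 2)
  samples <- data.frame(sample_id = sample_id,
                        condition = rep(c("control", "treated"),
                                        each = length(tp) * nrep),
                        timepoint_h = tp_all,
                        replicate = rep(rep(seq_len(nrep), length(tp)), 2),
                        stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, length(gid), length(sample_id),
                 dimnames = list(gid, sample_id))
  for (i in seq_along(gid)) {
    mult_treated <- temporal_template(classes[i], peak[i], tp)
    l2 <- c(rep(0, length(tp) * nrep),                     # control arm flat
            log2(rep(mult_treated, each = nrep)))          # treated arm
    vals[i, ] <- .simulate_gene(config, stream = 2L, index = i,
                                log2mult_per_sample = l2)
  }
  truth <- data.frame(gene_id = gid, class_label = unname(classes),
                      peak_fold = peak, stringsAsFactors = FALSE)
  list(matrix = expression_matrix(vals, samples), truth = truth)
}
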