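#' Run the full screen pipeline from a YAML config
#'
#' Wires simulate -> fold changes -> transient screen -> sustained screen
#' -> intersection (-> optional qPCR quantification) and writes all
#' outputs, a run log and a reproducibility manifest into one directory.
#' Re-running an identical config (including seed) reproduces byte-identical
#' outputs.
#'
#' The config has sections:
#' * `simulate`: `seed`, `n_genes`, `n_replicates`, `noise_log2_sd`,
#'   `wound_timepoints_h`, `fibrosis_timepoints_h`, `class_proportions`,
#'   `peak_folds`, `overlap` (gene -> fibrosis class), `alias`
#'   (gene -> display name); or instead `inputs` with paths
#'   `wound_matrix`/`wound_samples`/`fibrosis_matrix`/`fibrosis_samples`.
#' * `screen`: any [screen_criteria()] argument plus `fibrosis_baseline`
#'   (`"matched_control"` or `"pooled_control"`).
#' * `qpcr` (optional): `plate` (TSV path), `reference_gene`,
#'   `calibrator_sample`, `target_gene`.
#' * `output`: `dir`.
#'
#' @param config_path Path to the YAML config.
#' @param out_dir Output directory; overrides `output$dir`.
#' @return Invisibly, a list with the output directory, the manifest and
#'   the main in-memory results (`wound`, `fibrosis`, `candidates`).
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(out_dir)) out_dir <- cfg$output$dir
  if (is.null(out_dir))
    stop("pipeline [output]: no output directory configured", call. = FALSE)
  stage <- tempfile("scarscreen_stage_")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # ---- stage: inputs (simulate or load) -------------------------------
  sim <- cfg$simulate
  seed <- if (!is.null(sim$seed)) as.integer(sim$seed) else 1L
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline [%s]: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (!is.null(cfg$inputs)) {
    wound <- step("load", read_matrix(cfg$inputs$wound_matrix,
                                      cfg$inputs$wound_samples))
    fib <- step("load", read_matrix(cfg$inputs$fibrosis_matrix,
                                    cfg$inputs$fibrosis_samples))
    wound_truth <- fib_truth <- NULL
    say("load: wound %d x %d, fibrosis %d x %d", nrow(wound$values),
        ncol(wound$values), nrow(fib$values), ncol(fib$values))
  } else {
    props <- unlist(sim$class_proportions %||%
                      list(TRANSIENT = 0.05, SUSTAINED = 0.05, FLAT = 0.90))
    pf_default <- c(TRANSIENT = 10, SUSTAINED = 10, LATE = 5, REPRESSED = 5)
    pf <- unlist(sim$peak_folds)
    peak_folds <- pf_default
    if (length(pf)) peak_folds[names(pf)] <- pf
    wcfg <- step("simulate", simulation_config(
      n_genes = sim$n_genes %||% 1000,
      class_proportions = props,
      timepoints_h = unlist(sim$wound_timepoints_h %||%
                              c(0, 6, 12, 24, 72, 120, 168, 240)),
      n_replicates = sim$n_replicates %||% 3,
      noise_log2_sd = sim$noise_log2_sd %||% 0.2,
      peak_folds = peak_folds, seed = seed))
    alias <- unlist(sim$alias)
    wsim <- step("simulate", generate_timecourse(wcfg, alias = alias))
    wound <- wsim$matrix; wound_truth <- wsim$truth
    fcfg <- step("simulate", simulation_config(
      n_genes = wcfg$n_genes, class_proportions = props,
      timepoints_h = unlist(sim$fibrosis_timepoints_h %||% c(0, 72, 168, 240)),
      n_replicates = wcfg$n_replicates, noise_log2_sd = wcfg$noise_log2_sd,
      peak_folds = peak_folds, seed = seed + 1L))
    overlap <- unlist(sim$overlap) %||% character()
    if (length(overlap) && length(alias)) {
      # overlap may be declared under either the synthetic or aliased name
      hit <- names(overlap) %in% names(alias)
      names(overlap)[hit] <- unname(alias[names(overlap)[hit]])
    }
    fsim <- step("simulate", generate_fibrosis_course(
      fcfg, wound_truth, overlap_spec = overlap, peak_folds = peak_folds))
    fib <- fsim$matrix; fib_truth <- fsim$truth
    say("simulate: %d genes, wound %d samples, fibrosis %d samples, seed %d",
        wcfg$n_genes, ncol(wound$values), ncol(fib$values), seed)
    write_matrix(wound, file.path(stage, "wound_matrix.tsv"),
                 file.path(stage, "wound_samples.tsv"))
    write_matrix(fib, file.path(stage, "fibrosis_matrix.tsv"),
                 file.path(stage, "fibrosis_samples.tsv"))
    write_truth(wound_truth, file.path(stage, "wound_truth.tsv"))
    write_truth(fib_truth, file.path(stage, "fibrosis_truth.tsv"))
  }

  # ---- stage: screens --------------------------------------------------
  crit <- step("screen", read_criteria(cfg$screen %||% list()))
  fib_baseline <- (cfg$screen$fibrosis_baseline) %||% "matched_control"
  wprof <- step("screen", compute_fold_changes(wound, "timepoint0", crit))
  wres <- step("screen", classify_transient(wprof, crit))
  say("wound screen gates: %s",
      paste(names(wres$gate_counts), wres$gate_counts, sep = "=",
            collapse = " -> "))
  fprof <- step("screen", compute_fold_changes(fib, fib_baseline, crit))
  fres <- step("screen", classify_sustained_up(fprof, crit))
  say("fibrosis screen gates: %s",
      paste(names(fres$gate_counts), fres$gate_counts, sep = "=",
            collapse = " -> "))
  for (nt in c(attr(wprof, "notes"), attr(fprof, "notes")))
    say("note: %s", nt)
  hits <- step("intersect", intersect_screens(wres, fres))
  say("intersect: %d candidate gene(s)%s", nrow(hits),
      if (nrow(hits)) paste0(": ", paste(hits$gene_id, collapse = ", "))
      else "")
  write_results(wres, file.path(stage, "wound_screen.tsv"), json = TRUE)
  write_results(fres, file.path(stage, "fibrosis_screen.tsv"), json = TRUE)
  write_candidates(hits, file.path(stage, "candidates.tsv"))

  # ---- stage: qpcr (optional) -----------------------------------------
  if (!is.null(cfg$qpcr)) {
    q <- cfg$qpcr
    plate <- step("qpcr", read_qpcr_plate(q$plate, q$reference_gene,
                                          q$calibrator_sample))
    summ <- step("qpcr", plate_summary(plate, q$target_gene))
    out <- summ
    out$rq <- .fmt_num(out$rq); out$sd_delta_ct <- .fmt_num(out$sd_delta_ct)
    write.table(out, file.path(stage, "qpcr_rq.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    say("qpcr: %d sample(s) quantified for %s (reference %s, calibrator %s)",
        nrow(summ), q$target_gene, q$reference_gene, q$calibrator_sample)
  }

  # ---- finalize: manifest, log, atomic move ---------------------------
  writeLines(log_lines, file.path(stage, "run.log"))
  files <- sort(list.files(stage))
  digests <- as.list(tools::md5sum(file.path(stage, files)))
  names(digests) <- files
  manifest <- list(
    tool = "scarscreen",
    version = as.character(packageVersion("scarscreen")),
    seed = seed,
    config = cfg,
    criteria = unclass(crit),
    fibrosis_baseline = fib_baseline,
    gate_counts = list(wound = as.list(wres$gate_counts),
                       fibrosis = as.list(fres$gate_counts),
                       candidates = nrow(hits)),
    warnings = list(wound_floored = attr(wprof, "n_floored"),
                    fibrosis_floored = attr(fprof, "n_floored"),
                    notes = c(attr(wprof, "notes"), attr(fprof, "notes"))),
    output_digests = digests)
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage))
    file.copy(file.path(stage, f), file.path(out_dir, f), overwrite = TRUE)
  invisible(list(out_dir = out_dir, manifest = manifest, wound = wres,
                 fibrosis = fres, candidates = hits))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
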