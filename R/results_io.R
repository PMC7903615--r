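#' Write / read screen results
#'
#' One row per gene: `gene_id`, `class_label`, `max_fold_change`, then one
#' fold-change and one p-value column per timepoint (`fc_<t>h`, `p_<t>h`).
#' Rows keep the result's ranked order (class, descending max fold change,
#' gene id), so the file is a stable, human-scannable candidate list.
#' Floats use 12 significant digits; re-reading reproduces labels exactly
#' and numbers to well past 9 significant digits. With `json = TRUE` a
#' machine-readable mirror is written next to the TSV.
#'
#' @param result A `ScreenResult` from [classify_transient()] or
#'   [classify_sustained_up()].
#' @param path Output TSV path.
#' @param json Also write `<path>.json`?
#' @return `write_results()` the path, invisibly; `read_results()` a data
#'   frame in file order.
#' @export
write_results <- function(result, path, json = FALSE) {
  stopifnot(inherits(result, "ScreenResult"))
  w <- .profile_wide(result$profiles)
  genes <- result$genes
  out <- data.frame(gene_id = genes$gene_id,
                    class_label = as.character(genes$class_label),
                    max_fold_change = .fmt_num(genes$max_fold_change),
                    stringsAsFactors = FALSE)
  idx <- match(genes$gene_id, w$genes)
  for (t in w$tps)
    out[[sprintf("fc_%sh", .tp_label(t))]] <-
      .fmt_num(w$fc[idx, as.character(t)])
  for (t in w$tps)
    out[[sprintf("p_%sh", .tp_label(t))]] <-
      .fmt_num(w$p[idx, as.character(t)])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json) {
    jr <- list(screen_type = result$screen_type,
               criteria = unclass(result$criteria),
               gate_counts = as.list(result$gate_counts),
               genes = out)
    jsonlite::write_json(jr, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write candidate hits from [intersect_screens()] as TSV
#'
#' @param hits A `CandidateHits` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_candidates <- function(hits, path) {
  out <- hits
  for (col in c("wound_max_fc", "fibrosis_min_fc"))
    out[[col]] <- .fmt_num(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
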