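#' Expression matrix with sample metadata
#'
#' Container for a genes x samples abundance table (linear scale, values
#' >= 0) plus per-sample metadata. This is the substrate of the screen; it
#' mirrors the layout of a GEO series-matrix export reduced to a plain TSV.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids).
#' @param samples Data frame with one row per sample and columns
#'   `sample_id`, `condition` (e.g. `"control"`, `"injured"`, `"treated"`),
#'   `timepoint_h` (hours post injury, >= 0) and `replicate` (integer).
#'   Row order must not matter; samples are matched to matrix columns by
#'   `sample_id`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `samples` (metadata reordered to match the columns).
#' @export
#' @examples
#' v <- matrix(100, 2, 2, dimnames = list(c("G1", "G2"), c("s1", "s2")))
#' s <- data.frame(sample_id = c("s1", "s2"), condition = "control",
#'                 timepoint_h = 0, replicate = 1:2)
#' em <- expression_matrix(v, s)
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- character(0)
  gid <- rownames(values)
  sid <- colnames(values)
  if (anyDuplicated(gid))
    stop("duplicate gene identifier: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample identifier: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  required <- c("sample_id", "condition", "timepoint_h", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  absent <- setdiff(sid, samples$sample_id)
  if (length(absent))
    stop("sample(s) in matrix missing from sample sheet: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(samples$timepoint_h)) || any(samples$timepoint_h < 0))
    stop("timepoint_h must be finite and >= 0", call. = FALSE)
  samples <- samples[match(sid, samples$sample_id), required, drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tp <- sort(unique(x$samples$timepoint_h))
  cat("  timepoints (h):", paste(tp, collapse = ", "), "\n")
  cat("  conditions:",
      paste(sort(unique(x$samples$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# Fixed float format shared by all writers: 12 significant digits keeps
# round-trips lossless well past the 9-digit contract while staying stable
# across platforms.
.fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write an expression matrix and its sample sheet as TSV
#'
#' First column of the matrix file is `gene_id`; remaining columns are
#' samples. The companion sample sheet has columns `sample_id`,
#' `condition`, `timepoint_h`, `replicate`. Output bytes are deterministic
#' for a given input (fixed column order and float format).
#'
#' @param em An [expression_matrix()].
#' @param matrix_path,sample_sheet_path Output file paths.
#' @return Invisibly, the matrix path.
#' @export
write_matrix <- function(em, matrix_path, sample_sheet_path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(em$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(em$values)))
    df[[colnames(em$values)[j]]] <- .fmt_num(em$values[, j])
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- em$samples
  ss$timepoint_h <- .fmt_num(ss$timepoint_h)
  write.table(ss, sample_sheet_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_path)
}

#' Read an expression matrix and its sample sheet from TSV
#'
#' Inverse of [write_matrix()]: `read_matrix(write_matrix(em))` reproduces
#' `em` up to float formatting (>= 9 significant digits preserved). Sample
#' column order is taken from the matrix file.
#'
#' @param matrix_path Path to the matrix TSV (first column `gene_id`).
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(matrix_path, sample_sheet_path) {
  for (p in c(matrix_path, sample_sheet_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  raw <- read.delim(matrix_path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2 || names(raw)[1] != "gene_id")
    stop("matrix file must start with a 'gene_id' column", call. = FALSE)
  gid <- raw[[1]]
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("duplicate gene identifier: ", paste(dup, collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(gid, colnames(vals))))
  bad <- which(is.na(num) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], gid[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]), call. = FALSE)
  ss <- read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  missing <- setdiff(colnames(num), ss$sample_id)
  if (length(missing))
    stop("sample(s) in matrix missing from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  expression_matrix(num, ss)
}

#' Write / read a synthetic ground-truth table
#'
#' TSV with columns `gene_id`, `class_label`, `peak_fold`; one row per gene
#' of the paired matrix.
#'
#' @param truth Data frame as returned in the `truth` element of
#'   [generate_timecourse()].
#' @param path Output (or input) file path.
#' @return `write_truth()` the path, invisibly; `read_truth()` the data
#'   frame.
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(c("gene_id", "class_label", "peak_fold") %in% names(truth)))
  out <- truth[, c("gene_id", "class_label", "peak_fold")]
  out$peak_fold <- .fmt_num(out$peak_fold)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
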