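#' qPCR plate with triplicate Ct values
#'
#' Holds Ct values (cycles) per (sample, gene, replicate) together with the
#' declared endogenous reference gene (e.g. Gapdh in mouse) and calibrator
#' sample, as required by the comparative-Ct method. Every sample with
#' wells for any target gene must also have wells for the reference gene.
#'
#' @param ct_data Data frame with columns `sample_id`, `gene_id`, `ct`
#'   (cycles) and `replicate`.
#' @param reference_gene Endogenous reference gene id (normalizer).
#' @param calibrator_sample Sample all quantities are expressed relative
#'   to. Required: the comparative-Ct method is undefined without it.
#' @param ct_range Plausible Ct range in cycles; wells outside it error.
#' @return A list of class `QpcrPlate`.
#' @export
#' @examples
#' ct <- data.frame(sample_id = rep(c("wk0", "wk2"), each = 4),
#'                  gene_id = rep(c("Areg", "Areg", "Gapdh", "Gapdh"), 2),
#'                  ct = c(24, 24.2, 18, 18.1, 21, 21.1, 18, 18.2),
#'                  replicate = rep(1:2, 4))
#' plate <- qpcr_plate(ct, reference_gene = "Gapdh",
#'                     calibrator_sample = "wk0")
qpcr_plate <- function(ct_data, reference_gene, calibrator_sample,
                       ct_range = c(0, 45)) {
  required <- c("sample_id", "gene_id", "ct", "replicate")
  miss <- setdiff(required, names(ct_data))
  if (length(miss))
    stop("ct_data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (missing(calibrator_sample) || is.null(calibrator_sample))
    stop("calibrator_sample is required", call. = FALSE)
  bad <- !is.finite(ct_data$ct) | ct_data$ct < ct_range[1] |
    ct_data$ct > ct_range[2]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("Ct out of range [%g, %g]: sample '%s', gene '%s', replicate %s (Ct = %s)",
                 ct_range[1], ct_range[2], ct_data$sample_id[i],
                 ct_data$gene_id[i], ct_data$replicate[i], ct_data$ct[i]),
         call. = FALSE)
  }
  samples <- unique(ct_data$sample_id)
  has_ref <- samples %in% ct_data$sample_id[ct_data$gene_id == reference_gene]
  if (any(!has_ref))
    stop("incomplete plate: no reference-gene ('", reference_gene,
         "') wells for sample(s): ",
         paste(samples[!has_ref], collapse = ", "), call. = FALSE)
  if (!(calibrator_sample %in% samples))
    stop("calibrator sample '", calibrator_sample, "' not on plate",
         call. = FALSE)
  structure(list(ct_data = ct_data, reference_gene = reference_gene,
                 calibrator_sample = calibrator_sample, ct_range = ct_range),
            class = "QpcrPlate")
}

.mean_ct <- function(plate, sample, gene) {
  ct <- plate$ct_data$ct[plate$ct_data$sample_id == sample &
                           plate$ct_data$gene_id == gene]
  if (!length(ct))
    stop(sprintf("incomplete plate: no wells for sample '%s', gene '%s'",
                 sample, gene), call. = FALSE)
  c(mean = mean(ct), sd = if (length(ct) > 1) sd(ct) else 0)
}

# Replicate Cts are averaged arithmetically (standard comparative-Ct
# practice); no outlier rejection. Amplification efficiency is fixed at
# perfect doubling, the assumption of the comparative-Ct method.
.delta_ct <- function(plate, sample, target_gene) {
  tg <- .mean_ct(plate, sample, target_gene)
  rf <- .mean_ct(plate, sample, plate$reference_gene)
  c(dct = unname(tg["mean"] - rf["mean"]),
    sd = unname(sqrt(tg["sd"]^2 + rf["sd"]^2)))
}

#' Relative quantity by the comparative-Ct (delta-delta-Ct) method
#'
#' RQ = 2^(-ddCt) with ddCt = dCt(sample) - dCt(calibrator) and
#' dCt(s) = mean Ct of the target gene minus mean Ct of the reference gene
#' in sample s. RQ is dimensionless, always positive, equals 1 for the
#' calibrator, and is invariant under any global Ct shift applied equally
#' to target and reference.
#'
#' @param plate A [qpcr_plate()].
#' @param target_gene Target gene id.
#' @param sample Sample id to quantify.
#' @return The relative quantity (single positive number).
#' @export
relative_quantity <- function(plate, target_gene, sample) {
  stopifnot(inherits(plate, "QpcrPlate"))
  dct_s <- .delta_ct(plate, sample, target_gene)
  dct_c <- .delta_ct(plate, plate$calibrator_sample, target_gene)
  2^(-(dct_s[["dct"]] - dct_c[["dct"]]))
}

#' Per-sample RQ summary for one target gene
#'
#' One row per sample on the plate: relative quantity and the replicate SD
#' of delta-Ct (propagated from target and reference replicate Cts as
#' sqrt(sd_target^2 + sd_reference^2)).
#'
#' @inheritParams relative_quantity
#' @return Data frame with columns `sample_id`, `rq`, `sd_delta_ct`.
#' @export
plate_summary <- function(plate, target_gene) {
  stopifnot(inherits(plate, "QpcrPlate"))
  samples <- unique(plate$ct_data$sample_id)
  dct_c <- .delta_ct(plate, plate$calibrator_sample, target_gene)
  rows <- lapply(samples, function(s) {
    d <- .delta_ct(plate, s, target_gene)
    data.frame(sample_id = s, rq = 2^(-(d[["dct"]] - dct_c[["dct"]])),
               sd_delta_ct = d[["sd"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a qPCR plate from TSV
#'
#' Expects columns `sample_id`, `gene_id`, `ct`, `replicate`.
#'
#' @param path Input TSV path.
#' @inheritParams qpcr_plate
#' @return A [qpcr_plate()].
#' @export
read_qpcr_plate <- function(path, reference_gene, calibrator_sample,
                            ct_range = c(0, 45)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  qpcr_plate(read.delim(path, stringsAsFactors = FALSE), reference_gene,
             calibrator_sample, ct_range)
}
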