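# Per-cell QC, signature scoring and CBC/RSC/mixed classification.

#' QC thresholds for single cells
#'
#' Defaults follow the usual epithelial scRNA-seq gates: more than 1000
#' UMIs (strict), mitochondrial fraction below 0.30 (strict), and between
#' 2000 and 6000 detected genes (inclusive both ends).
#'
#' @param min_umi,max_mito,min_genes,max_genes Gate values.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_umi = 1000, max_mito = 0.30,
                          min_genes = 2000, max_genes = 6000) {
  stopifnot(min_genes <= max_genes, max_mito > 0, max_mito < 1)
  structure(list(min_umi = min_umi, max_mito = max_mito,
                 min_genes = min_genes, max_genes = max_genes),
            class = "qc_thresholds")
}

#' Per-cell QC metrics from a count matrix
#'
#' @param counts Gene x cell count matrix; mitochondrial genes are
#'   recognized by `mito_regex` on rownames.
#' @param patient Optional per-cell patient labels.
#' @param mito_regex Regex identifying mitochondrial features (default
#'   matches the human `MT-` / mouse `mt-` prefixes).
#' @return Data frame with `barcode`, `patient`, `umi_count`,
#'   `genes_detected`, `mito_fraction`.
#' @export
cell_qc_metrics <- function(counts, patient = NULL, mito_regex = "^(MT|mt)-") {
  umi <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito <- grepl(mito_regex, rownames(counts))
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(umi, 1) else
      rep(0, ncol(counts))
  data.frame(barcode = colnames(counts) %||% paste0("cell", seq_along(umi)),
             patient = patient %||% NA_character_,
             umi_count = as.integer(umi),
             genes_detected = as.integer(detected),
             mito_fraction = as.numeric(mito_frac),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter cells on QC gates
#'
#' A cell passes iff `umi_count > min_umi` AND `mito_fraction < max_mito`
#' AND `min_genes <= genes_detected <= max_genes`. Failing cells are
#' marked with reason codes, never dropped, so downstream steps can audit
#' the gate.
#'
#' @param cells Data frame with `umi_count`, `genes_detected`,
#'   `mito_fraction` (see [cell_qc_metrics()]).
#' @param thr [qc_thresholds()].
#' @return `cells` with added logical `qc_pass` and character `qc_reason`
#'   (`""` for passing cells; comma-separated codes among `low_umi`,
#'   `high_mito`, `low_genes`, `high_genes` otherwise).
#' @export
qc_filter <- function(cells, thr = qc_thresholds()) {
  need <- c("umi_count", "genes_detected", "mito_fraction")
  if (!all(need %in% names(cells)))
    stop("cells must contain: ", paste(need, collapse = ", "))
  if (anyNA(cells[need])) stop("QC metrics contain missing values")
  reasons <- mapply(function(u, g, m) {
    r <- c(if (!(u > thr$min_umi)) "low_umi",
           if (!(m < thr$max_mito)) "high_mito",
           if (g < thr$min_genes) "low_genes",
           if (g > thr$max_genes) "high_genes")
    paste(r, collapse = ",")
  }, cells$umi_count, cells$genes_detected, cells$mito_fraction)
  cells$qc_pass <- !nzchar(reasons)
  cells$qc_reason <- reasons
  if (!any(cells$qc_pass)) warning("qc_filter: no cell passes QC")
  cells
}

#' Depth-normalized log counts
#'
#' log1p of counts scaled to a fixed total per cell (default 10,000), the
#' conventional "logcounts" scale of single-cell toolkits.
#'
#' @param counts Gene x cell count matrix.
#' @param target_sum Per-cell total after scaling.
#' @return Matrix of the same shape on the logcounts scale.
#' @export
sc_logcounts <- function(counts, target_sum = 1e4) {
  depth <- Matrix::colSums(counts)
  if (any(depth == 0)) stop("cells with zero counts cannot be normalized")
  log1p(sweep(as.matrix(counts), 2, depth / target_sum, "/"))
}

#' Per-cell signature value
#'
#' The signature value of a cell is the arithmetic mean of its logcounts
#' over the signature genes present in the feature space; absent genes are
#' excluded from the denominator and reported once.
#'
#' @param logcounts Gene x cell matrix on the logcounts scale.
#' @param sig A [gene_signature].
#' @return Numeric vector, one value per cell.
#' @export
cell_signature_value <- function(logcounts, sig) {
  stopifnot(inherits(sig, "gene_signature"))
  present <- sig$genes[sig$genes %in% rownames(logcounts)]
  if (length(present) == 0L)
    stop("signature '", sig$name, "': no gene present in the matrix")
  if (length(present) < length(sig$genes))
    message(sprintf("signature '%s': %d/%d gene(s) absent from the matrix, mean over %d",
                    sig$name, length(sig$genes) - length(present),
                    length(sig$genes), length(present)))
  colMeans(logcounts[present, , drop = FALSE])
}

#' Positivity cutoff from a population percentile
#'
#' Takes the linear-interpolation percentile of the per-cell signature
#' values (so with tie-free values a 95th-percentile cutoff leaves 5\% of
#' cells strictly above it), then rounds to the nearest multiple of
#' `step` with ties rounding half up; `step = 0` disables rounding.
#'
#' @param values Per-cell signature values (>= 20 cells, all finite).
#' @param percentile Percentile in (0, 100); default 95.
#' @param step Rounding step on the logcounts scale; default 0.05.
#' @return The cutoff (single numeric).
#' @export
derive_cutoffs <- function(values, percentile = 95, step = 0.05) {
  if (length(values) < 20L) stop("need >= 20 cells to place a percentile cutoff")
  if (!all(is.finite(values))) stop("non-finite signature values")
  stopifnot(percentile > 0, percentile < 100, step >= 0)
  q <- unname(stats::quantile(values, percentile / 100, type = 7))
  # the 1e-9 guard keeps representation noise (0.475/0.05 < 9.5 in floating
  # point) from flipping an exact half tie downward
  if (step > 0) q <- floor(q / step + 0.5 + 1e-9) * step
  q
}

#' Classify cells as CBC / RSC / mixed / negative
#'
#' Positivity is strict: a value must exceed its cutoff. Cells above both
#' cutoffs are double-positive (`mixed`); above only one, `CBC` or `RSC`;
#' otherwise `negative`.
#'
#' @param cells Data frame with `cbc_value` and `rsc_value` (QC-passed
#'   cells only).
#' @param cbc_cutoff,rsc_cutoff Positivity cutoffs on the logcounts scale.
#' @return `cells` with an added `class` factor with levels
#'   `CBC`, `RSC`, `mixed`, `negative`.
#' @export
classify_cells <- function(cells, cbc_cutoff, rsc_cutoff) {
  stopifnot(all(c("cbc_value", "rsc_value") %in% names(cells)),
            is.finite(cbc_cutoff), is.finite(rsc_cutoff))
  cbc_pos <- cells$cbc_value > cbc_cutoff
  rsc_pos <- cells$rsc_value > rsc_cutoff
  cls <- ifelse(cbc_pos & rsc_pos, "mixed",
                ifelse(cbc_pos, "CBC",
                       ifelse(rsc_pos, "RSC", "negative")))
  cells$class <- factor(cls, levels = c("CBC", "RSC", "mixed", "negative"))
  cells
}
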