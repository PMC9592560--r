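# Bulk expression containers and between-sample normalization.

#' Construct a bulk expression matrix
#'
#' Thin container tying a gene x sample numeric matrix to its platform
#' scale, so downstream steps can pick the right kernel and normalization.
#'
#' @param values Numeric gene x sample matrix with rownames (gene ids) and
#'   colnames (sample ids); duplicate gene ids are not allowed.
#' @param platform One of `"rnaseq-counts"` (raw counts),
#'   `"microarray-intensity"` (normalized intensities), `"cpm"`
#'   (normalized counts-per-million), `"logcounts"` (log scale).
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values,
                        platform = c("rnaseq-counts", "microarray-intensity",
                                     "cpm", "logcounts")) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids; collapse first (see collapse_probes)")
  if (platform == "rnaseq-counts" && min(values) < 0)
    stop("rnaseq-counts values must be non-negative")
  structure(list(values = values, platform = platform),
            class = "expr_matrix")
}

#' @exportS3Method base::print
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$platform))
  invisible(x)
}

#' TMM-normalized counts-per-million
#'
#' Computes trimmed-mean-of-M-values scale factors (reference sample =
#' upper quartile closest to the mean upper quartile; log-ratio trim 0.30,
#' absolute-intensity trim 0.05; factors rescaled to geometric mean 1) and
#' returns counts-per-million on the effective library sizes. The
#' computation is delegated to edgeR, which implements exactly this
#' estimator.
#'
#' @param counts An `expr_matrix` with platform `"rnaseq-counts"`, or a
#'   plain count matrix; >= 2 samples; no all-zero sample.
#' @param log If `TRUE` return log2(CPM + 1) with platform `"logcounts"`,
#'   otherwise plain CPM.
#' @return An `expr_matrix`; the TMM scale factors are attached as
#'   attribute `"norm_factors"`.
#' @export
tmm_cpm <- function(counts, log = FALSE) {
  m <- if (inherits(counts, "expr_matrix")) {
    stopifnot(counts$platform == "rnaseq-counts")
    counts$values
  } else as.matrix(counts)
  if (ncol(m) < 2L) stop("TMM needs >= 2 samples")
  if (any(colSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  nf <- edgeR::calcNormFactors(m, method = "TMM")
  eff <- colSums(m) * nf
  cpm <- sweep(m, 2, eff / 1e6, "/")
  if (log) cpm <- log2(cpm + 1)
  out <- expr_matrix(cpm, platform = if (log) "logcounts" else "cpm")
  attr(out, "norm_factors") <- nf
  out
}

#' Collapse microarray probes to genes by averaging
#'
#' Per gene, the output value is the arithmetic mean of its probes' values
#' in each sample. Probes without a gene mapping are dropped and their
#' count reported.
#'
#' @param intensity An `expr_matrix` with platform
#'   `"microarray-intensity"` (rownames = probe ids), or a plain matrix.
#' @param probe_to_gene Data frame with columns `probe`, `gene`.
#' @return An `expr_matrix` of per-gene mean intensities.
#' @export
collapse_probes <- function(intensity, probe_to_gene) {
  m <- if (inherits(intensity, "expr_matrix")) intensity$values else
    as.matrix(intensity)
  stopifnot(all(c("probe", "gene") %in% names(probe_to_gene)))
  gene <- probe_to_gene$gene[match(rownames(m), probe_to_gene$probe)]
  unmapped <- sum(is.na(gene) | !nzchar(gene))
  if (unmapped > 0L)
    message(sprintf("collapse_probes: %d unmapped probe(s) dropped", unmapped))
  keep <- !is.na(gene) & nzchar(gene)
  if (!any(keep)) stop("no probe maps to a gene")
  m <- m[keep, , drop = FALSE]
  gene <- gene[keep]
  collapsed <- rowsum(m, group = gene) / as.vector(table(gene)[sort(unique(gene))])
  expr_matrix(collapsed, platform = "microarray-intensity")
}
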