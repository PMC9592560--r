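# Pseudobulk aggregation and cell-type specificity classification used to
# restrict stem-cell signatures to genes of predominantly epithelial origin.

#' Aggregate single-cell counts into (cell type, patient) pseudobulk
#'
#' Sums raw counts over all cells sharing a cell-type label and a patient
#' label. Empty groups are never emitted; the number of cells behind each
#' pseudobulk column is recorded.
#'
#' @param counts Gene x cell count matrix (dense or `Matrix` sparse),
#'   non-negative; rownames are gene identifiers.
#' @param cell_type Character vector, one label per cell.
#' @param patient Character vector, one label per cell.
#' @return A `pseudobulk` object: list with `counts` (gene x group integer
#'   matrix), `cell_type`, `patient`, `n_cells` (per column).
#' @export
pseudobulk_aggregate <- function(counts, cell_type, patient) {
  n_cells <- ncol(counts)
  if (length(cell_type) != n_cells || length(patient) != n_cells)
    stop("cell_type and patient must have one label per cell")
  bad <- which(is.na(cell_type) | is.na(patient) |
                 !nzchar(as.character(cell_type)) |
                 !nzchar(as.character(patient)))
  if (length(bad))
    stop("cells with missing labels: ",
         paste(utils::head(bad, 20L), collapse = ", "))
  if (min(counts) < 0) stop("counts must be non-negative")
  grp <- factor(paste(cell_type, patient, sep = "||"))
  # group-indicator crossproduct does the summation in one sparse product
  ind <- Matrix::sparseMatrix(i = seq_len(n_cells),
                              j = as.integer(grp),
                              x = 1, dims = c(n_cells, nlevels(grp)))
  pb <- as.matrix(counts %*% ind)
  lev <- do.call(rbind, strsplit(levels(grp), "||", fixed = TRUE))
  colnames(pb) <- paste(lev[, 1], lev[, 2], sep = ".")
  rownames(pb) <- rownames(counts)
  structure(list(counts = pb,
                 cell_type = lev[, 1],
                 patient = lev[, 2],
                 n_cells = as.integer(table(grp)[levels(grp)])),
            class = "pseudobulk")
}

#' @exportS3Method base::print
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %d genes x %d (cell type, patient) groups; %d cell types, %d patients\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_type)), length(unique(x$patient))))
  invisible(x)
}

#' Specificity-test parameters
#'
#' Houses the constants of the specificity rule: a gene is specific to a
#' cell type when its pseudobulk expression is higher there than in every
#' other cell type by at least `margin` raw counts and every pairwise
#' comparison is significant at `alpha`.
#'
#' @param alpha Significance threshold for each pairwise test (default 0.01).
#' @param margin Raw-count margin on total pseudobulk counts (default 1).
#' @param test Pairwise test variant; only `"welch"` (two-sided
#'   unequal-variance t-test on log1p counts-per-million of per-patient
#'   pseudobulk replicates) is implemented.
#' @return A `specificity_params` list.
#' @export
specificity_params <- function(alpha = 0.01, margin = 1, test = "welch") {
  stopifnot(alpha > 0, alpha < 1, margin >= 0, test == "welch")
  structure(list(alpha = alpha, margin = margin, test = test),
            class = "specificity_params")
}

welch_p <- function(x, y) {
  # two-sided Welch p with a deterministic degenerate branch: zero variance
  # in both groups gives p = 1 for equal means and p = 0 otherwise
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
           error = function(e) if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
}

#' Classify genes by cell-type specificity of pseudobulk expression
#'
#' A gene is `specific-to:<c>` iff (a) its total pseudobulk count (summed
#' over patients) in cell type `c` exceeds that of every other cell type by
#' at least `params$margin` (and strictly), and (b) every pairwise Welch
#' t-test of `c` versus each rival on log1p counts-per-million across
#' per-patient pseudobulk replicates has p below `params$alpha`. Otherwise
#' `non-specific`. Deterministic given its inputs.
#'
#' @param pb A [pseudobulk_aggregate()] result with >= 2 cell types and
#'   >= 2 patients per cell type.
#' @param params A [specificity_params()] list.
#' @return Data frame with one row per gene: `gene`, `class`, `margin`
#'   (minimum total-count difference over rivals of the best cell type),
#'   `max_p` (largest pairwise p-value for that cell type).
#' @export
classify_specificity <- function(pb, params = specificity_params()) {
  stopifnot(inherits(pb, "pseudobulk"))
  types <- unique(pb$cell_type)
  if (length(types) < 2L) stop("need >= 2 cell types")
  per_type_pat <- table(pb$cell_type)
  if (any(per_type_pat < 2L))
    stop("every cell type needs >= 2 patient replicates for the pairwise ",
         "test; relax by pooling patients or dropping cell types with one")
  counts <- pb$counts
  libsize <- colSums(counts)
  logcpm <- log1p(sweep(counts, 2, libsize / 1e6, "/"))
  totals <- vapply(types, function(tp)
    rowSums(counts[, pb$cell_type == tp, drop = FALSE]), numeric(nrow(counts)))
  cols_of <- lapply(types, function(tp) which(pb$cell_type == tp))
  names(cols_of) <- types

  n_genes <- nrow(counts)
  cls <- rep("non-specific", n_genes)
  marg <- rep(NA_real_, n_genes)
  maxp <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    best <- which.max(totals[g, ])        # only the top type can win
    rivals <- setdiff(seq_along(types), best)
    diffs <- totals[g, best] - totals[g, rivals]
    marg[g] <- min(diffs)
    if (!(all(diffs >= params$margin) && all(diffs > 0))) next
    ps <- vapply(rivals, function(r)
      welch_p(logcpm[g, cols_of[[best]]], logcpm[g, cols_of[[r]]]),
      numeric(1))
    maxp[g] <- max(ps)
    if (maxp[g] < params$alpha)
      cls[g] <- paste0("specific-to:", types[best])
  }
  data.frame(gene = rownames(counts), class = cls, margin = marg,
             max_p = maxp, stringsAsFactors = FALSE)
}

#' Refine a signature by cell-type expression clustering
#'
#' Restricts a signature to genes of predominantly epithelial origin:
#' computes a per-cell-type mean log2-CPM profile for every signature gene,
#' converts each profile to a moderated z-score, hierarchically clusters
#' the profiles (Euclidean distance, average linkage), labels each cluster
#' by its centroid, and drops clusters that are stromal-dominant,
#' epithelial with high stromal expression, or flat (no clear
#' cell-type-specific expression). Retained genes are returned in input
#' order.
#'
#' @param sig A [gene_signature]; genes absent from `pb` are dropped with a
#'   warning (and a warning when < 80\% of the signature is found).
#' @param pb A [pseudobulk_aggregate()] result.
#' @param k Number of clusters; default `min(8, floor(n_genes / 5))`,
#'   at least 2.
#' @param stromal_z Centroid stromal z-score above which an
#'   epithelial-labelled cluster is excluded (default 0.5).
#' @param flat_z Centroid maximum z-score below which a cluster is
#'   considered flat and excluded (default 0.5).
#' @param epithelial_type,stromal_types Cell-type labels interpreted as
#'   epithelial and stromal.
#' @return A [gene_signature] containing the retained genes. All genes
#'   excluded yields a zero-length signature list (returned unclassed, with
#'   a warning) — see Details.
#' @details When every cluster is excluded the result cannot satisfy the
#'   >= 2 gene invariant of `gene_signature`; an empty character vector of
#'   genes is returned inside an unclassed list with a warning so callers
#'   can detect the degenerate outcome.
#' @export
refine_signature <- function(sig, pb, k = NULL, stromal_z = 0.5,
                             flat_z = 0.5,
                             epithelial_type = "epithelial",
                             stromal_types = c("stroma", "stromal",
                                               "endothelial")) {
  stopifnot(inherits(sig, "gene_signature"), inherits(pb, "pseudobulk"))
  genes <- sig$genes[sig$genes %in% rownames(pb$counts)]
  n_missing <- length(sig$genes) - length(genes)
  if (n_missing > 0L)
    warning(sprintf("refine_signature: %d/%d signature gene(s) absent from pseudobulk",
                    n_missing, length(sig$genes)))
  if (length(genes) < 0.8 * length(sig$genes))
    warning("refine_signature: < 80% of the signature found in the pseudobulk matrix")
  if (length(genes) < 3L)
    stop("refine_signature: fewer than 3 signature genes found; clustering degenerate")

  counts <- pb$counts
  logcpm <- log2(sweep(counts, 2, colSums(counts) / 1e6, "/") + 1)
  types <- sort(unique(pb$cell_type))
  prof <- vapply(types, function(tp)
    rowMeans(logcpm[genes, pb$cell_type == tp, drop = FALSE]),
    numeric(length(genes)))
  rownames(prof) <- genes
  mu <- rowMeans(prof)
  sdv <- apply(prof, 1, stats::sd)
  # moderated z: the median per-gene sd regularizes the denominator so that
  # genes with negligible absolute variation across cell types cannot be
  # inflated into sharp profiles by z-scoring alone
  s0 <- stats::median(sdv)
  denom <- sdv + s0
  denom[denom == 0] <- 1
  z <- (prof - mu) / denom

  if (is.null(k)) k <- min(8L, floor(length(genes) / 5))
  k <- max(2L, min(as.integer(k), length(genes)))
  # Euclidean distance on the moderated-z profiles: shape and magnitude
  # both count, so low-variation genes gather near the origin instead of
  # being absorbed into sharp-profile clusters by chance shape alignment
  hc <- stats::hclust(stats::dist(z), method = "average")
  cl <- stats::cutree(hc, k = k)

  keep <- logical(length(genes))
  for (ci in unique(cl)) {
    centroid <- colMeans(z[cl == ci, , drop = FALSE])
    top <- types[which.max(centroid)]
    s_z <- if (any(types %in% stromal_types))
      max(centroid[types %in% stromal_types]) else -Inf
    flat <- max(centroid) < flat_z
    stromal_dom <- top %in% stromal_types
    epi_high_stromal <- identical(top, epithelial_type) && s_z > stromal_z
    keep[cl == ci] <- !(flat || stromal_dom || epi_high_stromal)
  }
  retained <- genes[keep]
  retained <- sig$genes[sig$genes %in% retained]   # input order
  if (length(retained) < 2L) {
    warning("refine_signature: all clusters excluded; returning empty gene set")
    return(list(name = sig$name, genes = character(0), species = sig$species,
                provenance = paste0(sig$provenance, " [refined: empty]")))
  }
  gene_signature(sig$name, retained, species = sig$species,
                 provenance = paste0(sig$provenance,
                                     " [refined by cell-type specificity]"))
}
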