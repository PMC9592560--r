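#' Construct a gene signature
#'
#' A gene signature is a named, ordered set of unique gene identifiers with
#' provenance metadata. The two built-in roles in this package are the
#' crypt-base columnar (CBC, LGR5-type) and regenerative stem cell (RSC,
#' ANXA1/CLU/PLAUR-type) signatures, but any signature can be scored.
#'
#' @param name Short, non-empty label (e.g. `"RSC"`).
#' @param genes Character vector of gene identifiers; duplicates are
#'   collapsed (first occurrence kept) with a warning; at least 2 unique
#'   genes required.
#' @param species `"human"` or `"mouse"`.
#' @param provenance Free-text origin note.
#' @return An object of class `gene_signature`: a list with fields `name`,
#'   `genes`, `species`, `provenance`.
#' @export
gene_signature <- function(name, genes, species = c("human", "mouse"),
                           provenance = "") {
  species <- match.arg(species)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes)) {
    warning(sprintf("signature '%s': %d duplicate gene(s) collapsed",
                    name, sum(duplicated(genes))))
    genes <- genes[!duplicated(genes)]
  }
  if (length(genes) < 2L)
    stop(sprintf("signature '%s' needs >= 2 unique genes", name))
  structure(list(name = name, genes = genes, species = species,
                 provenance = provenance),
            class = "gene_signature")
}

#' @exportS3Method base::print
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s (%s): %d genes\n", x$name, x$species,
              length(x$genes)))
  cat("  ", paste(utils::head(x$genes, 8L), collapse = ", "),
      if (length(x$genes) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' GMT dialect: one signature per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' required but ignored; trailing empty fields are tolerated; duplicate
#' genes within a line are collapsed with a warning.
#'
#' @param path Path to a GMT file.
#' @param species Species tag attached to every parsed signature.
#' @return List of [gene_signature] objects in file order, named by
#'   signature name.
#' @export
read_gmt <- function(path, species = c("human", "mouse")) {
  species <- match.arg(species)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[!(seq_along(fields) > 2L & !nzchar(fields))]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)))
    sigs[[i]] <- gene_signature(fields[[1]], fields[-(1:2)],
                                species = species,
                                provenance = fields[[2]])
  }
  names(sigs) <- vapply(sigs, `[[`, character(1), "name")
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param sigs A `gene_signature` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path) {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  lines <- vapply(sigs, function(s) {
    paste(c(s$name, if (nzchar(s$provenance)) s$provenance else "na",
            s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Map a signature across species via an ortholog table
#'
#' Replaces each gene by its ortholog in `table`; genes absent from the
#' table are dropped and their count reported; the result is deduplicated
#' (two source genes mapping onto one ortholog collapse to a single entry).
#'
#' @param sig A [gene_signature].
#' @param table Data frame with columns `mouse_gene`, `human_gene` (an
#'   optional `confidence` column is ignored here; supply a pre-filtered
#'   high-confidence table).
#' @param target_species `"human"` or `"mouse"`; must differ from
#'   `sig$species`.
#' @return A [gene_signature] in the target species.
#' @export
map_orthologs <- function(sig, table, target_species = c("human", "mouse")) {
  target_species <- match.arg(target_species)
  stopifnot(inherits(sig, "gene_signature"),
            all(c("mouse_gene", "human_gene") %in% names(table)))
  if (sig$species == target_species)
    stop("signature is already in species '", target_species, "'")
  from <- if (target_species == "human") "mouse_gene" else "human_gene"
  to   <- if (target_species == "human") "human_gene" else "mouse_gene"
  key <- as.character(table[[from]])
  val <- as.character(table[[to]])
  ok <- nzchar(key) & nzchar(val)
  key <- key[ok]; val <- val[ok]
  idx <- match(sig$genes, key)
  n_drop <- sum(is.na(idx))
  if (n_drop > 0L)
    message(sprintf("map_orthologs: %d/%d gene(s) without an ortholog dropped",
                    n_drop, length(sig$genes)))
  mapped <- unique(val[idx[!is.na(idx)]])
  if (length(mapped) < 2L)
    stop("ortholog mapping left fewer than 2 genes for signature '",
         sig$name, "'")
  gene_signature(sig$name, mapped, species = target_species,
                 provenance = paste0(sig$provenance, " [ortholog-mapped from ",
                                     sig$species, "]"))
}
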