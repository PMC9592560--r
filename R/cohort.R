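# Cohort-level analytics: polarized deciles, CNV categorization, pathway
# mutation prevalence, therapy-response plasticity, and multiregional-biopsy
# reproducibility statistics.

#' Segregate the most polarized deciles of a cohort
#'
#' Ranks samples by stem cell index; the lowest 10\% form the CBC-enriched
#' decile, the highest 10\% the RSC-enriched decile, the rest are middle.
#' Ties on the index are broken by CBC score (descending) then sample id.
#' An above-median predominance label (which of the two raw scores sits
#' above its cohort median) is reported alongside for plotting.
#'
#' @param results Data frame from [stem_cell_index()] (needs `sample_id`,
#'   `cbc_score`, `rsc_score`, `stem_cell_index`); n >= 10.
#' @param prop Fraction per tail (default 0.10).
#' @return `results` with added `decile` factor (`CBC-enriched`, `middle`,
#'   `RSC-enriched`) and `predominance` character.
#' @export
polarized_deciles <- function(results, prop = 0.10) {
  need <- c("sample_id", "cbc_score", "rsc_score", "stem_cell_index")
  stopifnot(all(need %in% names(results)))
  n <- nrow(results)
  if (n < 10L) stop("polarized deciles need n >= 10 samples")
  k <- round(prop * n)
  ord <- order(results$stem_cell_index, -results$cbc_score,
               results$sample_id)
  decile <- rep("middle", n)
  decile[ord[seq_len(k)]] <- "CBC-enriched"
  decile[ord[seq.int(n - k + 1L, n)]] <- "RSC-enriched"
  results$decile <- factor(decile,
                           levels = c("CBC-enriched", "middle", "RSC-enriched"))
  rsc_above <- results$rsc_score > stats::median(results$rsc_score)
  cbc_above <- results$cbc_score > stats::median(results$cbc_score)
  results$predominance <- ifelse(rsc_above & !cbc_above, "RSC",
                                 ifelse(cbc_above & !rsc_above, "CBC",
                                        "ambiguous"))
  results
}

#' Categorize copy-number segment means into gains and losses
#'
#' Values below `-threshold` are losses (-1), values above `threshold`
#' gains (+1), everything else neutral (0); both inequalities strict.
#'
#' @param segments Data frame with columns `sample`, `id`, `mean_value`.
#' @param threshold Gain/loss threshold on the segment-mean scale
#'   (default 0.3).
#' @return `segments` with an added integer `category` in \{-1, 0, 1\}.
#' @export
categorize_cnv <- function(segments, threshold = 0.3) {
  stopifnot(all(c("sample", "id", "mean_value") %in% names(segments)),
            threshold > 0)
  v <- segments$mean_value
  if (!all(is.finite(v))) stop("non-finite CNV values")
  segments$category <- ifelse(v < -threshold, -1L,
                              ifelse(v > threshold, 1L, 0L))
  segments
}

#' Per-decile gain/loss frequency table
#'
#' @param cnv Output of [categorize_cnv()].
#' @param deciles Output of [polarized_deciles()] (matched on
#'   `sample_id` = `sample`).
#' @return Data frame: `decile`, `id`, `gain_freq`, `loss_freq` (fractions
#'   of decile samples with category +1 / -1 for that segment).
#' @export
cnv_decile_frequencies <- function(cnv, deciles) {
  dec <- deciles$decile[match(cnv$sample, deciles$sample_id)]
  if (anyNA(dec)) stop("CNV samples missing from the decile assignment: ",
                       paste(utils::head(unique(cnv$sample[is.na(dec)]), 5L),
                             collapse = ", "))
  agg <- stats::aggregate(cbind(gain = cnv$category == 1L,
                                loss = cnv$category == -1L),
                          by = list(decile = dec, id = cnv$id), FUN = mean)
  names(agg)[3:4] <- c("gain_freq", "loss_freq")
  agg[order(agg$decile, agg$id), , drop = FALSE]
}

#' Pathway-level pathogenic mutation prevalence per decile
#'
#' For each pathway and decile, the fraction of samples carrying at least
#' one pathogenic mutation in any pathway gene. The mutation table is
#' expected to be pre-filtered for pathogenicity upstream.
#'
#' @param mutations Data frame with `sample`, `gene`, `pathogenic`
#'   (logical).
#' @param pathways Named list of gene-id character vectors (or
#'   `gene_signature` objects).
#' @param deciles Output of [polarized_deciles()].
#' @return Data frame: `pathway`, `decile`, `n_samples`, `n_mutated`,
#'   `prevalence` (fraction in \[0, 1\]).
#' @export
pathway_prevalence <- function(mutations, pathways, deciles) {
  stopifnot(all(c("sample", "gene", "pathogenic") %in% names(mutations)))
  pathways <- lapply(pathways, function(p)
    if (inherits(p, "gene_signature")) p$genes else as.character(p))
  mut <- mutations[as.logical(mutations$pathogenic), , drop = FALSE]
  out <- list()
  for (pw in names(pathways)) {
    genes <- pathways[[pw]]
    if (length(genes) == 0L || !any(genes %in% mut$gene))
      warning(sprintf("pathway '%s': no gene present in the mutation table", pw))
    hit_samples <- unique(mut$sample[mut$gene %in% genes])
    for (d in levels(deciles$decile)) {
      samp <- deciles$sample_id[deciles$decile == d]
      n_mut <- sum(samp %in% hit_samples)
      out[[length(out) + 1L]] <- data.frame(
        pathway = pw, decile = d, n_samples = length(samp),
        n_mutated = n_mut,
        prevalence = if (length(samp)) n_mut / length(samp) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Classify paired pre/post tumors as static or plastic
#'
#' A sample is RSC-positive when its stem cell index is positive and
#' CBC-positive otherwise (an exactly-zero index counts as CBC-positive:
#' "positive index" is read strictly). A patient is `plastic` when the
#' pre- and post-treatment classes differ, `static` otherwise.
#'
#' @param pairs Data frame with `patient`, `pre_index`, `post_index`
#'   (exactly one row per patient, no missing values).
#' @return Data frame: `patient`, `pre_index`, `post_index`, `pre_class`,
#'   `post_class` (`RSC-positive`/`CBC-positive`), `group`
#'   (`static`/`plastic`).
#' @export
classify_plasticity <- function(pairs) {
  stopifnot(all(c("patient", "pre_index", "post_index") %in% names(pairs)))
  if (anyDuplicated(pairs$patient))
    stop("duplicate patients: ",
         paste(unique(pairs$patient[duplicated(pairs$patient)]), collapse = ", "))
  miss <- pairs$patient[!is.finite(pairs$pre_index) | !is.finite(pairs$post_index)]
  if (length(miss))
    stop("patients with a missing pair member: ", paste(miss, collapse = ", "))
  cls <- function(idx) ifelse(idx > 0, "RSC-positive", "CBC-positive")
  pairs$pre_class <- cls(pairs$pre_index)
  pairs$post_class <- cls(pairs$post_index)
  pairs$group <- factor(ifelse(pairs$pre_class == pairs$post_class,
                               "static", "plastic"),
                        levels = c("static", "plastic"))
  pairs
}

#' Responder flag from histological regression grade
#'
#' Marked or moderate regression counts as response; none or mild does not.
#'
#' @param grades Character vector with values among `none`, `mild`,
#'   `moderate`, `marked`.
#' @return Logical responder flags.
#' @export
responder_flag <- function(grades) {
  ok <- c("none", "mild", "moderate", "marked")
  if (!all(grades %in% ok))
    stop("unknown regression grade(s): ",
         paste(unique(setdiff(grades, ok)), collapse = ", "))
  grades %in% c("moderate", "marked")
}

#' Fisher exact association of plasticity group with therapy response
#'
#' Builds the 2x2 static/plastic x responder/non-responder table and
#' returns the two-sided Fisher exact p-value (sum of hypergeometric
#' probabilities no larger than the observed table's) plus the sample odds
#' ratio (Haldane 0.5 correction when any cell is zero).
#'
#' @param calls Output of [classify_plasticity()].
#' @param labels Data frame with `patient` and either a logical
#'   `responder` column or a `grade` column (see [responder_flag()]).
#' @return List with `table` (2x2), `p_value`, `odds_ratio`.
#' @export
fisher_association <- function(calls, labels) {
  if (!"responder" %in% names(labels)) {
    if (!"grade" %in% names(labels))
      stop("labels need a 'responder' or 'grade' column")
    labels$responder <- responder_flag(labels$grade)
  }
  idx <- match(calls$patient, labels$patient)
  if (anyNA(idx))
    stop("patients without a response label: ",
         paste(calls$patient[is.na(idx)], collapse = ", "))
  resp <- factor(ifelse(labels$responder[idx], "responder", "non-responder"),
                 levels = c("responder", "non-responder"))
  tab <- table(group = calls$group, response = resp)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin in the 2x2 table; p = 1")
    p <- 1
  } else {
    p <- stats::fisher.test(tab)$p.value
  }
  t2 <- tab + if (any(tab == 0)) 0.5 else 0
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(table = tab, p_value = p, odds_ratio = unname(or))
}

#' Multiregional-biopsy reproducibility statistics
#'
#' One-way random-effects variance decomposition of an index measured on
#' multiple biopsies per tumor: between- and within-tumor mean squares
#' with the unbalanced-design coefficient k0, variance components
#' truncated at zero, ICC(1,1) = between / (between + within), and
#' within-/between-subject coefficients of variation as percentages of
#' the absolute grand mean.
#'
#' @param biopsies Data frame with `tumor`, `biopsy`, `index`; >= 2
#'   tumors, at least one tumor with >= 2 biopsies.
#' @param mean_tol Grand means smaller than this in absolute value make
#'   the CVs undefined (returned `NA` with a warning); ICC is always
#'   returned.
#' @return List with `icc`, `within_cv`, `between_cv`, `sigma2_between`,
#'   `sigma2_within`, `grand_mean`, `n_tumors`, `n_biopsies`.
#' @export
repro_stats <- function(biopsies, mean_tol = 1e-8) {
  stopifnot(all(c("tumor", "biopsy", "index") %in% names(biopsies)))
  y <- biopsies$index
  g <- factor(biopsies$tumor)
  a <- nlevels(g)
  if (a < 2L) stop("need >= 2 tumors")
  n_i <- as.vector(table(g))
  if (all(n_i < 2L)) stop("need >= 2 biopsies for at least one tumor")
  N <- length(y)
  gm <- mean(y)
  mean_i <- tapply(y, g, mean)
  msb <- sum(n_i * (mean_i - gm)^2) / (a - 1)
  msw <- sum((y - mean_i[g])^2) / (N - a)
  k0 <- (N - sum(n_i^2) / N) / (a - 1)
  s2b <- max(0, (msb - msw) / k0)
  s2w <- msw
  if (s2b + s2w == 0) {
    warning("zero total variance; ICC undefined, returning 0")
    icc <- 0
  } else icc <- s2b / (s2b + s2w)
  if (abs(gm) < mean_tol) {
    warning("grand mean ~ 0; coefficients of variation undefined")
    wcv <- bcv <- NA_real_
  } else {
    wcv <- 100 * sqrt(s2w) / abs(gm)
    bcv <- 100 * sqrt(s2b) / abs(gm)
  }
  list(icc = icc, within_cv = wcv, between_cv = bcv,
       sigma2_between = s2b, sigma2_within = s2w,
       grand_mean = gm, n_tumors = a, n_biopsies = N)
}
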