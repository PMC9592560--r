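# Synthetic-data generators with stored ground truth. Every generator is
# deterministic under its seed argument (local RNG state, restored on exit)
# and returns the truth tables needed to score downstream recovery.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Bulk cohort simulation configuration
#'
#' Samples are mixtures of a CBC archetype and an RSC archetype expression
#' profile plus optional non-epithelial (stromal) contamination; counts are
#' negative binomial around the mixture expectation.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param block_size Genes per planted archetype block (CBC, RSC, stromal;
#'   disjoint).
#' @param effect log2 fold change of block genes over baseline in their
#'   archetype (default 2).
#' @param dispersion Negative-binomial dispersion (default 0.2).
#' @param contamination Per-sample non-epithelial contamination fraction in
#'   \[0, 1): either a scalar or one value per sample.
#' @param rsc_fraction Optional per-sample RSC mixing fraction in \[0, 1\];
#'   default draws uniformly.
#' @param lib_size Range (min, max) of library sizes.
#' @return A `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_samples = 100, n_genes = 2000, block_size = 50,
                            effect = 2.0, dispersion = 0.2,
                            contamination = 0, rsc_fraction = NULL,
                            lib_size = c(5e5, 1e6)) {
  stopifnot(3 * block_size <= n_genes, effect >= 0, dispersion > 0,
            all(contamination >= 0), all(contamination < 1))
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 block_size = block_size, effect = effect,
                 dispersion = dispersion, contamination = contamination,
                 rsc_fraction = rsc_fraction, lib_size = lib_size),
            class = "bulk_sim_config")
}

#' Simulate a bulk RNA-seq cohort with a planted stem-cell phenotype axis
#'
#' Per sample, the expected expression is
#' `(1 - c) * ((1 - f) * CBC_archetype + f * RSC_archetype) + c * stromal`,
#' where `f` is the planted RSC mixing fraction and `c` the contamination
#' fraction; counts are negative binomial at the configured dispersion.
#'
#' @param cfg [bulk_sim_config()].
#' @param seed Integer seed; same seed, same matrix.
#' @return List: `expr` (an `expr_matrix` of counts), `truth` (data frame
#'   `sample_id`, `rsc_fraction`, `contamination`), `cbc_sig`, `rsc_sig`
#'   (the planted block signatures), `stromal_genes`, and `archetypes`
#'   (the design expectation profiles, for closed-form checks).
#' @export
simulate_bulk <- function(cfg = bulk_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  with_seed(seed, {
    p <- cfg$n_genes
    genes <- sprintf("G%04d", seq_len(p))
    bs <- cfg$block_size
    cbc_idx <- seq_len(bs)
    rsc_idx <- bs + seq_len(bs)
    str_idx <- 2 * bs + seq_len(bs)
    base <- stats::rlnorm(p, meanlog = log(5), sdlog = 1)
    up <- 2^cfg$effect
    cbc_arch <- base; cbc_arch[cbc_idx] <- cbc_arch[cbc_idx] * up
    rsc_arch <- base; rsc_arch[rsc_idx] <- rsc_arch[rsc_idx] * up
    stromal <- base; stromal[str_idx] <- stromal[str_idx] * up

    n <- cfg$n_samples
    f <- cfg$rsc_fraction %||% stats::runif(n)
    stopifnot(length(f) == n, all(f >= 0), all(f <= 1))
    cc <- rep_len(cfg$contamination, n)
    L <- stats::runif(n, cfg$lib_size[1], cfg$lib_size[2])

    counts <- matrix(0L, p, n, dimnames = list(genes,
                                               sprintf("S%03d", seq_len(n))))
    for (j in seq_len(n)) {
      mu <- (1 - cc[j]) * ((1 - f[j]) * cbc_arch + f[j] * rsc_arch) +
        cc[j] * stromal
      mu <- L[j] * mu / sum(mu)
      counts[, j] <- stats::rnbinom(p, mu = mu, size = 1 / cfg$dispersion)
    }
    list(expr = expr_matrix(counts, "rnaseq-counts"),
         truth = data.frame(sample_id = colnames(counts), rsc_fraction = f,
                            contamination = cc, stringsAsFactors = FALSE),
         cbc_sig = gene_signature("CBC", genes[cbc_idx],
                                  provenance = "synthetic planted block"),
         rsc_sig = gene_signature("RSC", genes[rsc_idx],
                                  provenance = "synthetic planted block"),
         stromal_genes = genes[str_idx],
         archetypes = list(cbc = stats::setNames(cbc_arch, genes),
                           rsc = stats::setNames(rsc_arch, genes),
                           stromal = stats::setNames(stromal, genes)))
  })
}

#' Single-cell simulation configuration
#'
#' Seven planted populations (CBC, RSC, double-positive mixed, non-stem
#' epithelial, stromal, myeloid, lymphoid) with per-patient structure, UMI
#' depth and mitochondrial-fraction distributions, marker-gene blocks with
#' stated effects, and a planted fraction of low-quality cells.
#'
#' @param n_patients,cells_per_patient Cohort dimensions.
#' @param proportions Named population proportions; must sum to 1.
#' @param n_genes Total genes (marker blocks carved from the front).
#' @param marker_effect log2 fold change of marker-block genes in their
#'   population (default 3).
#' @param block_size Genes per cell-type block (epithelial, stromal,
#'   myeloid, lymphoid).
#' @param stem_block_size Genes per CBC / RSC marker block.
#' @param depth_meanlog,depth_sdlog Log-normal UMI depth parameters.
#' @param mito_mean Mean mitochondrial fraction of healthy cells.
#' @param lowq_fraction Planted fraction of low-quality cells (half get a
#'   high mitochondrial fraction, half a collapsed depth).
#' @param patient_effect_sd sdlog of the per-patient gene-wise expression
#'   factor.
#' @return An `sc_sim_config` list.
#' @export
sc_sim_config <- function(n_patients = 5, cells_per_patient = 400,
                          proportions = c(CBC = 0.05, RSC = 0.05,
                                          mixed = 0.01,
                                          other_epithelial = 0.59,
                                          stromal = 0.15, myeloid = 0.10,
                                          lymphoid = 0.05),
                          n_genes = 4000, marker_effect = 3.0,
                          block_size = 80, stem_block_size = 40,
                          depth_meanlog = log(12000), depth_sdlog = 0.12,
                          mito_mean = 0.05, lowq_fraction = 0.05,
                          patient_effect_sd = 0.1) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            all(c("CBC", "RSC", "mixed", "other_epithelial", "stromal",
                  "myeloid", "lymphoid") %in% names(proportions)),
            4 * block_size + 2 * stem_block_size + 13 < n_genes,
            lowq_fraction >= 0, lowq_fraction < 1)
  structure(list(n_patients = n_patients,
                 cells_per_patient = cells_per_patient,
                 proportions = proportions, n_genes = n_genes,
                 marker_effect = marker_effect, block_size = block_size,
                 stem_block_size = stem_block_size,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 mito_mean = mito_mean, lowq_fraction = lowq_fraction,
                 patient_effect_sd = patient_effect_sd),
            class = "sc_sim_config")
}

#' Simulate a single-cell cohort with planted populations
#'
#' Cells are multinomial draws at a population-specific expression program:
#' each population elevates its marker block(s) by `marker_effect` log2
#' units; block baseline masses are equalized so cross-population
#' library-composition tilts stay small; mitochondrial genes (prefix
#' `MT-`) receive each cell's drawn mitochondrial share.
#'
#' @param cfg [sc_sim_config()].
#' @param seed Integer seed.
#' @return List: `counts` (gene x cell integer matrix), `cells` (truth:
#'   `barcode`, `patient`, `population`, `cell_type`, `lowq`), `genes`
#'   (truth: `gene`, `block`).
#' @export
simulate_single_cell <- function(cfg = sc_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  with_seed(seed, {
    p <- cfg$n_genes
    bs <- cfg$block_size; ss <- cfg$stem_block_size
    blocks <- list(epithelial = seq_len(bs),
                   stromal_block = bs + seq_len(bs),
                   myeloid_block = 2 * bs + seq_len(bs),
                   lymphoid_block = 3 * bs + seq_len(bs),
                   cbc_marker = 4 * bs + seq_len(ss),
                   rsc_marker = 4 * bs + ss + seq_len(ss))
    n_mito <- 13L
    mito_idx <- (4 * bs + 2 * ss) + seq_len(n_mito)
    genes <- sprintf("G%04d", seq_len(p))
    genes[mito_idx] <- sprintf("MT-%02d", seq_len(n_mito))
    block_lab <- rep("background", p)
    for (b in names(blocks)) block_lab[blocks[[b]]] <- b
    block_lab[mito_idx] <- "mito"

    base <- stats::rlnorm(p, 0, 1)
    # equalize block masses: per-gene mean inside each block matches the
    # lognormal mean, so no block dominates a library by construction
    for (b in names(blocks)) {
      idx <- blocks[[b]]
      base[idx] <- base[idx] / sum(base[idx]) * length(idx) * exp(0.5)
    }
    up <- 2^cfg$marker_effect
    prog <- list(
      CBC = c("epithelial", "cbc_marker"),
      RSC = c("epithelial", "rsc_marker"),
      mixed = c("epithelial", "cbc_marker", "rsc_marker"),
      other_epithelial = "epithelial",
      stromal = "stromal_block",
      myeloid = "myeloid_block",
      lymphoid = "lymphoid_block")
    coarse <- c(CBC = "epithelial", RSC = "epithelial", mixed = "epithelial",
                other_epithelial = "epithelial", stromal = "stroma",
                myeloid = "myeloid", lymphoid = "lymphocytes")

    n_cells <- cfg$n_patients * cfg$cells_per_patient
    pop <- character(n_cells); pat <- character(n_cells)
    counts <- matrix(0L, p, n_cells)
    lowq <- logical(n_cells)
    cell <- 0L
    for (pt in seq_len(cfg$n_patients)) {
      pat_eff <- stats::rlnorm(p, 0, cfg$patient_effect_sd)
      pops <- sample(names(cfg$proportions), cfg$cells_per_patient,
                     replace = TRUE, prob = cfg$proportions)
      for (ci in seq_len(cfg$cells_per_patient)) {
        cell <- cell + 1L
        pop[cell] <- pops[ci]
        pat[cell] <- sprintf("P%02d", pt)
        w <- base * pat_eff
        for (b in prog[[pops[ci]]]) w[blocks[[b]]] <- w[blocks[[b]]] * up
        lowq[cell] <- stats::runif(1) < cfg$lowq_fraction
        high_mito <- lowq[cell] && stats::runif(1) < 0.5
        m <- if (high_mito) stats::rbeta(1, 22, 18) else
          stats::rbeta(1, 4, 4 * (1 - cfg$mito_mean) / cfg$mito_mean)
        depth <- stats::rlnorm(1, cfg$depth_meanlog, cfg$depth_sdlog)
        if (lowq[cell] && !high_mito) depth <- depth * 0.06
        pr <- numeric(p)
        nm <- setdiff(seq_len(p), mito_idx)
        pr[nm] <- (1 - m) * w[nm] / sum(w[nm])
        pr[mito_idx] <- m * w[mito_idx] / sum(w[mito_idx])
        counts[, cell] <- stats::rmultinom(1, size = max(1L, round(depth)),
                                           prob = pr)
      }
    }
    dimnames(counts) <- list(genes, sprintf("C%05d", seq_len(n_cells)))
    list(counts = counts,
         cells = data.frame(barcode = colnames(counts), patient = pat,
                            population = pop,
                            cell_type = unname(coarse[pop]),
                            lowq = lowq, stringsAsFactors = FALSE),
         genes = data.frame(gene = genes, block = block_lab,
                            stringsAsFactors = FALSE))
  })
}

#' Paired pre/post therapy cohort simulation configuration
#'
#' @param n_patients Number of pre/post pairs (default 75).
#' @param fraction_plastic Planted fraction whose index sign flips.
#' @param index_mean Mean absolute index per timepoint.
#' @param noise_sd Gaussian noise on each index.
#' @param responder_rate_static,responder_rate_plastic Planted response
#'   rates per group.
#' @return A `paired_sim_config` list.
#' @export
paired_sim_config <- function(n_patients = 75, fraction_plastic = 0.3,
                              index_mean = 0.4, noise_sd = 0.05,
                              responder_rate_static = 0.6,
                              responder_rate_plastic = 0.2) {
  stopifnot(fraction_plastic >= 0, fraction_plastic <= 1, index_mean > 0,
            noise_sd >= 0)
  structure(list(n_patients = n_patients,
                 fraction_plastic = fraction_plastic,
                 index_mean = index_mean, noise_sd = noise_sd,
                 responder_rate_static = responder_rate_static,
                 responder_rate_plastic = responder_rate_plastic),
            class = "paired_sim_config")
}

#' Simulate paired pre/post stem cell indices with planted plasticity
#'
#' Static patients keep their index sign across treatment; plastic
#' patients flip it. Responder labels are drawn at the per-group rates and
#' expressed as histological regression grades.
#'
#' @param cfg [paired_sim_config()].
#' @param seed Integer seed.
#' @return List: `pairs` (`patient`, `pre_index`, `post_index`), `labels`
#'   (`patient`, `grade`, `responder`), `truth` (`patient`, `group`).
#' @export
simulate_paired <- function(cfg = paired_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "paired_sim_config"))
  with_seed(seed, {
    n <- cfg$n_patients
    plastic <- stats::runif(n) < cfg$fraction_plastic
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    draw <- function(s) s * abs(stats::rnorm(n, cfg$index_mean, cfg$noise_sd))
    pre <- draw(sgn)
    post <- draw(ifelse(plastic, -sgn, sgn))
    rate <- ifelse(plastic, cfg$responder_rate_plastic,
                   cfg$responder_rate_static)
    responder <- stats::runif(n) < rate
    grade <- ifelse(responder,
                    sample(c("moderate", "marked"), n, replace = TRUE),
                    sample(c("none", "mild"), n, replace = TRUE))
    id <- sprintf("PT%03d", seq_len(n))
    list(pairs = data.frame(patient = id, pre_index = pre, post_index = post,
                            stringsAsFactors = FALSE),
         labels = data.frame(patient = id, grade = grade,
                             responder = responder, stringsAsFactors = FALSE),
         truth = data.frame(patient = id,
                            group = ifelse(plastic, "plastic", "static"),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate CNV segments and pathway-annotated mutation tables
#'
#' Produces per-sample copy-number segment means and a pathogenic-flagged
#' mutation table with planted per-group rates, for exercising the decile
#' CNV and pathway-prevalence analytics against known truth.
#'
#' @param samples Character vector of sample ids.
#' @param group Factor/character of the same length assigning each sample
#'   to a rate group (e.g. the polarized decile).
#' @param segments Segment/region identifiers.
#' @param gain_rate,loss_rate Named per-group probabilities that a segment
#'   carries a gain (+1) or loss (-1); names must cover the groups.
#' @param pathways Named list of pathway gene sets.
#' @param mutation_rate Group x pathway matrix of probabilities that a
#'   sample carries at least one pathogenic mutation in the pathway.
#' @param seed Integer seed.
#' @return List: `cnv` (`sample`, `id`, `mean_value`), `mutations`
#'   (`sample`, `gene`, `pathogenic`), `truth` (the planted rates).
#' @export
simulate_genomics <- function(samples, group,
                              segments = paste0("chr", 1:8),
                              gain_rate, loss_rate, pathways, mutation_rate,
                              seed = 1) {
  group <- as.character(group)
  stopifnot(length(group) == length(samples),
            all(group %in% names(gain_rate)),
            all(group %in% names(loss_rate)),
            all(group %in% rownames(mutation_rate)),
            identical(colnames(mutation_rate), names(pathways)))
  with_seed(seed, {
    cnv <- expand.grid(sample = samples, id = segments,
                       stringsAsFactors = FALSE)
    g <- group[match(cnv$sample, samples)]
    u <- stats::runif(nrow(cnv))
    gr <- gain_rate[g]; lr <- loss_rate[g]
    cnv$mean_value <- ifelse(u < gr, stats::runif(nrow(cnv), 0.35, 1),
                             ifelse(u < gr + lr,
                                    stats::runif(nrow(cnv), -1, -0.35),
                                    stats::runif(nrow(cnv), -0.25, 0.25)))
    mut <- list()
    for (i in seq_along(samples)) {
      for (pw in names(pathways)) {
        if (stats::runif(1) < mutation_rate[group[i], pw]) {
          mut[[length(mut) + 1L]] <- data.frame(
            sample = samples[i],
            gene = sample(pathways[[pw]], 1),
            pathogenic = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    mutations <- if (length(mut)) do.call(rbind, mut) else
      data.frame(sample = character(0), gene = character(0),
                 pathogenic = logical(0))
    list(cnv = cnv, mutations = mutations,
         truth = list(gain_rate = gain_rate, loss_rate = loss_rate,
                      mutation_rate = mutation_rate))
  })
}

#' Simulate multiregional biopsies with a designed intraclass correlation
#'
#' Tumor effects are Normal(0, icc * sd^2), biopsy noise
#' Normal(0, (1 - icc) * sd^2); each biopsy value is the grand mean plus
#' both. Defaults emulate a multiregional-biopsy design whose
#' between-tumor spread dominates the within-tumor spread.
#'
#' @param n_tumors,biopsies_per_tumor Design dimensions.
#' @param icc_design Designed ICC in \[0, 1).
#' @param grand_mean,total_sd Location and total spread of the index.
#' @param seed Integer seed.
#' @return Data frame: `tumor`, `biopsy`, `index`.
#' @export
simulate_biopsies <- function(n_tumors = 30, biopsies_per_tumor = 5,
                              icc_design = 0.826, grand_mean = 1,
                              total_sd = 0.3, seed = 1) {
  stopifnot(icc_design >= 0, icc_design < 1, total_sd > 0)
  with_seed(seed, {
    tum <- stats::rnorm(n_tumors, 0, total_sd * sqrt(icc_design))
    out <- data.frame(
      tumor = rep(sprintf("T%02d", seq_len(n_tumors)),
                  each = biopsies_per_tumor),
      biopsy = rep(sprintf("B%d", seq_len(biopsies_per_tumor)), n_tumors),
      index = grand_mean + rep(tum, each = biopsies_per_tumor) +
        stats::rnorm(n_tumors * biopsies_per_tumor, 0,
                     total_sd * sqrt(1 - icc_design)),
      stringsAsFactors = FALSE)
    out
  })
}
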