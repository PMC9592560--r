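index_frame <- function(idx, cbc = NULL) {
  n <- length(idx)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             cbc_score = cbc %||% -idx / 2, rsc_score = idx / 2,
             stem_cell_index = idx, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("polarized deciles pick the extremes and swap under negation", {
  set.seed(2)
  idx <- sample(seq(-1, 1, length.out = 20))
  res <- polarized_deciles(index_frame(idx))
  expect_equal(sum(res$decile == "CBC-enriched"), 2)
  expect_equal(sum(res$decile == "RSC-enriched"), 2)
  expect_setequal(res$sample_id[res$decile == "CBC-enriched"],
                  res$sample_id[order(idx)][1:2])
  expect_setequal(res$sample_id[res$decile == "RSC-enriched"],
                  res$sample_id[order(idx)][19:20])

  neg <- polarized_deciles(index_frame(-idx))
  expect_setequal(neg$sample_id[neg$decile == "CBC-enriched"],
                  res$sample_id[res$decile == "RSC-enriched"])

  expect_error(polarized_deciles(index_frame(rnorm(9))), "n >= 10")
})

test_that("decile membership matches a full-sort oracle on 100 samples", {
  set.seed(3)
  idx <- rnorm(100)
  res <- polarized_deciles(index_frame(idx))
  ord <- order(idx)
  expect_setequal(which(res$decile == "CBC-enriched"), ord[1:10])
  expect_setequal(which(res$decile == "RSC-enriched"), ord[91:100])
  expect_equal(sum(res$decile == "middle"), 80)
})

test_that("CNV categorization uses strict +/-0.3 thresholds", {
  segs <- data.frame(sample = "s1", id = paste0("seg", 1:10),
                     mean_value = c(-0.31, -0.3, -0.29, 0, 0.29, 0.3, 0.31,
                                    1.2, -2, 0.05))
  out <- categorize_cnv(segs)
  expect_equal(out$category,
               c(-1L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, -1L, 0L))
  expect_error(categorize_cnv(transform(segs, mean_value = NaN)), "non-finite")
})

test_that("per-decile CNV frequencies count gains and losses per segment", {
  dec <- index_frame(c(-3, -2, 2, 3, 0, 0, 0, 0, 0.5, -0.5))
  dec <- polarized_deciles(dec)
  cnv <- data.frame(sample = rep(dec$sample_id, each = 2),
                    id = rep(c("segA", "segB"), 10),
                    mean_value = rep(c(0.5, -0.5), 10))
  freq <- cnv_decile_frequencies(categorize_cnv(cnv), dec)
  expect_true(all(freq$gain_freq[freq$id == "segA"] == 1))
  expect_true(all(freq$loss_freq[freq$id == "segB"] == 1))
})

test_that("pathway prevalence counts samples with any pathogenic hit", {
  dec <- polarized_deciles(index_frame(seq(-1, 1, length.out = 10)))
  cbc_dec <- dec$sample_id[dec$decile == "CBC-enriched"]
  mut <- data.frame(sample = c(cbc_dec[1], cbc_dec[1], "S005"),
                    gene = c("APC", "CTNNB1", "APC"),
                    pathogenic = c(TRUE, TRUE, FALSE))
  out <- pathway_prevalence(mut, list(Wnt = c("APC", "CTNNB1")), dec)
  wnt_cbc <- out[out$pathway == "Wnt" & out$decile == "CBC-enriched", ]
  expect_equal(wnt_cbc$prevalence, 1)  # the one CBC sample mutated counts once
  expect_equal(wnt_cbc$n_samples, 1)
  mid <- out[out$pathway == "Wnt" & out$decile == "middle", ]
  expect_equal(mid$n_mutated, 0)  # S005 hit is non-pathogenic

  expect_warning(out0 <- pathway_prevalence(mut, list(Empty = character(0)), dec),
                 "no gene")
  expect_true(all(out0$prevalence == 0))
})

test_that("plasticity classification applies the strict sign rule", {
  pairs <- data.frame(patient = c("a", "b", "c", "d"),
                      pre_index = c(0.2, 0.2, -0.3, 0),
                      post_index = c(-0.1, 0.05, -0.2, 0.1))
  out <- classify_plasticity(pairs)
  expect_equal(as.character(out$group),
               c("plastic", "static", "static", "plastic"))
  # index exactly 0 is CBC-positive (not positive)
  expect_equal(out$pre_class[4], "CBC-positive")
  expect_equal(sum(table(out$group)), 4)

  expect_error(classify_plasticity(pairs[c(1, 1), ]), "duplicate")
  pairs$post_index[2] <- NA
  expect_error(classify_plasticity(pairs), "missing pair")
})

test_that("Fisher association matches hypergeometric enumeration and is symmetric", {
  calls <- classify_plasticity(data.frame(
    patient = sprintf("p%02d", 1:20),
    pre_index = rep(c(0.5, 0.5, -0.5, 0.5), 5),
    post_index = rep(c(0.5, -0.5, -0.5, 0.5), 5)))
  stopifnot(sum(calls$group == "plastic") == 5)
  labels <- data.frame(patient = calls$patient,
                       responder = c(rep(TRUE, 8), rep(FALSE, 12)))
  fa <- fisher_association(calls, labels)
  expect_equal(fa$p_value, oracle_fisher_p(fa$table), tolerance = 1e-12)
  expect_gt(fa$p_value, 0); expect_lte(fa$p_value, 1)
  # transposing the table leaves the two-sided p unchanged
  expect_equal(stats::fisher.test(t(fa$table))$p.value, fa$p_value)

  # balanced table: no association, p = 1
  tab <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(oracle_fisher_p(tab), stats::fisher.test(tab)$p.value)
  expect_equal(stats::fisher.test(tab)$p.value, 1)

  # the spec toy: enumeration equals the returned p
  tab2 <- matrix(c(3, 8, 7, 2), 2)
  expect_equal(stats::fisher.test(tab2)$p.value, oracle_fisher_p(tab2),
               tolerance = 1e-12)
  expect_equal(oracle_fisher_p(tab2), oracle_fisher_p(tab2[2:1, ]),
               tolerance = 1e-12)
})

test_that("degenerate response margins return p = 1 with a warning", {
  calls <- classify_plasticity(data.frame(patient = c("a", "b"),
                                          pre_index = c(1, 1),
                                          post_index = c(1, 1)))
  labels <- data.frame(patient = c("a", "b"), responder = c(TRUE, FALSE))
  expect_warning(fa <- fisher_association(calls, labels), "degenerate")
  expect_equal(fa$p_value, 1)
})

test_that("reproducibility statistics equal a hand variance-components computation", {
  # 3 tumors x 2 biopsies, worked by hand through the one-way ANOVA:
  # values (1,2), (4,6), (8,12); grand mean 5.5
  b <- data.frame(tumor = rep(c("t1", "t2", "t3"), each = 2),
                  biopsy = rep(c("b1", "b2"), 3),
                  index = c(1, 2, 4, 6, 8, 12))
  rs <- repro_stats(b)
  means <- c(1.5, 5, 10); gm <- 5.5
  msb <- sum(2 * (means - gm)^2) / 2
  msw <- (0.5 + 2 + 8) / 3
  k0 <- (6 - 12 / 6) / 2
  s2b <- (msb - msw) / k0
  expect_equal(rs$sigma2_within, msw)
  expect_equal(rs$sigma2_between, s2b)
  expect_equal(rs$icc, s2b / (s2b + msw))
  expect_equal(rs$within_cv, 100 * sqrt(msw) / gm)
  expect_equal(rs$between_cv, 100 * sqrt(s2b) / gm)
})

test_that("degenerate biopsy designs hit the documented conventions", {
  # identical biopsies within each tumor, tumors differ: ICC = 1, within CV 0
  b <- data.frame(tumor = rep(c("t1", "t2", "t3"), each = 2),
                  biopsy = rep(c("b1", "b2"), 3),
                  index = rep(c(1, 2, 3), each = 2))
  rs <- repro_stats(b)
  expect_equal(rs$icc, 1)
  expect_equal(rs$within_cv, 0)

  # all values identical: zero variance, ICC returned as 0 with a warning
  b$index <- 2
  expect_warning(rs0 <- repro_stats(b), "zero total variance")
  expect_equal(rs0$icc, 0)

  # grand mean ~ 0: CVs undefined, ICC still present
  b$index <- rep(c(-1, 1, 0), each = 2) + rep(c(-0.01, 0.01), 3)
  expect_warning(rsm <- repro_stats(b), "grand mean")
  expect_true(is.na(rsm$within_cv) && is.na(rsm$between_cv))
  expect_true(is.finite(rsm$icc))

  expect_error(repro_stats(data.frame(tumor = "t1", biopsy = c("b1", "b2"),
                                      index = c(1, 2))), ">= 2 tumors")
})

test_that("planted per-decile CNV and mutation rates are recovered within counting error", {
  set.seed(41)
  dec <- polarized_deciles(index_frame(rnorm(200)))
  gsim <- simulate_genomics(
    dec$sample_id, dec$decile, segments = paste0("chr", 1:40),
    gain_rate = c("CBC-enriched" = 0.5, "middle" = 0.2, "RSC-enriched" = 0.1),
    loss_rate = c("CBC-enriched" = 0.1, "middle" = 0.2, "RSC-enriched" = 0.4),
    pathways = list(Wnt = c("APC", "CTNNB1", "RNF43"),
                    TGFb = c("SMAD4", "TGFBR2")),
    mutation_rate = matrix(c(0.8, 0.4, 0.2, 0.1, 0.3, 0.6), nrow = 3,
                           dimnames = list(c("CBC-enriched", "middle",
                                             "RSC-enriched"),
                                           c("Wnt", "TGFb"))),
    seed = 13)
  freq <- cnv_decile_frequencies(categorize_cnv(gsim$cnv), dec)
  for (d in c("CBC-enriched", "RSC-enriched")) {
    n_obs <- sum(dec$decile == d) * 40
    obs_gain <- mean(freq$gain_freq[freq$decile == d])
    expect_lt(abs(obs_gain - gsim$truth$gain_rate[[d]]),
              4 * sqrt(0.5 * 0.5 / n_obs))
  }
  prev <- pathway_prevalence(gsim$mutations, list(Wnt = c("APC", "CTNNB1", "RNF43"),
                                                  TGFb = c("SMAD4", "TGFBR2")), dec)
  for (d in levels(dec$decile)) {
    for (pw in c("Wnt", "TGFb")) {
      row <- prev[prev$pathway == pw & prev$decile == d, ]
      p0 <- gsim$truth$mutation_rate[d, pw]
      expect_lt(abs(row$prevalence - p0),
                4 * sqrt(0.25 / row$n_samples) + 1e-9)
    }
  }
})
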