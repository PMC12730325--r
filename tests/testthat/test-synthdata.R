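test_that("configuration is validated", {
  expect_error(pop_config(n_individuals = 1), ">= 2")
  expect_error(pop_config(founder_fst = 1), "\\[0, 1\\)")
  expect_error(pop_config(founder_fst = -0.1), "\\[0, 1\\)")
  expect_error(pop_config(case_fraction = 0), "\\(0, 1\\)")
})

test_that("zero drift gives identical populations and seeds are reproducible", {
  cfg <- pop_config(n_genes = 10, founder_fst = 0, seed = 4)
  v <- simulate_allele_freqs(cfg)
  expect_identical(v$af1, v$af2)
  expect_true(all(v$af1 > 0 & v$af1 < 1))
  # determinism contract
  expect_identical(v, simulate_allele_freqs(cfg))
  # a different seed moves the frequencies
  expect_false(identical(v$af1, simulate_allele_freqs(cfg, seed = 5)$af1))
})

test_that("drift magnitude scales with the divergence parameter", {
  # Balding-Nichols: Var(af2 | af1) = Fst * af1 * (1 - af1), so the mean
  # absolute AF difference must grow with Fst
  mean_shift <- function(f) {
    cfg <- pop_config(n_genes = 500, variants_per_gene = 20,
                      founder_fst = f, seed = 11)
    v <- simulate_allele_freqs(cfg)
    mean(abs(v$af1 - v$af2))
  }
  expect_gt(mean_shift(0.3), mean_shift(0.05))
})

test_that("genotypes are in Hardy-Weinberg proportions", {
  cfg <- pop_config(n_individuals = 10000, n_genes = 10, seed = 6)
  tr <- sim_truth(cfg, simulate_allele_freqs(cfg))
  co <- simulate_cohort(cfg, tr)
  af <- tr$variants$af1
  # chi-square GOF per variant against HWE expectations at the known AF
  pvals <- vapply(seq_along(af), function(j) {
    obs <- tabulate(co$genotypes[, j] + 1L, 3L)
    expd <- 10000 * c((1 - af[j])^2, 2 * af[j] * (1 - af[j]), af[j]^2)
    keep <- expd > 0
    suppressWarnings(stats::chisq.test(obs[keep], p = expd[keep] / sum(expd[keep]))$p.value)
  }, numeric(1))
  expect_lt(mean(pvals < 0.01, na.rm = TRUE), 0.05)
})

test_that("null cohorts hit the target case rate; planted genes enrich carriers", {
  cfg <- pop_config(n_individuals = 5000, n_genes = 4, case_fraction = 0.2,
                    seed = 9)
  tr <- sim_truth(cfg, simulate_allele_freqs(cfg))
  co <- simulate_cohort(cfg, tr)
  rate <- mean(co$phenotype$status)
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / 5000) + 0.02)

  # strong dominant gene: damaged individuals over-represented among cases
  tp <- tiny_planted_cohort(n = 4000, seed = 13, effect = 2.5)
  sub <- tp$truth$variants[tp$truth$variants$gene == "G0001", ]
  pp <- genecentric:::damage_p0p1(tp$cohort$genotypes[, sub$variant_id], sub$score)
  damaged <- (1 - pp$p0) > 0.5
  status <- tp$cohort$phenotype$status
  expect_gt(mean(damaged[status == 1]), mean(damaged[status == 0]))
})

test_that("a two-individual cohort is valid", {
  cfg <- pop_config(n_individuals = 2, n_genes = 2, seed = 1)
  tr <- sim_truth(cfg, simulate_allele_freqs(cfg))
  co <- simulate_cohort(cfg, tr)
  expect_equal(nrow(co$genotypes), 2)
  expect_equal(nrow(co$phenotype), 2)
})

test_that("risk genes are validated against the annotation", {
  cfg <- pop_config(n_genes = 3, seed = 2)
  v <- simulate_allele_freqs(cfg)
  expect_error(
    sim_truth(cfg, v, risk_genes = data.frame(gene = "NOPE", mode = "dominant",
                                              effect = 1)),
    "must exist")
  expect_error(
    sim_truth(cfg, v, risk_genes = data.frame(gene = "G0001", mode = "additive",
                                              effect = 1)),
    "dominant")
})

test_that("summary-statistic export reports exact AFs and flags monomorphs", {
  cfg <- pop_config(n_individuals = 500, n_genes = 3, case_fraction = 0.3,
                    seed = 17)
  tr <- sim_truth(cfg, simulate_allele_freqs(cfg))
  co <- simulate_cohort(cfg, tr)
  # force one column monomorphic
  co$genotypes[, 5] <- 0L
  ss <- export_summary_stats(co)
  expect_equal(nrow(ss), ncol(co$genotypes))
  expect_equal(ss$af, unname(colSums(co$genotypes) / (2 * 500)))
  expect_equal(ss$flag[5], "monomorphic")
  expect_true(is.na(ss$beta[5]))
})

test_that("a planted strong common variant reaches genome-wide significance", {
  # one-variant gene carrying a large dominant effect at a common AF
  cfg <- pop_config(n_individuals = 6000, n_genes = 2, variants_per_gene = 1,
                    af_shape1 = 20, af_shape2 = 60, case_fraction = 0.3,
                    seed = 23)
  v <- simulate_allele_freqs(cfg)
  tr <- sim_truth(cfg, v, class_probs = c(synonymous = 0, missense = 0, lof = 1),
                  risk_genes = data.frame(gene = "G0001", mode = "dominant",
                                          effect = 1.2))
  co <- simulate_cohort(cfg, tr)
  ss <- export_summary_stats(co)
  planted <- ss$p[ss$variant_id %in%
                    tr$variants$variant_id[tr$variants$gene == "G0001"]]
  expect_lt(planted, 5e-8)
})

test_that("permuted phenotypes give uniform p-values and lambda near 1", {
  cfg <- pop_config(n_individuals = 2000, n_genes = 60, case_fraction = 0.2,
                    seed = 31)
  tr <- sim_truth(cfg, simulate_allele_freqs(cfg))
  co <- simulate_cohort(cfg, tr)
  set.seed(1)
  co$phenotype$status <- sample(co$phenotype$status)
  ss <- filter_maf(export_summary_stats(co), 0.01)
  p <- ss$p[!is.na(ss$p)]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(genomic_inflation(p)$lambda_gc - 1), 0.1)
})

test_that("export requires both phenotype classes", {
  cfg <- pop_config(n_individuals = 50, n_genes = 2, seed = 3)
  tr <- sim_truth(cfg, simulate_allele_freqs(cfg))
  co <- simulate_cohort(cfg, tr)
  co$phenotype$status <- 0L
  expect_error(export_summary_stats(co), "at least one case")
})
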