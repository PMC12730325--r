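genes3 <- data.frame(
  gene = c("gA", "gB", "gBnested"),
  chrom = c("chr1", "chr1", "chr1"),
  start = c(99, 500, 550),        # BED 0-based half-open
  end = c(200, 700, 620),
  stringsAsFactors = FALSE
)

test_that("variant-to-gene mapping reconciles BED and 1-based conventions", {
  rec <- data.frame(chrom = "chr1", pos = c(100, 99, 200, 201),
                    af = 0.1, beta = 0.1, p = 1e-9)
  ann <- map_variants_to_genes(rec, genes3)
  # BED [99, 200) covers 1-based positions 100..200
  expect_equal(ann$gene[ann$pos == 100], "gA")
  expect_true(is.na(ann$gene[ann$pos == 99]))
  expect_equal(ann$gene[ann$pos == 200], "gA")
  expect_true(is.na(ann$gene[ann$pos == 201]))
})

test_that("nested genes yield one annotation per overlap; cg mode drops intergenic", {
  rec <- data.frame(chrom = "chr1", pos = c(600, 50), af = 0.1, beta = 1, p = 1e-9)
  ann <- map_variants_to_genes(rec, genes3)
  expect_setequal(ann$gene[ann$pos == 600], c("gB", "gBnested"))
  expect_equal(nrow(ann), 3)  # two overlaps + one intergenic row
  cg <- map_variants_to_genes(rec, genes3, cg_mode = TRUE)
  expect_false(any(is.na(cg$gene)))
  expect_equal(nrow(cg), 2)
})

test_that("intergenic fraction matches a hand count on a small fixture", {
  set.seed(1)
  pos <- c(150, 160, 110, 555, 600, 650, 1000, 2000, 3000, 4000)
  rec <- data.frame(chrom = "chr1", pos = pos, af = 0.2, beta = 1, p = 1e-9)
  ann <- map_variants_to_genes(rec, genes3)
  # hand count: 6 positions inside gene bodies, 4 intergenic
  expect_equal(sum(is.na(ann$gene)), 4)
})

test_that("chrX/Y exclusion and malformed intervals are handled", {
  rec <- data.frame(chrom = c("chr1", "chrX"), pos = c(100, 100),
                    af = 0.1, beta = 1, p = 1e-9)
  ann <- map_variants_to_genes(rec, genes3, cg_mode = TRUE)
  expect_false(any(ann$chrom == "chrX"))
  bad <- rbind(genes3, data.frame(gene = "gBad", chrom = "chr1",
                                  start = 900, end = 900))
  expect_warning(map_variants_to_genes(rec, bad), "malformed")
})

test_that("MAF filter folds the allele frequency", {
  rec <- data.frame(af = c(0.995, 0.02, 0.005, 0.5))
  out <- filter_maf(rec, 0.01)
  expect_equal(out$af, c(0.02, 0.5))
  # a fixture where exactly 15% of records fall below the cut
  rec <- data.frame(af = c(rep(0.2, 85), rep(0.004, 15)))
  out <- filter_maf(rec, 0.01)
  expect_equal(attr(out, "removed_fraction"), 0.15)
})

test_that("gene coherence requires >= 2 variants and directional majority", {
  rec <- data.frame(
    gene = c("g1", "g1", "g1", "g2", "g2", "g2", "g3"),
    beta = c(0.2, 0.3, 0.1, 0.2, 0.3, -0.1, 0.5),
    p = 1e-9
  )
  sup <- gene_coherence_filter(rec)
  expect_equal(sup$direction_coherence[sup$gene == "g1"], 1)
  expect_true(sup$passes[sup$gene == "g1"])
  expect_equal(sup$direction_coherence[sup$gene == "g2"], 2 / 3, tolerance = 1e-12)
  expect_false(sup$passes[sup$gene == "g2"])
  # single-variant genes are excluded from the pass set
  expect_false(sup$passes[sup$gene == "g3"])
  # invariant: passes => n >= 2; coherence in [0.5, 1]
  expect_true(all(sup$n_sig_variants[sup$passes] >= 2))
  expect_true(all(sup$direction_coherence >= 0.5 & sup$direction_coherence <= 1))
})

test_that("gene coherence is invariant to record order and respects the p cut", {
  set.seed(2)
  rec <- data.frame(gene = sample(c("a", "b", "c"), 40, TRUE),
                    beta = rnorm(40), p = runif(40, 0, 1e-7))
  s1 <- gene_coherence_filter(rec)
  s2 <- gene_coherence_filter(rec[sample(nrow(rec)), ])
  expect_equal(s1, s2)
  # raising the threshold can only shrink the support counts
  s3 <- gene_coherence_filter(rec, sig_threshold = 1e-8)
  common <- intersect(s1$gene, s3$gene)
  expect_true(all(s3$n_sig_variants[match(common, s3$gene)] <=
                    s1$n_sig_variants[match(common, s1$gene)]))
})

test_that("genomic inflation matches its definition and null behaviour", {
  # all p = 0.5: median chi-square equals the null median exactly
  expect_equal(genomic_inflation(rep(0.5, 11))$lambda_gc, 1, tolerance = 1e-12)
  # sampling sd of the chi-square median at 1e5 tests is ~0.006 on lambda
  set.seed(5)
  expect_lt(abs(genomic_inflation(runif(1e5))$lambda_gc - 1), 0.03)
  # chi-square statistics scaled by 1.2 inflate lambda to ~1.2
  x <- 1.2 * rchisq(1e5, 1)
  p <- pchisq(x, 1, lower.tail = FALSE)
  expect_lt(abs(genomic_inflation(p)$lambda_gc - 1.2), 0.03)
  expect_error(genomic_inflation(numeric()), "no p-values")
})

test_that("VIF screen flags collinearity and matches the direct formula", {
  set.seed(7)
  # covariates orthogonal to each other and the intercept: R^2 = 0, VIF = 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 3), 200))))[, -1]
  v <- vif_screen(Q)
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-10)
  # duplicated column: infinite VIF, flagged at both thresholds
  X <- cbind(a = rnorm(50), b = rnorm(50))
  X <- cbind(X, c = X[, "a"])
  v <- vif_screen(X)
  expect_true(is.infinite(v$vif[v$covariate == "a"]))
  expect_true(all(v$flag50[is.infinite(v$vif)]))
  # correlated triple: matches 1 / (1 - R^2) computed directly
  Z <- matrix(rnorm(300), 100, 3)
  Z[, 3] <- Z[, 1] + 0.5 * Z[, 2] + rnorm(100, sd = 0.5)
  v <- vif_screen(Z)
  r2 <- summary(lm(Z[, 3] ~ Z[, 1:2]))$r.squared
  expect_equal(v$vif[3], 1 / (1 - r2), tolerance = 1e-10)
  expect_error(vif_screen(matrix(1:10, ncol = 1)), "two covariates")
})
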