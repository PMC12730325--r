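test_that("exact keys match directly; swapped alleles match with the flip rule", {
  a <- ss_frame("1", c(100, 200, 300), c("A", "C", "A"), c("G", "T", "C"),
                af = c(0.1, 0.2, 0.3), beta = c(0.5, -0.2, 0.1))
  b <- ss_frame("1", c(100, 200, 400), c("A", "T", "A"), c("G", "C", "C"),
                af = c(0.12, 0.75, 0.3), beta = c(0.45, 0.2, 0.1))
  m <- match_variants(a, b)
  mm <- m$matches
  direct <- mm[mm$variant_id == "1:100:A:G", ]
  expect_false(direct$flip_applied)
  expect_equal(direct$beta_b, 0.45)
  flipped <- mm[mm$variant_id == "1:200:C:T", ]
  expect_true(flipped$flip_applied)
  expect_equal(flipped$beta_b, -0.2)
  expect_equal(flipped$af_b, 0.25)
  # 300 unmatched in b; 400 unmatched in a
  expect_equal(m$missing_in_b, 1 / 3, tolerance = 1e-12)
  expect_equal(m$missing_in_a, 1 / 3, tolerance = 1e-12)
})

test_that("missingness fraction counts absent variants", {
  a <- ss_frame("1", 1:10, "A", "G", af = rep(0.2, 10), beta = rep(0.1, 10))
  b <- a[1:7, ]
  m <- match_variants(a, b)
  expect_equal(m$missing_in_b, 0.3, tolerance = 1e-12)
})

test_that("strand-ambiguous variants are never flipped", {
  a <- ss_frame("1", 100, "A", "T", af = 0.1, beta = 0.5)
  b <- ss_frame("1", 100, "T", "A", af = 0.9, beta = -0.5)
  m <- match_variants(a, b)
  expect_equal(nrow(m$matches), 0)
  expect_equal(m$n_ambiguous, 1)
})

test_that("the allele flip is an involution and matching is symmetric", {
  rec <- data.frame(af = 0.3, beta = 0.42)
  expect_equal(flip_record(flip_record(rec)), rec)

  set.seed(12)
  a <- ss_frame("1", 1:20, sample(c("A", "C"), 20, TRUE), "G",
                af = runif(20, 0.05, 0.95), beta = rnorm(20))
  b <- a[sample(20, 14), ]
  # swap alleles for some of b's records
  sw <- c(1, 3, 5)
  tmp <- b$ref[sw]; b$ref[sw] <- b$alt[sw]; b$alt[sw] <- tmp
  b$beta[sw] <- -b$beta[sw]; b$af[sw] <- 1 - b$af[sw]
  ab <- match_variants(a, b)$matches
  ba <- match_variants(b, a)$matches
  norm_key <- function(m) sort(m$variant_id)
  # same pair set up to flip bookkeeping (keys follow the query cohort)
  expect_equal(length(norm_key(ab)), length(norm_key(ba)))
  expect_equal(sum(ab$flip_applied), sum(ba$flip_applied))
  # flipped betas agree with the original unswapped records
  expect_equal(ab$beta_b, a$beta[match(ab$variant_id, paste(a$chrom, a$pos,
                                                            a$ref, a$alt,
                                                            sep = ":"))],
               tolerance = 1e-12)
})

test_that("concordance report counts directions, discordance and moderate effects", {
  m <- data.frame(
    variant_id = paste0("v", 1:5),
    af_a = c(0.1, 0.2, 0.3, 0.4, 0.05), beta_a = c(0.26, 0.3, -0.2, 0.05, 0.12),
    se_a = 0.05, p_a = 1e-9,
    af_b = c(0.1, 0.2, 0.3, 0.4, 0.05), beta_b = c(-0.15, 0.25, -0.3, 0.04, 0.2),
    se_b = 0.05, p_b = 1e-6,
    flip_applied = FALSE
  )
  rep_ <- concordance_report(m)
  expect_equal(rep_$sign_concordance, 4 / 5)
  # the opposite-direction pair with both |beta| > 0.1
  expect_equal(rep_$discordant$variant_id, "v1")
  expect_equal(rep_$moderate_fraction, 4 / 5)

  agree <- m; agree$beta_b <- abs(agree$beta_b) * sign(agree$beta_a)
  expect_equal(nrow(concordance_report(agree)$discordant), 0)

  # counting fixture: 42 of 100 moderate
  m2 <- data.frame(variant_id = paste0("w", 1:100), af_a = 0.2,
                   beta_a = c(rep(0.2, 42), rep(0.01, 58)), se_a = 0.05,
                   p_a = 1e-9, af_b = 0.2, beta_b = 0.1, se_b = 0.05,
                   p_b = 1e-6, flip_applied = FALSE)
  expect_equal(concordance_report(m2)$moderate_fraction, 0.42)
})

test_that("pleiotropy profiles partition significant traits by direction", {
  ph <- synthetic_phewas_table()
  prof <- pleiotropy_profile(ph, "chr22:28365160:C:T")
  expect_equal(prof$n_significant, 10)
  expect_equal(nrow(prof$protective), 0)

  prof <- pleiotropy_profile(ph, "chr22:39599242:A:C")
  expect_true("breast cancer" %in% prof$risk$trait)
  expect_true("bladder cancer" %in% prof$protective$trait)

  # nothing passes an impossible threshold
  empty <- pleiotropy_profile(ph, "chr22:28365160:C:T", sig = 1e-20)
  expect_equal(empty$n_significant, 0)
})

test_that("drift-free populations replicate effect directions as n grows", {
  conc <- vapply(c(400, 8000), function(n) planted_sign_concordance(n),
                 numeric(1))
  expect_gte(conc[2], conc[1])
  expect_gte(conc[2], 0.9)
})
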