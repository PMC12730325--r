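test_that("score-threshold filtering reproduces the packaged counts", {
  ot <- synthetic_ot_scores()
  expect_equal(nrow(ot), 638)
  expect_equal(attr(ot_threshold_filter(ot, 0.5), "n"), 208)
  expect_equal(nrow(ot_threshold_filter(ot, 0)), 638)
  expect_equal(nrow(ot_threshold_filter(ot, 1.01)), 0)
  expect_error(ot_threshold_filter(data.frame(gene = "x", ga_score = 1.5)),
               "\\[0, 1\\]")
})

test_that("score-gap prioritization surfaces externally supported genes", {
  ot <- synthetic_ot_scores()
  hi <- ot_threshold_filter(ot, 0.5)
  top10 <- score_gap_prioritize(hi, "external-support", top = 10)
  expect_setequal(top10$gene,
                  c("CCNE1", "C11orf65", "PTPN11", "RAD51B", "BRCA2", "DNMT3A",
                    "ATM", "ERBB4", "PALB2", "ESR1"))
  # tie behaviour: equal scores keep input order
  eq <- data.frame(gene = c("g1", "g2", "g3"), ga_score = 0.6,
                   global_score = 0.6)
  expect_equal(score_gap_prioritize(eq)$gene, c("g1", "g2", "g3"))
  # direction antisymmetry on a 2-gene fixture
  two <- data.frame(gene = c("ext", "gen"), ga_score = c(0.5, 0.9),
                    global_score = c(0.9, 0.5))
  expect_equal(score_gap_prioritize(two, "external-support")$gene[1], "ext")
  expect_equal(score_gap_prioritize(two, "genetic-only")$gene[1], "gen")
})

test_that("hypergeometric overlap matches exhaustive enumeration and limits", {
  expect_equal(hypergeometric_overlap(100, 10, 10, 0)$p_upper, 1)
  expect_equal(hypergeometric_overlap(4, 2, 2, 2)$p_upper, 1 / 6,
               tolerance = 1e-12)
  # every configuration with N <= 12 against the log-gamma summation oracle
  for (N in 2:12) {
    for (K in 1:(N - 1)) {
      for (n in 1:(N - 1)) {
        for (k in max(0, K + n - N):min(K, n)) {
          got <- hypergeometric_overlap(N, K, n, k)$p_upper
          expect_equal(got, hyper_tail_oracle(N, K, n, k), tolerance = 1e-10)
        }
      }
    }
  }
  expect_error(hypergeometric_overlap(10, 5, 5, 6), "impossible")
})

test_that("binomial support test matches closed forms and term summation", {
  expect_equal(binomial_support_test(5, 5, 0.5), 0.5^5, tolerance = 1e-12)
  expect_equal(binomial_support_test(0, 7, 0.3), 1)
  for (p0 in c(0.2, 0.3, 0.4, 0.5)) {
    expect_equal(binomial_support_test(11, 15, p0),
                 binom_tail_oracle(11, 15, p0), tolerance = 1e-12)
  }
  expect_error(binomial_support_test(2, 5, 0), "p0")
  expect_error(binomial_support_test(6, 5, 0.5), "k <= n")
})

test_that("label predicates encode the documented evidence combinations", {
  labs <- assign_labels(list(
    g1 = c("OT0.75", "TWAS"),
    g2 = "PWAS",
    g3 = character(),
    g4 = c("FG11", "FG12", "OT0.75", "TWAS"),
    g5 = "ExPheWAS"
  ))
  expect_equal(labs$g1, "b")
  expect_equal(labs$g2, "g")
  expect_equal(labs$g3, character(0))
  expect_true("d" %in% labs$g4)
  expect_equal(labs$g5, "i")
  expect_error(assign_labels(list(g = "NOT_A_SOURCE")), "unknown evidence")
})

test_that("core assembly reproduces the curated candidate table", {
  tab <- table3_evidence()
  expect_equal(nrow(tab), 45)
  expect_equal(sort(strsplit(tab$labels[tab$gene == "CHEK2"], ",")[[1]]),
               c("c", "d", "g"))
  expect_equal(tab$labels[tab$gene == "ARHGEF5"], "b")
  expect_true(tab$excluded[tab$gene == "ARHGEF5"])

  core <- assemble_core(tab)
  expect_equal(core$n_candidates, 45)
  expect_equal(core$n_multi_evidence, 13)
  expect_equal(core$n_excluded, 7)
  expect_equal(core$n_core, 38)
  # the curated exclusion flags coincide with the rule-derived ones
  expect_equal(core$table$core_status == "excluded", tab$excluded)
})

test_that("core assembly is idempotent and monotone in evidence", {
  tab <- table3_evidence()
  core <- assemble_core(tab)
  again <- assemble_core(core$table[, c("gene", "labels")])
  expect_equal(again$table$core_status, core$table$core_status)
  # adding evidence to an excluded gene promotes it, never the reverse
  tab2 <- tab
  tab2$labels[tab2$gene == "ARHGEF5"] <- "b,i"
  core2 <- assemble_core(tab2)
  expect_equal(core2$table$core_status[core2$table$gene == "ARHGEF5"], "core")
  expect_equal(core2$n_core, core$n_core + 1)
  # empty input
  empty <- assemble_core(data.frame(gene = character(), labels = character()))
  expect_equal(empty$n_core, 0)
})

test_that("venn regions partition the union and match the packaged overlap", {
  sets <- list(A = c("x", "y"), B = c("z"))
  vi <- venn_intersections(sets)
  expect_equal(vi$count[vi$region == "A&B"], 0)
  expect_equal(sum(vi$count), 3)

  sets <- list(A = c("x", "y"), B = c("x", "y", "z"))
  vi <- venn_intersections(sets)
  expect_equal(vi$count[vi$region == "A"], 0)  # A minus B empty
  expect_equal(vi$count[vi$region == "A&B"], 2)

  lists <- synthetic_cohort_gene_lists()
  vi <- venn_intersections(lists)
  expect_equal(sum(vi$count), length(unique(unlist(lists))))
  expect_equal(vi$count[vi$region == "FG11&FG12&OT0.5"], 17)
  # composite core: triple intersection plus single-freeze genes with
  # high-confidence aggregator support (GA >= 0.75)
  ot <- synthetic_ot_scores()
  hi <- ot$gene[ot$ga_score >= 0.75]
  triple <- strsplit(vi$members[vi$region == "FG11&FG12&OT0.5"], ",")[[1]]
  fg_extra <- setdiff(intersect(union(lists$FG11, lists$FG12), hi), triple)
  expect_equal(length(union(triple, fg_extra)), 20)
})

test_that("driver-set overlap with the aggregator list matches the packaged genes", {
  drv <- synthetic_driver_sets()
  ot208 <- ot_threshold_filter(synthetic_ot_scores(), 0.5)$gene
  expect_length(drv$TSG, 52)
  expect_length(drv$ONC, 36)
  shared_tsg <- intersect(ot208, drv$TSG)
  expect_setequal(shared_tsg,
                  c("BRCA2", "FOXP1", "ZFP36L1", "TBX3", "MAP3K1", "CHEK2"))
  expect_setequal(intersect(ot208, drv$FABRIC), c("CASP8", "CDKN2A"))
})
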