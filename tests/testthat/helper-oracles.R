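# Independent oracles and small fixture builders shared across test files.

# Brute-force damage distribution: enumerate every damage outcome over the
# individual allele copies (2^c paths) and sum probabilities by event count.
enum_damage_oracle <- function(genotypes, scores) {
  q <- rep(1 - scores, times = genotypes)  # per-copy damage probabilities
  if (!length(q)) return(c(p0 = 1, p1 = 0))
  outcomes <- as.matrix(expand.grid(rep(list(0:1), length(q))))
  pr <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, q, 1 - q)))
  k <- rowSums(outcomes)
  c(p0 = sum(pr[k == 0]), p1 = sum(pr[k == 1]))
}

# Exact hypergeometric upper tail via log-gamma summation, independent of
# phyper.
hyper_tail_oracle <- function(N, K, n, k) {
  lchoose_ <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  i <- k:min(K, n)
  sum(exp(lchoose_(K, i) + lchoose_(N - K, n - i) - lchoose_(N, n)))
}

# Exact binomial upper tail by direct term summation.
binom_tail_oracle <- function(k, n, p0) {
  i <- k:n
  sum(choose(n, i) * p0^i * (1 - p0)^(n - i))
}

# Benjamini-Hochberg adjusted p-values by the step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# A calibrated single-causal locus: one causal variant, independent z-scores,
# PIPs equal to the exact posterior under the generative model (uniform
# prior), so 95% credible sets have >= 95% nominal coverage of the causal.
sim_single_causal_locus <- function(m = 10, lambda = 3, seed = 1) {
  set.seed(seed)
  causal <- sample.int(m, 1)
  z <- rnorm(m) + lambda * (seq_len(m) == causal)
  lr <- dnorm(z - lambda) / dnorm(z)
  data.frame(
    chrom = "chr1", pos = seq_len(m) * 100L,
    ref = "A", alt = "G",
    variant_id = paste0("v", seq_len(m)),
    pip = lr / sum(lr),
    causal = seq_len(m) == causal
  )
}

# Small summary-statistic frame builder for cross-cohort tests.
ss_frame <- function(chrom, pos, ref, alt, af, beta,
                     se = rep(0.05, length(pos)), p = rep(1e-4, length(pos))) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             af = af, beta = beta, se = se, p = p,
             stringsAsFactors = FALSE)
}

# Beta sign-concordance between two drift-free populations for planted
# single-variant risk genes (moderate effect, so small n shows sign noise
# and large n approaches full concordance).
planted_sign_concordance <- function(n, effect = 0.25, seed = 77) {
  cfg <- pop_config(n_individuals = n, n_genes = 20, variants_per_gene = 1,
                    founder_fst = 0, case_fraction = 0.3,
                    af_shape1 = 5, af_shape2 = 45, seed = seed)
  v <- simulate_allele_freqs(cfg)
  tr <- sim_truth(cfg, v,
                  class_probs = c(synonymous = 0, missense = 0, lof = 1),
                  risk_genes = data.frame(gene = sprintf("G%04d", 1:20),
                                          mode = "dominant", effect = effect))
  ss1 <- export_summary_stats(simulate_cohort(cfg, tr, population = 1, seed = 1))
  ss2 <- export_summary_stats(simulate_cohort(cfg, tr, population = 2, seed = 2))
  m <- match_variants(ss1, ss2)$matches
  ok <- !is.na(m$beta_a) & !is.na(m$beta_b)
  mean(sign(m$beta_a[ok]) == sign(m$beta_b[ok]))
}

# Small planted-cohort builder used by several files.
tiny_planted_cohort <- function(n = 2000, n_genes = 8, seed = 1,
                                mode = "dominant", effect = 1.5,
                                case_fraction = 0.3) {
  cfg <- pop_config(n_individuals = n, n_genes = n_genes,
                    case_fraction = case_fraction, seed = seed)
  v <- simulate_allele_freqs(cfg)
  tr <- sim_truth(cfg, v,
                  risk_genes = data.frame(gene = "G0001", mode = mode,
                                          effect = effect))
  list(cfg = cfg, truth = tr, cohort = simulate_cohort(cfg, tr))
}
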