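#' Per-individual gene damage distribution
#'
#' Treats each alternative-allele copy of variant v as an independent
#' damaging event with probability q_v = 1 - s_v, where s_v in \[0, 1\] is the
#' variant's functional-effect score (1 = fully functional, 0 = loss of
#' function).  For an individual with genotype counts g_v in \{0, 1, 2\} the
#' number of damaging events in the gene is Poisson-binomial over the allele
#' copies, so
#' \deqn{P(0) = \prod_v s_v^{g_v}, \qquad
#'       P(1) = P(0) \sum_v g_v (1 - s_v) / s_v}
#' (with exact short-circuits when any s_v = 0).  The dominant damage
#' probability is 1 - P(0) (at least one damaging event), the recessive one
#' 1 - P(0) - P(1) (at least two events anywhere in the gene, which counts
#' compound heterozygotes in unphased data).  The corresponding *effect
#' scores* are the complements P(0) and P(0) + P(1): higher means less
#' functional damage.
#'
#' Accumulation is in log space so genes with thousands of variants remain
#' numerically stable; products underflowing 1e-300 are flushed to zero.
#'
#' @param genotypes Integer vector of alternative-allele counts (0, 1, 2),
#'   one per variant.
#' @param scores Numeric vector of functional-effect scores in \[0, 1\],
#'   aligned with `genotypes`.
#' @return A list with `p0`, `p1`, `dom_damage` (= 1 - p0), `rec_damage`
#'   (= 1 - p0 - p1), `dom_score` (= p0) and `rec_score` (= p0 + p1).
#' @examples
#' # two heterozygous variants, score 0.5 each
#' gene_damage_distribution(c(1, 1), c(0.5, 0.5))
#' @export
gene_damage_distribution <- function(genotypes, scores) {
  if (any(scores < 0 | scores > 1)) {
    stop("functional-effect scores must lie in [0, 1]", call. = FALSE)
  }
  if (!all(genotypes %in% 0:2)) {
    stop("genotype counts must be 0, 1 or 2", call. = FALSE)
  }
  pp <- damage_p0p1(matrix(genotypes, nrow = 1), scores)
  p0 <- pp$p0[1]
  p1 <- pp$p1[1]
  list(p0 = p0, p1 = p1,
       dom_damage = 1 - p0, rec_damage = max(0, 1 - p0 - p1),
       dom_score = p0, rec_score = min(1, p0 + p1))
}

# Vectorised core: G is an n x m matrix of allele counts, s length-m scores.
# Returns P(0 events) and P(exactly 1 event) per row, in log space with an
# underflow floor at 1e-300 and exact handling of s = 0 (certain damage).
damage_p0p1 <- function(G, s) {
  stopifnot(ncol(G) == length(s))
  zero <- s == 0
  n <- nrow(G)
  if (any(zero)) {
    z <- as.vector(G[, zero, drop = FALSE] %*% rep(1, sum(zero)))
    Gp <- G[, !zero, drop = FALSE]
    sp <- s[!zero]
  } else {
    z <- rep(0, n)
    Gp <- G
    sp <- s
  }
  if (length(sp)) {
    logp0 <- as.vector(Gp %*% log(sp))
    ratio <- as.vector(Gp %*% ((1 - sp) / sp))
  } else {
    logp0 <- rep(0, n)
    ratio <- rep(0, n)
  }
  p0_base <- ifelse(logp0 < log(1e-300), 0, exp(logp0))
  p0 <- ifelse(z == 0, p0_base, 0)
  p1 <- ifelse(z == 0, p0_base * ratio,
               ifelse(z == 1, p0_base, 0))
  list(p0 = p0, p1 = pmin(p1, 1 - p0))
}

#' Gene-level effect scores for a cohort
#'
#' Aggregates variant functional-effect scores into per-individual,
#' per-gene dominant and recessive effect scores (see
#' [gene_damage_distribution()] for the model).
#'
#' @param genotypes Numeric matrix of alternative-allele counts, individuals
#'   in rows, variants in columns; column names must be variant ids.
#' @param scores Data.frame with columns `variant_id`, `gene`, `score`.
#'   Variants present in `scores` but absent from the genotype matrix are
#'   ignored with a warning; one score per (variant, gene) is required.
#' @return An object of class `gene_scores`: list with matrices `dom` and
#'   `rec` (individuals x genes, effect scores where higher = less damage)
#'   and the `genes` character vector.
#' @export
gene_effect_scores <- function(genotypes, scores) {
  stopifnot(is.matrix(genotypes), !is.null(colnames(genotypes)))
  stopifnot(all(c("variant_id", "gene", "score") %in% names(scores)))
  if (anyDuplicated(scores[c("variant_id", "gene")])) {
    stop("one score per (variant, gene) pair is required", call. = FALSE)
  }
  if (any(scores$score < 0 | scores$score > 1)) {
    stop("functional-effect scores must lie in [0, 1]", call. = FALSE)
  }
  keep <- scores$variant_id %in% colnames(genotypes)
  if (!all(keep)) {
    warning(sum(!keep), " scored variants absent from the genotype matrix; ignored")
    scores <- scores[keep, , drop = FALSE]
  }
  genes <- unique(scores$gene)
  n <- nrow(genotypes)
  dom <- matrix(NA_real_, n, length(genes), dimnames = list(rownames(genotypes), genes))
  rec <- dom
  for (j in seq_along(genes)) {
    sub <- scores[scores$gene == genes[j], , drop = FALSE]
    G <- genotypes[, sub$variant_id, drop = FALSE]
    pp <- damage_p0p1(G, sub$score)
    dom[, j] <- pp$p0
    rec[, j] <- pmin(pp$p0 + pp$p1, 1)
  }
  structure(list(dom = dom, rec = rec, genes = genes, n = n),
            class = "gene_scores")
}

#' @export
print.gene_scores <- function(x, ...) {
  cat(sprintf("Gene effect scores: %d individuals x %d genes\n",
              x$n, length(x$genes)))
  cat(sprintf("  mean dominant damage: %.3f   mean recessive damage: %.3f\n",
              mean(1 - x$dom), mean(1 - x$rec)))
  invisible(x)
}
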