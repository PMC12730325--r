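#' Configuration for a synthetic case/control population
#'
#' Bundles the parameters of the synthetic-cohort generator: cohort and gene
#' panel size, the allele-frequency law, the founder-drift divergence between
#' the two emulated populations, and the target case fraction.  The second
#' population's allele frequencies are drawn from the first by a
#' Balding-Nichols beta law with divergence parameter `founder_fst`, emulating
#' the founder effects and bottlenecks that make cohorts from related
#' populations (e.g. Finnish vs. broader European) differ.
#'
#' @param n_individuals Number of individuals per cohort (>= 2).
#' @param n_genes Number of genes in the synthetic panel.
#' @param variants_per_gene Number of variants simulated per gene.
#' @param founder_fst Balding-Nichols divergence parameter in \[0, 1) between
#'   population 1 and population 2.  0 means identical allele frequencies.
#' @param af_shape1,af_shape2 Shape parameters of the beta law for baseline
#'   alternative-allele frequencies.  The defaults (0.3, 3) give a
#'   rare-skewed spectrum typical of coding variation.
#' @param case_fraction Target proportion of cases in (0, 1).
#' @param covariate_effects Named numeric vector of log-odds effects for the
#'   simulated covariates `sex`, `pc1`, `pc2`.
#' @param seed Integer base seed; every stochastic operation derives its own
#'   stream from it, so runs are reproducible end to end.
#'
#' @return An object of class `pop_config` (a validated list).
#' @examples
#' cfg <- pop_config(n_individuals = 500, n_genes = 10, seed = 42)
#' cfg
#' @export
pop_config <- function(n_individuals = 2000,
                       n_genes = 50,
                       variants_per_gene = 20,
                       founder_fst = 0.05,
                       af_shape1 = 0.3,
                       af_shape2 = 3,
                       case_fraction = 0.1,
                       covariate_effects = c(sex = 0.3, pc1 = 0.15, pc2 = -0.15),
                       seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals < 2) {
    stop("`n_individuals` must be >= 2", call. = FALSE)
  }
  if (!is.numeric(founder_fst) || founder_fst < 0 || founder_fst >= 1) {
    stop("`founder_fst` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(case_fraction) || case_fraction <= 0 || case_fraction >= 1) {
    stop("`case_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (n_genes < 1 || variants_per_gene < 1) {
    stop("`n_genes` and `variants_per_gene` must be positive", call. = FALSE)
  }
  if (af_shape1 <= 0 || af_shape2 <= 0) {
    stop("beta shape parameters must be positive", call. = FALSE)
  }
  stopifnot(all(c("sex", "pc1", "pc2") %in% names(covariate_effects)))
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_genes = as.integer(n_genes),
      variants_per_gene = as.integer(variants_per_gene),
      founder_fst = founder_fst,
      af_shape1 = af_shape1,
      af_shape2 = af_shape2,
      case_fraction = case_fraction,
      covariate_effects = covariate_effects,
      seed = as.integer(seed)
    ),
    class = "pop_config"
  )
}

#' @export
print.pop_config <- function(x, ...) {
  cat("Synthetic population configuration\n")
  cat(sprintf("  individuals: %d   genes: %d x %d variants\n",
              x$n_individuals, x$n_genes, x$variants_per_gene))
  cat(sprintf("  founder Fst: %.3f   case fraction: %.2f   seed: %d\n",
              x$founder_fst, x$case_fraction, x$seed))
  invisible(x)
}

# Deterministic genomic layout for the synthetic panel: genes round-robin on
# chromosomes 1..22, 1 Mb apart, 10 kb gene bodies (0-based half-open).
gene_layout <- function(cfg) {
  i <- seq_len(cfg$n_genes)
  chrom <- ((i - 1L) %% 22L) + 1L
  slot <- (i - 1L) %/% 22L
  start <- 1000000L + slot * 1000000L
  data.frame(
    gene = sprintf("G%04d", i),
    chrom = paste0("chr", chrom),
    start = start,
    end = start + 10000L,
    stringsAsFactors = FALSE
  )
}

#' Gene interval annotation for a synthetic panel
#'
#' Returns the gene bodies of the synthetic panel as BED-convention
#' (0-based, half-open) intervals.
#'
#' @param cfg A [pop_config()].
#' @return A data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
gene_intervals <- function(cfg) {
  stopifnot(inherits(cfg, "pop_config"))
  gene_layout(cfg)
}

#' Simulate allele frequencies for two related populations
#'
#' Draws baseline alternative-allele frequencies from a beta law and derives
#' a second, drifted population by the Balding-Nichols parameterization:
#' given baseline frequency p and divergence F, the drifted frequency is
#' Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance F p (1-p).
#' With F = 0 the two populations are identical.
#'
#' @param cfg A [pop_config()].
#' @param seed Seed for this draw; defaults to `cfg$seed`.
#' @return A data.frame of class `variant_table` with one row per variant:
#'   `variant_id` (chrom:pos:ref:alt), `gene`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `af1`, `af2`.
#' @examples
#' v <- simulate_allele_freqs(pop_config(n_genes = 4, seed = 7))
#' head(v)
#' @export
simulate_allele_freqs <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "pop_config"))
  layout <- gene_layout(cfg)
  m <- cfg$n_genes * cfg$variants_per_gene
  with_seed(seed, {
    gene_idx <- rep(seq_len(cfg$n_genes), each = cfg$variants_per_gene)
    offs <- vapply(seq_len(cfg$n_genes), function(i) {
      sort(sample.int(10000L, cfg$variants_per_gene))
    }, integer(cfg$variants_per_gene))
    pos <- layout$start[gene_idx] + as.vector(offs)  # 1-based inside body
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    af1 <- pmin(pmax(rbeta(m, cfg$af_shape1, cfg$af_shape2), 0.001), 0.999)
    af2 <- if (cfg$founder_fst == 0) {
      af1
    } else {
      f <- cfg$founder_fst
      pmin(pmax(rbeta(m, af1 * (1 - f) / f, (1 - af1) * (1 - f) / f),
                0.001), 0.999)
    }
    out <- data.frame(
      variant_id = paste(layout$chrom[gene_idx], pos, ref, alt, sep = ":"),
      gene = layout$gene[gene_idx],
      chrom = layout$chrom[gene_idx],
      pos = pos,
      ref = ref,
      alt = alt,
      af1 = af1,
      af2 = af2,
      stringsAsFactors = FALSE
    )
    class(out) <- c("variant_table", "data.frame")
    out
  })
}

#' Planted truth for a synthetic cohort
#'
#' Assigns each variant a functional class and a true functional-effect
#' score (1 = fully functional, 0 = loss of function), and records the
#' planted risk genes with their inheritance mode and liability effect size.
#' Class proportions default to 50% synonymous (score 1), 40% missense
#' (score ~ Beta(4, 1)) and 10% loss of function (score ~ U(0, 0.03)).
#'
#' @param cfg A [pop_config()].
#' @param variants A variant table from [simulate_allele_freqs()].
#' @param risk_genes Optional data.frame with columns `gene`, `mode`
#'   ("dominant" or "recessive") and `effect` (log-odds per unit damage
#'   probability).  Default: no planted effects.
#' @param class_probs Probabilities for (synonymous, missense, lof).
#' @param seed Seed; defaults to `cfg$seed + 1`.
#' @return An object of class `sim_truth`: list with elements `variants`
#'   (the variant table plus `class` and `score` columns) and `risk_genes`.
#' @export
sim_truth <- function(cfg, variants, risk_genes = NULL,
                      class_probs = c(synonymous = 0.5, missense = 0.4, lof = 0.1),
                      seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "pop_config"), is.data.frame(variants))
  stopifnot(abs(sum(class_probs) - 1) < 1e-8)
  if (!is.null(risk_genes)) {
    stopifnot(all(c("gene", "mode", "effect") %in% names(risk_genes)))
    if (!all(risk_genes$gene %in% variants$gene)) {
      stop("every risk gene must exist in the variant annotation", call. = FALSE)
    }
    if (!all(risk_genes$mode %in% c("dominant", "recessive"))) {
      stop("risk gene `mode` must be 'dominant' or 'recessive'", call. = FALSE)
    }
    if (!all(is.finite(risk_genes$effect))) {
      stop("risk gene effect sizes must be finite", call. = FALSE)
    }
  } else {
    risk_genes <- data.frame(gene = character(), mode = character(),
                             effect = numeric(), stringsAsFactors = FALSE)
  }
  m <- nrow(variants)
  with_seed(seed, {
    cls <- sample(names(class_probs), m, replace = TRUE, prob = class_probs)
    score <- rep(1, m)
    score[cls == "missense"] <- rbeta(sum(cls == "missense"), 4, 1)
    score[cls == "lof"] <- runif(sum(cls == "lof"), 0, 0.03)
    v <- variants
    v$class <- cls
    v$score <- score
    structure(list(variants = v, risk_genes = risk_genes), class = "sim_truth")
  })
}
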