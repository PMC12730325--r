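#' Simulate a case/control cohort
#'
#' Draws Hardy-Weinberg genotypes from the chosen population's allele
#' frequencies and case/control status from a logistic liability model.  The
#' linear predictor adds, for each planted risk gene, `effect x damage`,
#' where damage is the dominant (P >= 1 damaging event) or recessive
#' (P >= 2 events) gene damage probability computed from the *true* variant
#' scores with the same aggregation the association stage uses — so
#' parameter recovery is well posed.  Covariates are sex (Bernoulli 0.5) and
#' two synthetic principal components (standard normal) with the log-odds
#' effects in the configuration.  The intercept is set so the expected case
#' fraction matches `cfg$case_fraction`.
#'
#' Variants with degenerate allele frequencies (0 or 1) are excluded with a
#' message; within the generator this cannot occur because frequencies are
#' clipped away from the boundaries.
#'
#' @param cfg A [pop_config()].
#' @param truth A [sim_truth()] carrying variant scores and risk genes.
#' @param population Which population's allele frequencies to use (1 or 2).
#' @param seed Seed; defaults to `cfg$seed + 1 + population`.
#' @return An object of class `sim_cohort`: list with `genotypes`
#'   (individuals x variants allele-count matrix), `phenotype` (data.frame
#'   `id`, `status`, `sex`, `pc1`, `pc2`), `variants` (the scored variant
#'   table) and `population`.
#' @examples
#' cfg <- pop_config(n_individuals = 200, n_genes = 5, seed = 3)
#' v <- simulate_allele_freqs(cfg)
#' tr <- sim_truth(cfg, v)
#' co <- simulate_cohort(cfg, tr)
#' table(co$phenotype$status)
#' @export
simulate_cohort <- function(cfg, truth, population = 1,
                            seed = cfg$seed + 1L + as.integer(population)) {
  stopifnot(inherits(cfg, "pop_config"), inherits(truth, "sim_truth"))
  stopifnot(population %in% c(1, 2))
  v <- truth$variants
  af <- if (population == 1) v$af1 else v$af2
  bad <- af <= 0 | af >= 1
  if (any(bad)) {
    message(sum(bad), " variants with degenerate allele frequency excluded")
    v <- v[!bad, , drop = FALSE]
    af <- af[!bad]
  }
  n <- cfg$n_individuals
  with_seed(seed, {
    G <- matrix(rbinom(n * nrow(v), 2L, rep(af, each = n)), nrow = n,
                dimnames = list(sprintf("I%05d", seq_len(n)), v$variant_id))
    sex <- rbinom(n, 1L, 0.5)
    pc1 <- rnorm(n)
    pc2 <- rnorm(n)
    ce <- cfg$covariate_effects
    eta <- ce[["sex"]] * sex + ce[["pc1"]] * pc1 + ce[["pc2"]] * pc2
    if (nrow(truth$risk_genes)) {
      for (i in seq_len(nrow(truth$risk_genes))) {
        rg <- truth$risk_genes[i, ]
        sub <- v[v$gene == rg$gene, , drop = FALSE]
        pp <- damage_p0p1(G[, sub$variant_id, drop = FALSE], sub$score)
        damage <- if (rg$mode == "dominant") 1 - pp$p0 else pmax(0, 1 - pp$p0 - pp$p1)
        eta <- eta + rg$effect * damage
      }
    }
    b0 <- qlogis(cfg$case_fraction) - mean(eta)
    status <- rbinom(n, 1L, plogis(b0 + eta))
    structure(
      list(
        genotypes = G,
        phenotype = data.frame(id = rownames(G), status = status,
                               sex = sex, pc1 = pc1, pc2 = pc2,
                               stringsAsFactors = FALSE),
        variants = v,
        population = population
      ),
      class = "sim_cohort"
    )
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort (population %d): %d individuals, %d variants\n",
              x$population, nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  cases: %d   controls: %d\n",
              sum(x$phenotype$status == 1), sum(x$phenotype$status == 0)))
  invisible(x)
}

#' Per-variant GWAS summary statistics for a cohort
#'
#' Runs a per-variant logistic regression of case status on allele count
#' plus covariates and exports the summary-statistic dialect the filtering
#' and cross-cohort stages consume.  Monomorphic variants are emitted with
#' `NA` effect estimates and flagged rather than dropped, so record counts
#' are conserved.
#'
#' @param cohort A [simulate_cohort()] result, or a genotype matrix.
#' @param phenotype If `cohort` is a matrix: data.frame with a `status`
#'   column aligned to the rows of the matrix.
#' @param covariates Character vector of covariate columns of `phenotype`
#'   to adjust for (default `c("sex", "pc1", "pc2")`; use `NULL` for none).
#' @param variants Optional variant table (`variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`) used to fill the coordinate columns; taken from the
#'   cohort object when available.
#' @return A data.frame with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `af`, `beta`, `se`, `p`, `flag` (`""` or `"monomorphic"`).
#'   `af` is the empirical alternative-allele frequency (allele count / 2n).
#' @export
export_summary_stats <- function(cohort, phenotype = NULL,
                                 covariates = c("sex", "pc1", "pc2"),
                                 variants = NULL) {
  if (inherits(cohort, "sim_cohort")) {
    G <- cohort$genotypes
    phenotype <- cohort$phenotype
    variants <- variants %||% cohort$variants
  } else {
    G <- cohort
    stopifnot(is.matrix(G), !is.null(phenotype))
  }
  y <- phenotype$status
  if (sum(y == 1) < 1 || sum(y == 0) < 1) {
    stop("need at least one case and one control", call. = FALSE)
  }
  covariates <- intersect(covariates %||% character(), names(phenotype))
  X0 <- cbind(`(Intercept)` = 1,
              as.matrix(phenotype[, covariates, drop = FALSE]))
  m <- ncol(G)
  beta <- se <- p <- rep(NA_real_, m)
  flag <- rep("", m)
  af <- colSums(G) / (2 * nrow(G))
  for (j in seq_len(m)) {
    g <- G[, j]
    if (var(g) == 0) {
      flag[j] <- "monomorphic"
      next
    }
    fit <- suppressWarnings(glm.fit(cbind(X0, g = g), y, family = binomial()))
    k <- fit$rank
    if (is.na(fit$coefficients[["g"]]) || k < ncol(X0) + 1) {
      flag[j] <- "aliased"
      next
    }
    ses <- wald_se(fit)
    beta[j] <- fit$coefficients[["g"]]
    se[j] <- ses[length(ses)]
    p[j] <- 2 * pnorm(-abs(beta[j] / se[j]))
  }
  vid <- colnames(G)
  out <- data.frame(variant_id = vid, stringsAsFactors = FALSE)
  if (!is.null(variants)) {
    idx <- match(vid, variants$variant_id)
    out$chrom <- variants$chrom[idx]
    out$pos <- variants$pos[idx]
    out$ref <- variants$ref[idx]
    out$alt <- variants$alt[idx]
  } else {
    parts <- strsplit(vid, ":", fixed = TRUE)
    out$chrom <- vapply(parts, `[`, "", 1L)
    out$pos <- as.integer(vapply(parts, `[`, "", 2L))
    out$ref <- vapply(parts, `[`, "", 3L)
    out$alt <- vapply(parts, `[`, "", 4L)
  }
  out$af <- af
  out$beta <- beta
  out$se <- se
  out$p <- p
  out$flag <- flag
  out
}

# Wald standard errors from a glm.fit object (binomial dispersion = 1),
# following summary.glm's use of the pivoted qr decomposition.
wald_se <- function(fit) {
  k <- fit$rank
  piv <- fit$qr$pivot[seq_len(k)]
  covm <- chol2inv(fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE])
  se <- rep(NA_real_, length(fit$coefficients))
  se[piv] <- sqrt(diag(covm))
  se
}
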