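#' Gene-level burden association under a combined dominant/recessive model
#'
#' Fits, for every gene, a logistic regression of case status on the
#' covariates plus the gene's dominant and recessive *effect scores*
#' (complements of the damage probabilities; higher = less damage, see
#' [gene_damage_distribution()]).  The headline test is a combined 2-df
#' likelihood-ratio test of the covariates-only model against the model
#' with both burden components: a significant result indicates that one (or
#' both) of the gene-level burden measures is associated with the phenotype.
#' Per-component 1-df Wald tests and Cohen's d effect sizes are reported
#' alongside, and an inheritance mode (dominant / recessive / hybrid) is
#' inferred for genes passing the combined multiple-testing threshold.
#'
#' Sign convention: the tests are run on effect scores, so a *negative* z
#' indicates a risk gene (more damage associates with case status) and a
#' positive z a protective one.
#'
#' @param formula Model formula for the covariate adjustment, e.g.
#'   `status ~ sex + pc1 + pc2`.  The response must be 0/1 case status.
#' @param data Data.frame holding the response and covariates, one row per
#'   individual, aligned with the rows of `genotypes`.
#' @param genotypes Individuals x variants allele-count matrix (column
#'   names = variant ids), or a `sim_cohort`.
#' @param scores Data.frame of variant functional-effect scores
#'   (`variant_id`, `gene`, `score`), or a `sim_truth`.
#' @param alpha Family-wise level for the combined test (Bonferroni over
#'   genes), used for the significance calls in `summary()` and for mode
#'   inference.  Default 0.05.
#' @return An object of class `pwas`: the per-gene association table plus
#'   fit metadata.  Methods: [print.pwas()], [summary.pwas()],
#'   [coef.pwas()], [plot.pwas()].
#' @examples
#' cfg <- pop_config(n_individuals = 400, n_genes = 6, case_fraction = 0.3,
#'                   seed = 11)
#' tr <- sim_truth(cfg, simulate_allele_freqs(cfg),
#'                 risk_genes = data.frame(gene = "G0001", mode = "dominant",
#'                                         effect = 2))
#' co <- simulate_cohort(cfg, tr)
#' fit <- pwas(status ~ sex + pc1 + pc2, data = co$phenotype,
#'             genotypes = co, scores = tr)
#' fit
#' @export
pwas <- function(formula, data, genotypes, scores, alpha = 0.05) {
  if (inherits(genotypes, "sim_cohort")) genotypes <- genotypes$genotypes
  if (inherits(scores, "sim_truth")) {
    scores <- scores$variants[, c("variant_id", "gene", "score")]
  }
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (!all(y %in% 0:1)) stop("response must be 0/1 case status", call. = FALSE)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (nrow(X) != nrow(genotypes)) {
    stop("`data` and `genotypes` must describe the same individuals", call. = FALSE)
  }
  gs <- if (inherits(scores, "gene_scores")) scores
        else gene_effect_scores(genotypes, scores)
  null_fit <- glm.fit(X, y, family = binomial())
  res <- do.call(rbind, lapply(seq_along(gs$genes), function(j) {
    associate_gene(gs$dom[, j], gs$rec[, j], y, X, null_fit = null_fit,
                   gene_id = gs$genes[j])
  }))
  rownames(res) <- NULL
  n_genes <- nrow(res)
  thr <- alpha / n_genes
  res$significant <- !is.na(res$p_combined) & res$p_combined <= thr
  res$inferred_mode <- ifelse(res$significant,
                              infer_mode(res$p_dom, res$p_rec, thr),
                              NA_character_)
  structure(
    list(results = res, call = match.call(), n = length(y),
         n_case = sum(y == 1), n_control = sum(y == 0),
         n_genes = n_genes, alpha = alpha, threshold = thr),
    class = "pwas"
  )
}

# Mode rule: a component counts if its Wald p passes the same
# Bonferroni-corrected threshold as the combined test; both -> hybrid,
# neither (despite combined significance) -> the smaller component p decides.
infer_mode <- function(p_dom, p_rec, thr) {
  d <- !is.na(p_dom) & p_dom <= thr
  r <- !is.na(p_rec) & p_rec <= thr
  out <- ifelse(d & r, "hybrid", ifelse(d, "dominant", ifelse(r, "recessive", NA)))
  fall <- is.na(out)
  out[fall] <- ifelse(pmin(p_dom[fall], Inf) <= pmin(p_rec[fall], Inf),
                      "dominant", "recessive")
  out
}

#' Associate one gene's burden scores with case status
#'
#' The single-gene workhorse behind [pwas()].  Degenerate inputs
#' (zero-variance scores, complete separation, aliased components) yield a
#' flagged row with `NA` statistics rather than an error.
#'
#' @param dom,rec Per-individual dominant and recessive effect scores.
#' @param y 0/1 case status.
#' @param X Covariate model matrix (including intercept).
#' @param null_fit Optional pre-computed covariates-only `glm.fit`.
#' @param gene_id Label for the output row.
#' @return One-row data.frame: `gene`, `z_dom`, `z_rec`, `p_dom`, `p_rec`,
#'   `p_combined`, `d_dom`, `d_rec`, `flag`.
#' @export
associate_gene <- function(dom, rec, y, X, null_fit = NULL, gene_id = "gene") {
  if (sum(y == 1) < 1 || sum(y == 0) < 1) {
    stop("need at least one case and one control", call. = FALSE)
  }
  row <- data.frame(gene = gene_id, z_dom = NA_real_, z_rec = NA_real_,
                    p_dom = NA_real_, p_rec = NA_real_, p_combined = NA_real_,
                    d_dom = NA_real_, d_rec = NA_real_, flag = "",
                    stringsAsFactors = FALSE)
  # degenerate groups surface through the flag, not warnings, inside the scan
  row$d_dom <- suppressWarnings(cohens_d(dom[y == 1], dom[y == 0]))
  row$d_rec <- suppressWarnings(cohens_d(rec[y == 1], rec[y == 0]))
  use_dom <- var(dom) > 0
  use_rec <- var(rec) > 0
  if (!use_dom && !use_rec) {
    row$flag <- "zero_variance"
    return(row)
  }
  if (is.null(null_fit)) null_fit <- glm.fit(X, y, family = binomial())
  B <- cbind(if (use_dom) dom, if (use_rec) rec)
  colnames(B) <- c(if (use_dom) "dom", if (use_rec) "rec")
  fit <- withCallingHandlers(
    glm.fit(cbind(X, B), y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        row$flag <<- "separation"
      }
      invokeRestart("muffleWarning")
    }
  )
  if (row$flag == "separation") return(row)
  cf <- fit$coefficients
  aliased <- names(cf)[is.na(cf)]
  tested <- setdiff(colnames(B), aliased)
  if (!length(tested)) {
    row$flag <- "aliased"
    return(row)
  }
  ses <- setNames(wald_se(fit), names(cf))
  for (comp in tested) {
    z <- cf[[comp]] / ses[[comp]]
    if (comp == "dom") {
      row$z_dom <- z
      row$p_dom <- 2 * pnorm(-abs(z))
    } else {
      row$z_rec <- z
      row$p_rec <- 2 * pnorm(-abs(z))
    }
  }
  df <- length(tested)
  lr <- null_fit$deviance - fit$deviance
  row$p_combined <- pchisq(pmax(lr, 0), df = df, lower.tail = FALSE)
  if (df < 2 && (use_dom && use_rec)) row$flag <- "aliased_component"
  if (df < 2 && !(use_dom && use_rec)) row$flag <- "single_component"
  row
}

#' Cohen's d standardized mean difference
#'
#' `(mean(x) - mean(y)) / s_p` with the pooled standard deviation using
#' n - 1 denominators per group.  Returns `NA` (with a warning) when the
#' pooled SD is zero.
#'
#' @param x,y Numeric vectors (cases and controls), each of length >= 2.
#' @return A single numeric value.
#' @examples
#' cohens_d(c(2, 4), c(1, 3))  # 0.7071
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    warning("Cohen's d needs >= 2 observations per group")
    return(NA_real_)
  }
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    warning("pooled SD is zero; effect size undefined")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Multiple-testing adjustment with fixed-threshold parity modes
#'
#' Wraps [stats::p.adjust()] Bonferroni and Benjamini-Hochberg corrections
#' and adds the fixed genome-wide / exome-scale thresholds commonly used in
#' biobank association scans (5e-8, 5e-7).
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @param method One of `"BH"`, `"bonferroni"`, `"fixed"`; determines which
#'   column drives the `significant` call.
#' @param alpha Level for the adjusted-p methods.
#' @param threshold Fixed threshold used when `method = "fixed"`.
#' @return Data.frame with `p`, `bonferroni`, `bh`, `significant`.  Empty
#'   input gives an empty frame.
#' @export
adjust_multiple <- function(p, method = c("BH", "bonferroni", "fixed"),
                            alpha = 0.05, threshold = 5e-7) {
  method <- match.arg(method)
  if (!length(p)) {
    return(data.frame(p = numeric(), bonferroni = numeric(), bh = numeric(),
                      significant = logical()))
  }
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  out <- data.frame(p = p,
                    bonferroni = p.adjust(p, "bonferroni"),
                    bh = p.adjust(p, "BH"))
  out$significant <- switch(method,
    BH = out$bh <= alpha,
    bonferroni = out$bonferroni <= alpha,
    fixed = out$p <= threshold
  )
  out
}

#' @export
print.pwas <- function(x, ...) {
  cat("Gene-level burden association (combined dominant/recessive model)\n")
  cat(sprintf("  %d genes, %d cases / %d controls\n",
              x$n_genes, x$n_case, x$n_control))
  cat(sprintf("  combined-test Bonferroni threshold: %.3g (alpha = %g)\n",
              x$threshold, x$alpha))
  sig <- x$results[x$results$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat(sprintf("  %d significant gene(s):\n", nrow(sig)))
    print(sig[order(sig$p_combined),
              c("gene", "p_combined", "inferred_mode", "d_dom", "d_rec")],
          row.names = FALSE, digits = 3)
  } else {
    cat("  no genes pass the combined threshold\n")
  }
  invisible(x)
}

#' Summary of a gene burden association fit
#'
#' @param object A [pwas()] fit.
#' @param ... Unused.
#' @return The association table augmented with Bonferroni and BH adjusted
#'   combined p-values, ordered by `p_combined`, of class `summary.pwas`.
#' @export
summary.pwas <- function(object, ...) {
  res <- object$results
  ok <- !is.na(res$p_combined)
  res$p_bonferroni <- res$p_bh <- NA_real_
  res$p_bonferroni[ok] <- p.adjust(res$p_combined[ok], "bonferroni")
  res$p_bh[ok] <- p.adjust(res$p_combined[ok], "BH")
  res <- res[order(res$p_combined), ]
  structure(list(table = res, n_case = object$n_case,
                 n_control = object$n_control, alpha = object$alpha,
                 threshold = object$threshold),
            class = "summary.pwas")
}

#' @export
print.summary.pwas <- function(x, ...) {
  cat(sprintf("Gene burden associations: %d genes, %d cases / %d controls\n",
              nrow(x$table), x$n_case, x$n_control))
  print(head(x$table[, c("gene", "z_dom", "z_rec", "p_combined",
                         "p_bonferroni", "inferred_mode", "flag")], 10),
        row.names = FALSE, digits = 3)
  if (nrow(x$table) > 10) cat("  ... (", nrow(x$table) - 10, " more)\n", sep = "")
  invisible(x)
}

#' @export
coef.pwas <- function(object, ...) {
  m <- as.matrix(object$results[, c("z_dom", "z_rec")])
  rownames(m) <- object$results$gene
  m
}

#' QQ plot of combined burden-test p-values
#'
#' @param x A [pwas()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pwas <- function(x, ...) {
  p <- sort(x$results$p_combined[!is.na(x$results$p_combined)])
  exp_p <- ppoints(length(p))
  graphics::plot(-log10(exp_p), -log10(p),
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
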