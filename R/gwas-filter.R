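#' Annotate summary-statistic records with overlapping genes
#'
#' Maps each variant (1-based position) onto gene-body intervals and labels
#' it with *all* overlapping genes; variants overlapping no gene are kept
#' with `gene = NA` ("intergenic").  In coding-gene mode (`cg_mode = TRUE`)
#' intergenic records are dropped and, by default, chromosomes X and Y are
#' excluded, restricting the scan to autosomal coding-gene bodies.
#'
#' @param records Summary-statistic data.frame with at least `chrom`, `pos`
#'   (1-based).
#' @param genes Gene intervals: a data.frame with `gene`, `chrom`, `start`,
#'   `end` in BED convention (0-based half-open) — e.g. from
#'   [gene_intervals()] or [read_gene_intervals()] — or a `GRanges` with a
#'   `gene` metadata column.
#' @param cg_mode Drop intergenic records (coding-gene GWAS restriction).
#' @param promoter_pad Symmetric padding in bp added to each gene body.
#' @param drop_xy Exclude chrX/chrY records; defaults to `cg_mode`.
#' @return `records` expanded to one row per (variant, overlapping gene)
#'   with a `gene` column (`NA` for intergenic rows when `cg_mode = FALSE`).
#' @export
map_variants_to_genes <- function(records, genes, cg_mode = FALSE,
                                  promoter_pad = 0, drop_xy = cg_mode) {
  gr_genes <- as_gene_granges(genes)
  if (promoter_pad > 0) {
    gr_genes <- GenomicRanges::resize(gr_genes,
      GenomicRanges::width(gr_genes) + 2 * promoter_pad, fix = "center")
  }
  if (drop_xy) {
    sex <- tolower(records$chrom) %in% c("chrx", "chry", "x", "y", "23", "24")
    records <- records[!sex, , drop = FALSE]
  }
  if (!nrow(records)) {
    records$gene <- character(0)
    return(records)
  }
  gr_rec <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(records$pos, records$pos))
  hits <- GenomicRanges::findOverlaps(gr_rec, gr_genes)
  q <- S4Vectors::queryHits(hits)
  ann <- records[q, , drop = FALSE]
  ann$gene <- gr_genes$gene[S4Vectors::subjectHits(hits)]
  inter <- setdiff(seq_len(nrow(records)), unique(q))
  if (!cg_mode && length(inter)) {
    extra <- records[inter, , drop = FALSE]
    extra$gene <- NA_character_
    ann <- rbind(ann, extra)
  }
  ord <- order(match(rownames(ann), rownames(records)))
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

# Gene intervals (BED-convention data.frame or GRanges) -> GRanges, with
# 0-based half-open converted to 1-based closed at this boundary.
as_gene_granges <- function(genes) {
  if (methods::is(genes, "GRanges")) {
    if (is.null(genes$gene)) stop("GRanges must carry a `gene` column", call. = FALSE)
    return(genes)
  }
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  bad <- !is.finite(genes$start) | !is.finite(genes$end) | genes$end <= genes$start
  if (any(bad)) {
    warning(sum(bad), " malformed gene interval(s) skipped")
    genes <- genes[!bad, , drop = FALSE]
  }
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1L, genes$end),
                         gene = genes$gene)
}

#' Filter records by minor allele frequency
#'
#' Keeps records whose folded minor allele frequency `min(af, 1 - af)`
#' exceeds the threshold; common variants are retained regardless of which
#' allele is labelled alternative.
#'
#' @param records Data.frame with an `af` column.
#' @param threshold MAF threshold (default 0.01, i.e. MAF > 1%).
#' @return The retained records, with the removed fraction in attribute
#'   `"removed_fraction"`.
#' @export
filter_maf <- function(records, threshold = 0.01) {
  maf <- pmin(records$af, 1 - records$af)
  keep <- !is.na(maf) & maf > threshold
  out <- records[keep, , drop = FALSE]
  attr(out, "removed_fraction") <- if (nrow(records)) mean(!keep) else 0
  out
}

#' Gene-coherence filter on significant GWAS variants
#'
#' Implements the gene-support rule used to prune single-hit GWAS genes: a
#' gene passes only when it is supported by at least `min_variants`
#' significant variants and the vast majority of them share the same effect
#' direction (modal beta-sign fraction >= `coherence`).
#'
#' @param records Gene-annotated records (see [map_variants_to_genes()])
#'   with `gene`, `beta` and `p` columns.
#' @param min_variants Minimum significant variants per gene (default 2).
#' @param coherence Minimum modal-direction fraction (default 0.75).
#' @param sig_threshold Significance cut applied to `p` before counting
#'   (default 5e-8); `NULL` if the records are already restricted.
#' @return Data.frame with one row per gene: `gene`, `n_sig_variants`,
#'   `direction_coherence`, `passes`.
#' @export
gene_coherence_filter <- function(records, min_variants = 2, coherence = 0.75,
                                  sig_threshold = 5e-8) {
  rec <- records[!is.na(records$gene), , drop = FALSE]
  if (!is.null(sig_threshold)) {
    rec <- rec[!is.na(rec$p) & rec$p < sig_threshold, , drop = FALSE]
  }
  rec <- rec[!is.na(rec$beta) & rec$beta != 0, , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(gene = character(), n_sig_variants = integer(),
                      direction_coherence = numeric(), passes = logical()))
  }
  sgn <- split(sign(rec$beta), rec$gene)
  out <- data.frame(
    gene = names(sgn),
    n_sig_variants = vapply(sgn, length, integer(1)),
    direction_coherence = vapply(sgn, function(s) max(mean(s > 0), mean(s < 0)),
                                 numeric(1)),
    stringsAsFactors = FALSE
  )
  out$passes <- out$n_sig_variants >= min_variants &
    out$direction_coherence >= coherence
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Genomic inflation factor and QQ coordinates
#'
#' The inflation factor is the median of the observed 1-df chi-square
#' statistics (back-transformed from the p-values) divided by the null
#' median 0.45494; values near 1 indicate a well-calibrated scan.
#'
#' @param p Numeric vector of p-values in (0, 1\].
#' @return An object of class `inflation_report`: list with `lambda_gc` and
#'   a `qq` data.frame of expected vs. observed -log10(p).
#' @examples
#' genomic_inflation(runif(1000))$lambda_gc
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values supplied", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chisq) / qchisq(0.5, df = 1, lower.tail = FALSE)
  ord <- sort(p)
  structure(
    list(lambda_gc = lambda,
         qq = data.frame(expected = -log10(ppoints(length(ord))),
                         observed = -log10(ord))),
    class = "inflation_report"
  )
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("Genomic inflation: lambda = %.4f (%d tests)\n",
              x$lambda_gc, nrow(x$qq)))
  invisible(x)
}

#' Variance-inflation-factor screen for covariate collinearity
#'
#' Regresses each covariate on all the others and reports
#' VIF_j = 1 / (1 - R^2_j), flagging the conventional thresholds 5 and 50.
#' A perfectly collinear column gets `Inf`.
#'
#' @param X Numeric matrix or data.frame of covariates (n rows > columns,
#'   >= 2 columns).
#' @return Data.frame with `covariate`, `vif`, `flag5`, `flag50`.
#' @export
vif_screen <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least two covariates", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("need more rows than covariates", call. = FALSE)
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    # a perfectly collinear column triggers summary.lm's perfect-fit warning;
    # the Inf flag is the intended report
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = nm, vif = vif, flag5 = vif > 5, flag50 = vif > 50,
             stringsAsFactors = FALSE)
}
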