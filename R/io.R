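#' Read GWAS summary statistics
#'
#' Reads a TSV of per-variant summary statistics, mapping cohort-specific
#' header dialects onto the canonical columns `chrom`, `pos`, `ref`, `alt`,
#' `af`, `beta`, `se`, `p`.  Rows with out-of-range values (af outside
#' (0, 1), se <= 0, p outside (0, 1\]) are rejected and counted; a missing
#' mandatory column is a hard error naming the column.
#'
#' @param path Path to the TSV (plain or gzip; `read.delim` handles both).
#' @param dialect Header dialect: `"generic"` (canonical names),
#'   `"finngen"` (`#chrom`, `pos`, `ref`, `alt`, `af_alt`, `beta`,
#'   `sebeta`, `pval`) or `"plink"` (`CHR`, `POS`, `REF`, `ALT`, `AF`,
#'   `BETA`, `SE`, `P`).
#' @param extra_map Optional named character vector overriding the column
#'   map (canonical name -> file column).
#' @return Data.frame of validated records with the canonical columns plus
#'   any extra columns present; the number of rejected rows is in
#'   attribute `"n_rejected"`.
#' @export
read_summary_stats <- function(path, dialect = c("generic", "finngen", "plink"),
                               extra_map = NULL) {
  dialect <- match.arg(dialect)
  map <- switch(dialect,
    generic = c(chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
                af = "af", beta = "beta", se = "se", p = "p"),
    finngen = c(chrom = "X.chrom", pos = "pos", ref = "ref", alt = "alt",
                af = "af_alt", beta = "beta", se = "sebeta", p = "pval"),
    plink = c(chrom = "CHR", pos = "POS", ref = "REF", alt = "ALT",
              af = "AF", beta = "BETA", se = "SE", p = "P")
  )
  if (!is.null(extra_map)) map[names(extra_map)] <- extra_map
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(sprintf("%s (as `%s`)", missing_cols, names(missing_cols)),
               collapse = ", "), call. = FALSE)
  }
  out <- raw
  for (canon in names(map)) out[[canon]] <- raw[[map[[canon]]]]
  extra <- setdiff(names(raw), unname(map))
  out <- out[, c(names(map), extra), drop = FALSE]
  out$pos <- as.integer(out$pos)
  valid <- !is.na(out$pos) &
    !is.na(out$af) & out$af > 0 & out$af < 1 &
    (is.na(out$se) | out$se > 0) &
    (is.na(out$p) | (out$p > 0 & out$p <= 1))
  n_rejected <- sum(!valid)
  out <- out[valid, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write summary statistics as TSV
#'
#' @param records Data.frame of summary-statistic records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' Uses `rtracklayer` for the parsing and returns the intervals in BED
#' convention (0-based, half-open) as the rest of the package expects; the
#' BED name field supplies the gene id.
#'
#' @param path Path to a BED file.
#' @return Data.frame with `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    gene = if (!is.null(gr$name)) gr$name else paste0("interval", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Write gene intervals as BED
#'
#' @param genes Data.frame with `gene`, `chrom`, `start`, `end` (BED
#'   convention, as from [gene_intervals()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_intervals <- function(genes, path) {
  write.table(genes[, c("chrom", "start", "end", "gene")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fine-mapping PIP table
#'
#' @param path TSV with columns `locus`, `chrom`, `pos`, `ref`, `alt`,
#'   `pip`.
#' @return Validated data.frame (PIPs in \[0, 1\], duplicate variants
#'   within a locus rejected).
#' @export
read_pip_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "chrom", "pos", "ref", "alt", "pip")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(out$pip < 0 | out$pip > 1, na.rm = TRUE)) {
    stop("PIPs must lie in [0, 1]", call. = FALSE)
  }
  out$variant_id <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
  dup <- tapply(out$variant_id, out$locus, anyDuplicated)
  if (any(dup > 0)) {
    stop("duplicate variant ids within locus: ",
         paste(names(dup)[dup > 0], collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a genotype matrix
#'
#' Supports the package's canonical TSV allele-count matrix (individuals in
#' rows, variants in columns, first column `id`) and VCF with GT fields via
#' `vcfR`.  VCF genotypes are converted to alternative-allele counts;
#' variant ids are formed as `chrom:pos:ref:alt`.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"vcf"`; guessed from the file extension by
#'   default.
#' @return Numeric matrix, individuals x variants.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    G <- as.matrix(df[, -1, drop = FALSE])
    rownames(G) <- df[[1]]
    storage.mode(G) <- "integer"
    return(G)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  fix <- vcfR::getFIX(vcf)
  rownames(counts) <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"],
                            fix[, "ALT"], sep = ":")
  t(counts)
}

#' Write a genotype matrix as TSV
#'
#' @param genotypes Individuals x variants allele-count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes) %||% seq_len(nrow(genotypes)),
                   genotypes, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read named gene-set list files
#'
#' @param paths Named character vector of files, one gene symbol per line.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(paths) {
  stopifnot(!is.null(names(paths)))
  lapply(paths, function(p) {
    x <- readLines(p)
    unique(trimws(x[nzchar(trimws(x))]))
  })
}
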