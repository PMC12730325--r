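#' Build a 95% credible set from posterior inclusion probabilities
#'
#' Ranks the locus's variants by PIP (descending) and returns the smallest
#' prefix whose cumulative PIP reaches the coverage target.  Ties in PIP are
#' broken deterministically by position, then ref/alt allele, so identical
#' inputs always give identical sets.  When the total PIP of the locus
#' falls short of the target, the set contains all variants and is flagged
#' as under-covered.
#'
#' @param pips Data.frame for one locus with columns `pip` and (for
#'   tie-breaking and downstream gene mapping) `chrom`, `pos`, `ref`,
#'   `alt`; a `variant_id` column is carried through if present.
#' @param target Coverage target in (0, 1\]; default 0.95.
#' @param locus_id Label stored on the result.
#' @return An object of class `credible_set`: the selected rows augmented
#'   with `rank` and `cum_pip`, with attributes `locus_id`, `target`,
#'   `covered` (logical) and `total_pip`.
#' @examples
#' cs <- build_credible_set(data.frame(pos = 1:4, ref = "A", alt = "G",
#'                                     pip = c(0.6, 0.3, 0.08, 0.02)))
#' nrow(cs)  # 3: 0.9 < 0.95 <= 0.98
#' @export
build_credible_set <- function(pips, target = 0.95, locus_id = "locus") {
  stopifnot(is.data.frame(pips), "pip" %in% names(pips))
  if (any(pips$pip < 0 | pips$pip > 1, na.rm = TRUE)) {
    stop("PIPs must lie in [0, 1]", call. = FALSE)
  }
  if ("variant_id" %in% names(pips) && anyDuplicated(pips$variant_id)) {
    stop("duplicate variant ids in locus ", locus_id, call. = FALSE)
  }
  ord <- order(-pips$pip,
               if ("pos" %in% names(pips)) pips$pos else seq_len(nrow(pips)),
               if ("ref" %in% names(pips)) pips$ref else "",
               if ("alt" %in% names(pips)) pips$alt else "")
  sorted <- pips[ord, , drop = FALSE]
  cum <- cumsum(sorted$pip)
  total <- cum[length(cum)]
  covered <- total >= target
  k <- if (covered) which(cum >= target)[1] else nrow(sorted)
  out <- sorted[seq_len(k), , drop = FALSE]
  out$rank <- seq_len(k)
  out$cum_pip <- cum[seq_len(k)]
  rownames(out) <- NULL
  structure(out, locus_id = locus_id, target = target, covered = covered,
            total_pip = total, class = c("credible_set", "data.frame"))
}

#' Credible sets for every locus of a PIP table
#'
#' @param pip_table Data.frame with a `locus` column plus the columns
#'   [build_credible_set()] expects.
#' @param target Coverage target, default 0.95.
#' @return Named list of `credible_set` objects, one per locus.
#' @export
credible_sets <- function(pip_table, target = 0.95) {
  stopifnot("locus" %in% names(pip_table))
  loci <- split(pip_table, pip_table$locus)
  lapply(setNames(names(loci), names(loci)), function(id) {
    build_credible_set(loci[[id]], target = target, locus_id = id)
  })
}

#' Map credible sets to genes
#'
#' Each credible set is assigned the union of genes overlapped by its
#' member variants.  Sets whose members overlap no gene are labelled
#' intergenic and annotated with the nearest gene and its distance.
#'
#' @param cs A `credible_set` or a list of them (see [credible_sets()]).
#' @param genes Gene intervals as in [map_variants_to_genes()].
#' @return Data.frame with `locus`, `genes` (comma-joined, `NA` if
#'   intergenic), `intergenic`, `nearest_gene`, `distance`.
#' @export
cs_to_genes <- function(cs, genes) {
  if (inherits(cs, "credible_set")) cs <- list(cs)
  gr_genes <- as_gene_granges(genes)
  rows <- lapply(cs, function(s) {
    gr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, s$pos))
    hits <- GenomicRanges::findOverlaps(gr, gr_genes)
    gset <- unique(gr_genes$gene[S4Vectors::subjectHits(hits)])
    if (length(gset)) {
      data.frame(locus = attr(s, "locus_id"),
                 genes = paste(sort(gset), collapse = ","),
                 intergenic = FALSE, nearest_gene = NA_character_,
                 distance = NA_integer_, stringsAsFactors = FALSE)
    } else {
      # distance = bp between the variant position and the closest base of
      # the gene body, so 5 kb upstream of the first base reports 5000
      near <- NA_character_
      dist <- NA_integer_
      gstart <- GenomicRanges::start(gr_genes)
      gend <- GenomicRanges::end(gr_genes)
      gchrom <- as.character(GenomicRanges::seqnames(gr_genes))
      for (i in seq_len(nrow(s))) {
        same <- gchrom == as.character(s$chrom[i])
        if (!any(same)) next
        d <- pmax(gstart[same] - s$pos[i], s$pos[i] - gend[same], 0)
        j <- which.min(d)
        if (is.na(dist) || d[j] < dist) {
          dist <- as.integer(d[j])
          near <- gr_genes$gene[same][j]
        }
      }
      data.frame(locus = attr(s, "locus_id"), genes = NA_character_,
                 intergenic = TRUE, nearest_gene = near,
                 distance = as.integer(dist), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
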