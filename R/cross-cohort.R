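#' Match variants between two disjoint cohorts
#'
#' Joins two summary-statistic tables on the exact variant key
#' `chrom:pos:ref:alt`.  Records whose alleles are swapped between the
#' cohorts (`ref`/`alt` exchanged) are matched with the flip rule: cohort
#' B's beta sign is negated and its allele frequency complemented, exactly
#' once (`flip_applied = TRUE`).  Strand-ambiguous variants (A/T and C/G)
#' are never flipped; an attempted flip on one is counted as ambiguous and
#' excluded, as is a key matching with inconsistent alleles.  Per-cohort
#' missingness fractions are reported.
#'
#' @param a,b Summary-statistic data.frames with `chrom`, `pos`, `ref`,
#'   `alt`, `af`, `beta`, `se`, `p`.
#' @param allow_flip Attempt allele-swap matching (default TRUE).
#' @return List of class `variant_match`: `matches` (data.frame with
#'   `variant_id`, `af_a`, `beta_a`, `se_a`, `p_a`, `af_b`, `beta_b`,
#'   `se_b`, `p_b`, `flip_applied`), `missing_in_b`, `missing_in_a`
#'   (fractions), `n_ambiguous`.
#' @export
match_variants <- function(a, b, allow_flip = TRUE) {
  need <- c("chrom", "pos", "ref", "alt", "af", "beta", "se", "p")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  flipkey <- function(x) paste(x$chrom, x$pos, x$alt, x$ref, sep = ":")
  ka <- key(a)
  kb <- key(b)
  j <- match(ka, kb)
  flip <- rep(FALSE, nrow(a))
  ambiguous <- 0L
  if (allow_flip) {
    fj <- match(ka, flipkey(b))
    cand <- is.na(j) & !is.na(fj)
    amb <- cand & strand_ambiguous(a$ref, a$alt)
    ambiguous <- sum(amb)
    use <- cand & !amb
    j[use] <- fj[use]
    flip[use] <- TRUE
  }
  ok <- !is.na(j)
  jo <- j[ok]
  fo <- flip[ok]
  matches <- data.frame(
    variant_id = ka[ok],
    af_a = a$af[ok], beta_a = a$beta[ok], se_a = a$se[ok], p_a = a$p[ok],
    af_b = ifelse(fo, 1 - b$af[jo], b$af[jo]),
    beta_b = ifelse(fo, -b$beta[jo], b$beta[jo]),
    se_b = b$se[jo], p_b = b$p[jo],
    flip_applied = fo,
    stringsAsFactors = FALSE
  )
  matched_b <- logical(nrow(b))
  matched_b[jo] <- TRUE
  rownames(matches) <- NULL
  structure(
    list(matches = matches,
         missing_in_b = 1 - nrow(matches) / max(nrow(a), 1L),
         missing_in_a = 1 - sum(matched_b) / max(nrow(b), 1L),
         n_ambiguous = ambiguous),
    class = "variant_match"
  )
}

strand_ambiguous <- function(ref, alt) {
  paste0(ref, alt) %in% c("AT", "TA", "CG", "GC")
}

#' Flip a summary-statistic record's allele orientation
#'
#' Negates beta and complements the allele frequency; applying it twice
#' restores the original record (involution).
#'
#' @param record Data.frame (or one-row slice) with `af` and `beta`.
#' @return The record with `af -> 1 - af`, `beta -> -beta`.
#' @export
flip_record <- function(record) {
  record$af <- 1 - record$af
  record$beta <- -record$beta
  record
}

#' @export
print.variant_match <- function(x, ...) {
  cat(sprintf("Cross-cohort variant match: %d matched pairs\n", nrow(x$matches)))
  cat(sprintf("  missing in B: %.1f%%   missing in A: %.1f%%   flipped: %d   ambiguous: %d\n",
              100 * x$missing_in_b, 100 * x$missing_in_a,
              sum(x$matches$flip_applied), x$n_ambiguous))
  invisible(x)
}

#' Cross-cohort concordance report
#'
#' Summarises agreement of allele frequencies and effect sizes between two
#' matched cohorts: the beta sign-concordance fraction, the variants with
#' discordant directions where *both* cohorts show at least a moderate
#' effect (|beta| > `moderate_beta`), the fraction of matched variants with
#' a moderate effect in cohort A, and AF scatter data over the full range
#' and a rare-frequency window.
#'
#' @param match A [match_variants()] result or its `matches` data.frame.
#' @param moderate_beta Moderate-effect threshold on |beta| (default 0.1).
#' @param rare_range AF window for the rare-variant scatter
#'   (default c(0.001, 0.1)).
#' @return List of class `concordance_report`: `sign_concordance`,
#'   `discordant` (data.frame), `moderate_fraction`, `af_scatter`,
#'   `af_scatter_rare`, `n`.
#' @export
concordance_report <- function(match, moderate_beta = 0.1,
                               rare_range = c(0.001, 0.1)) {
  m <- if (inherits(match, "variant_match")) match$matches else match
  if (!nrow(m)) stop("no matched variants", call. = FALSE)
  ok <- !is.na(m$beta_a) & !is.na(m$beta_b) & m$beta_a != 0 & m$beta_b != 0
  conc <- mean(sign(m$beta_a[ok]) == sign(m$beta_b[ok]))
  disc <- m[ok & sign(m$beta_a) != sign(m$beta_b) &
              abs(m$beta_a) > moderate_beta & abs(m$beta_b) > moderate_beta,
            , drop = FALSE]
  rare <- m$af_a >= rare_range[1] & m$af_a <= rare_range[2]
  structure(
    list(sign_concordance = conc,
         discordant = disc,
         moderate_fraction = mean(abs(m$beta_a) > moderate_beta, na.rm = TRUE),
         af_scatter = m[, c("variant_id", "af_a", "af_b")],
         af_scatter_rare = m[rare, c("variant_id", "af_a", "af_b")],
         moderate_beta = moderate_beta,
         n = nrow(m)),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance over %d matched variants\n", x$n))
  cat(sprintf("  beta sign concordance: %.3f\n", x$sign_concordance))
  cat(sprintf("  moderate effects (|beta| > %g): %.1f%%\n",
              x$moderate_beta, 100 * x$moderate_fraction))
  cat(sprintf("  discordant with moderate effect in both cohorts: %d\n",
              nrow(x$discordant)))
  invisible(x)
}

#' Pleiotropy profile of a variant across traits
#'
#' Extracts the traits significantly associated with one variant from a
#' PheWAS table and partitions them by effect direction: positive beta =
#' risk, negative beta = protective.
#'
#' @param phewas Data.frame with `variant_id`, `trait`, `beta`, `p`,
#'   `n_cases`.
#' @param variant The variant id to profile.
#' @param sig Significance threshold (default 5e-8).
#' @return List of class `pleiotropy_profile`: `variant`, `n_significant`,
#'   `risk` and `protective` data.frames (trait, beta, p, n_cases).
#' @export
pleiotropy_profile <- function(phewas, variant, sig = 5e-8) {
  stopifnot(all(c("variant_id", "trait", "beta", "p") %in% names(phewas)))
  rec <- phewas[phewas$variant_id == variant & !is.na(phewas$p) &
                  phewas$p < sig, , drop = FALSE]
  rec <- rec[order(rec$p), , drop = FALSE]
  rownames(rec) <- NULL
  structure(
    list(variant = variant,
         n_significant = nrow(rec),
         risk = rec[rec$beta > 0, , drop = FALSE],
         protective = rec[rec$beta < 0, , drop = FALSE]),
    class = "pleiotropy_profile"
  )
}

#' @export
print.pleiotropy_profile <- function(x, ...) {
  cat(sprintf("Pleiotropy profile for %s: %d significant trait(s)\n",
              x$variant, x$n_significant))
  if (nrow(x$risk)) {
    cat("  risk:", paste(x$risk$trait, collapse = ", "), "\n")
  }
  if (nrow(x$protective)) {
    cat("  protective:", paste(x$protective$trait, collapse = ", "), "\n")
  }
  invisible(x)
}
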