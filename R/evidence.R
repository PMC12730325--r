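#' Filter genes by genetic-association score
#'
#' Keeps genes whose genetic-association (GA) score reaches the threshold,
#' the first pruning step applied to aggregator gene lists before any set
#' algebra.
#'
#' @param genes Data.frame with `gene` and `ga_score` columns (scores in
#'   \[0, 1\]).
#' @param theta Threshold; default 0.5.
#' @return The retained rows, with the retained count in attribute `"n"`.
#' @export
ot_threshold_filter <- function(genes, theta = 0.5) {
  stopifnot(all(c("gene", "ga_score") %in% names(genes)))
  if (any(genes$ga_score < 0 | genes$ga_score > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  out <- genes[!is.na(genes$ga_score) & genes$ga_score >= theta, , drop = FALSE]
  attr(out, "n") <- nrow(out)
  out
}

#' Rank genes by the gap between global and genetic-association scores
#'
#' A gene whose overall evidence score exceeds its genetic-association
#' score is backed by independent, non-genetic evidence (literature, animal
#' models, burden tests, clinical databases); the converse gap flags genes
#' whose support is genetic only.  Sorting on the signed gap therefore
#' prioritizes candidates in either direction.
#'
#' @param genes Data.frame with `gene`, `ga_score`, `global_score`.
#' @param direction `"external-support"` sorts by `global_score - ga_score`
#'   descending; `"genetic-only"` by `ga_score - global_score` descending.
#' @param top Optional cut: return only the first `top` genes.
#' @return The reordered data.frame with a `score_gap` column.  Ties keep
#'   input order (stable sort).
#' @export
score_gap_prioritize <- function(genes,
                                 direction = c("external-support", "genetic-only"),
                                 top = NULL) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene", "ga_score", "global_score") %in% names(genes)))
  gap <- if (direction == "external-support") {
    genes$global_score - genes$ga_score
  } else {
    genes$ga_score - genes$global_score
  }
  out <- genes
  out$score_gap <- gap
  out <- out[order(-gap), , drop = FALSE]  # order() is stable
  if (!is.null(top)) out <- head(out, top)
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap test between two gene sets
#'
#' Exact upper-tail probability of observing at least `k` genes shared
#' between a set of size `K` and an independent draw of size `n` from a
#' universe of `N` genes (sampling without replacement).
#'
#' @param N Universe size (e.g. 18053 protein-coding genes).
#' @param K Size of the first set (successes in the universe).
#' @param n Size of the second set (draws).
#' @param k Observed overlap.
#' @return An object of class `overlap_test`: list with `N`, `K`, `n`, `k`,
#'   `p_upper`.
#' @examples
#' hypergeometric_overlap(N = 18053, K = 52, n = 208, k = 6)$p_upper
#' @export
hypergeometric_overlap <- function(N, K, n, k) {
  if (k > min(K, n) || min(K, n) > N || K < 0 || n < 0 || k < 0) {
    stop("impossible overlap configuration", call. = FALSE)
  }
  p <- phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, p_upper = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("Hypergeometric overlap: %d shared of %d x %d in universe %d\n",
              x$k, x$K, x$n, x$N))
  cat(sprintf("  P(X >= %d) = %.4g\n", x$k, x$p_upper))
  invisible(x)
}

#' Exact binomial support test
#'
#' Upper-tail probability P(X >= k | n, p0) that at least `k` of `n` genes
#' carry support when each does so independently with background rate `p0`.
#' The background rate is a required, explicit argument: it encodes the
#' assumed base rate of (e.g.) literature support among candidate genes and
#' there is no defensible universal default.
#'
#' @param k Observed supported count (0 <= k <= n).
#' @param n Number of genes tested.
#' @param p0 Background support probability in (0, 1).
#' @return The exact upper-tail p-value.
#' @export
binomial_support_test <- function(k, n, p0) {
  if (!is.numeric(p0) || length(p0) != 1 || p0 <= 0 || p0 >= 1) {
    stop("`p0` must be a single probability in (0, 1)", call. = FALSE)
  }
  if (k < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}

#' Evidence-label configuration
#'
#' Defines how evidence labels are derived from source memberships and
#' which label, standing alone, disqualifies a gene from the core list.
#' Memberships are subsets of `FG11`, `FG12`, `OT0.5`, `OT0.75`, `TWAS`,
#' `PWAS`, `ExPheWAS` (with `OT0.75` implying `OT0.5`).
#'
#' The default predicates encode the combinations the curated evidence
#' table states outright: `d` = shared by both cohort freezes, the
#' high-confidence aggregator set and TWAS; `b` = aggregator-high plus TWAS
#' without cohort replication; `g` = protein-function burden (PWAS) hit;
#' `i` = gene-level PheWAS hit.  Labels `a`, `c`, `e`, `f`, `h` are
#' documented best-guess defaults inferred from label co-occurrence and are
#' fully overridable; curated evidence tables that already carry printed
#' labels bypass the predicates entirely (see [assemble_core()]).
#'
#' @param labels Named list of predicate functions; each takes a character
#'   vector of memberships and returns TRUE/FALSE.
#' @param exclude_sole Labels whose *sole* presence disqualifies a gene
#'   (default `"b"`).
#' @param ga_thresholds The two GA score cuts (default 0.5 and 0.75).
#' @return List of class `evidence_config`.
#' @export
evidence_config <- function(labels = NULL, exclude_sole = "b",
                            ga_thresholds = c(0.5, 0.75)) {
  has <- function(m, s) s %in% m
  default <- list(
    a = function(m) has(m, "FG11") && has(m, "FG12") && has(m, "OT0.5") &&
      !has(m, "OT0.75"),
    b = function(m) has(m, "OT0.75") && has(m, "TWAS") &&
      !has(m, "FG11") && !has(m, "FG12"),
    c = function(m) has(m, "FG11") && has(m, "FG12") && has(m, "OT0.75") &&
      !has(m, "TWAS"),
    d = function(m) has(m, "FG11") && has(m, "FG12") && has(m, "OT0.75") &&
      has(m, "TWAS"),
    e = function(m) xor(has(m, "FG11"), has(m, "FG12")) && has(m, "OT0.5") &&
      !has(m, "OT0.75"),
    f = function(m) xor(has(m, "FG11"), has(m, "FG12")) && has(m, "OT0.75"),
    g = function(m) has(m, "PWAS"),
    h = function(m) has(m, "TWAS") && (has(m, "FG11") || has(m, "FG12")) &&
      !has(m, "OT0.5"),
    i = function(m) has(m, "ExPheWAS")
  )
  if (!is.null(labels)) default[names(labels)] <- labels
  structure(list(labels = default, exclude_sole = exclude_sole,
                 ga_thresholds = ga_thresholds,
                 sources = c("FG11", "FG12", "OT0.5", "OT0.75",
                             "TWAS", "PWAS", "ExPheWAS")),
            class = "evidence_config")
}

#' Derive evidence labels from source memberships
#'
#' Applies the configuration's label predicates to each gene's membership
#' set.  Deterministic: identical memberships always yield identical
#' labels.
#'
#' @param memberships Named list: for each gene, a character vector of
#'   sources the gene appears in (see [evidence_config()] for the alphabet).
#' @param cfg An [evidence_config()].
#' @return Named list of character label vectors, one per gene.
#' @export
assign_labels <- function(memberships, cfg = evidence_config()) {
  stopifnot(inherits(cfg, "evidence_config"))
  lapply(memberships, function(m) {
    unknown <- setdiff(m, cfg$sources)
    if (length(unknown)) {
      stop("unknown evidence source(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if ("OT0.75" %in% m) m <- union(m, "OT0.5")
    names(cfg$labels)[vapply(cfg$labels, function(f) isTRUE(f(m)), logical(1))]
  })
}

#' Assemble the high-confidence core gene list
#'
#' Applies the exclusion rule to a labelled candidate table: a gene whose
#' label set is exactly one of the disqualifying singletons (by default
#' `{b}`, i.e. aggregator-plus-TWAS support with no independent
#' replication) is excluded; every other candidate enters the core list.
#' Adding evidence can therefore never demote a gene, and re-running the
#' assembly on its own output changes nothing.
#'
#' @param genes Data.frame with a `gene` column and either a `labels`
#'   column (comma-separated label strings, e.g. from a curated evidence
#'   table) or a `memberships` list column / named list passed through
#'   [assign_labels()].
#' @param cfg An [evidence_config()].
#' @return An object of class `core_gene_list`: list with `table` (gene,
#'   labels, n_labels, core_status, exclusion_reason), `n_candidates`,
#'   `n_multi_evidence`, `n_excluded`, `n_core`.
#' @examples
#' tab <- table3_evidence()
#' assemble_core(tab)
#' @export
assemble_core <- function(genes, cfg = evidence_config()) {
  stopifnot("gene" %in% names(genes))
  if (anyDuplicated(genes$gene)) stop("duplicate gene ids", call. = FALSE)
  if ("labels" %in% names(genes)) {
    labs <- lapply(strsplit(as.character(genes$labels), ","), trimws)
    labs <- lapply(labs, function(l) sort(l[nzchar(l)]))
  } else if ("memberships" %in% names(genes)) {
    labs <- assign_labels(setNames(genes$memberships, genes$gene), cfg)
  } else {
    stop("`genes` needs a `labels` or `memberships` column", call. = FALSE)
  }
  n_labels <- lengths(labs)
  sole_excluded <- n_labels == 1 &
    vapply(labs, function(l) length(l) == 1 && l %in% cfg$exclude_sole,
           logical(1))
  tab <- data.frame(
    gene = genes$gene,
    labels = vapply(labs, paste, "", collapse = ","),
    n_labels = n_labels,
    core_status = ifelse(sole_excluded, "excluded", "core"),
    exclusion_reason = ifelse(sole_excluded,
                              paste0("sole evidence '",
                                     vapply(labs, paste, "", collapse = ","),
                                     "' lacks independent support"), ""),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(
    list(table = tab,
         n_candidates = nrow(tab),
         n_multi_evidence = sum(n_labels >= 2),
         n_excluded = sum(sole_excluded),
         n_core = sum(!sole_excluded)),
    class = "core_gene_list"
  )
}

#' @export
print.core_gene_list <- function(x, ...) {
  cat("Core gene list assembly\n")
  cat(sprintf("  candidates: %d   multi-evidence: %d   excluded: %d   core: %d\n",
              x$n_candidates, x$n_multi_evidence, x$n_excluded, x$n_core))
  invisible(x)
}

#' All intersection regions of named gene sets
#'
#' Enumerates the 2^m - 1 membership patterns of m named sets and reports
#' each region's cardinality and members (a region is the set of elements
#' belonging to exactly that combination of sets, i.e. the Venn-diagram
#' cells).  Region counts always sum to the size of the union.
#'
#' @param sets Named list of >= 2 character vectors.
#' @return Data.frame with `region` (set names joined by `&`), `degree`,
#'   `count` and `members` (comma-joined).
#' @export
venn_intersections <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  m <- length(sets)
  combos <- unlist(lapply(seq_len(m), function(d) {
    utils::combn(names(sets), d, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = combos))
  members <- vapply(combos, function(cb) {
    paste(sort(universe[pattern == cb]), collapse = ",")
  }, "")
  data.frame(
    region = combos,
    degree = lengths(strsplit(combos, "&", fixed = TRUE)),
    count = as.integer(counts),
    members = members,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
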