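#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end synthetic pipeline — stage
#' toggles, filter thresholds, significance cuts, the population
#' configuration and the output directory — into one validated object that
#' round-trips losslessly through YAML.
#'
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param stages Named logical vector toggling `simulate`, `pwas`,
#'   `gwasfilter`, `credsets`, `concord`, `evidence`.
#' @param population Arguments passed to [pop_config()].
#' @param risk_genes Planted risk genes (see [sim_truth()]), as a
#'   data.frame or NULL.
#' @param maf_threshold MAF filter threshold (default 0.01).
#' @param coherence Direction-coherence threshold (default 0.75).
#' @param sig_genomewide,sig_exome Significance thresholds (5e-8, 5e-7).
#' @param cs_target Credible-set coverage target (default 0.95).
#' @param moderate_beta Moderate-effect threshold (default 0.1).
#' @param ga_cut,ga_cut_high Aggregator score cuts (0.5, 0.75).
#' @param seed Base seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("genecentric_run_"),
                            stages = c(simulate = TRUE, pwas = TRUE,
                                       gwasfilter = TRUE, credsets = TRUE,
                                       concord = TRUE, evidence = TRUE),
                            population = list(),
                            risk_genes = NULL,
                            maf_threshold = 0.01,
                            coherence = 0.75,
                            sig_genomewide = 5e-8,
                            sig_exome = 5e-7,
                            cs_target = 0.95,
                            moderate_beta = 0.1,
                            ga_cut = 0.5,
                            ga_cut_high = 0.75,
                            seed = 1L) {
  stopifnot(maf_threshold >= 0, maf_threshold < 0.5,
            coherence >= 0.5, coherence <= 1,
            cs_target > 0, cs_target <= 1,
            sig_genomewide > 0, sig_exome > 0,
            ga_cut >= 0, ga_cut <= 1, ga_cut_high >= ga_cut)
  structure(
    list(out_dir = out_dir, stages = as.list(stages),
         population = population, risk_genes = risk_genes,
         maf_threshold = maf_threshold, coherence = coherence,
         sig_genomewide = sig_genomewide, sig_exome = sig_exome,
         cs_target = cs_target, moderate_beta = moderate_beta,
         ga_cut = ga_cut, ga_cut_high = ga_cut_high,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$risk_genes)) x$risk_genes <- as.list(x$risk_genes)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  rg <- if (!is.null(x$risk_genes)) {
    data.frame(x$risk_genes, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  do.call(pipeline_config, c(
    x[setdiff(names(x), c("risk_genes", "stages"))],
    list(risk_genes = rg, stages = unlist(x$stages))
  ))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' cohort simulation, gene burden association, summary-statistic export
#' with MAF / gene-coherence filtering and inflation QC, credible-set
#' construction from single-causal approximate posteriors over each gene's
#' variants, cross-population concordance, and core-list assembly from the
#' packaged evidence table.  Every stage writes a TSV into the output
#' directory and logs input/kept/dropped record counts; a manifest
#' (package version, seed, full configuration, per-stage counts) makes the
#' run reproducible.  Identical configurations give byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return List of class `pipeline_result` with the in-memory stage
#'   outputs, the manifest, and `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  st <- config$stages
  out <- list()
  counts <- list()
  cfg <- do.call(pop_config, c(config$population, list(seed = config$seed)))

  if (isTRUE(st$simulate)) {
    say("stage simulate: ", cfg$n_individuals, " individuals x ",
        cfg$n_genes, " genes")
    variants <- simulate_allele_freqs(cfg)
    truth <- sim_truth(cfg, variants, risk_genes = config$risk_genes)
    cohort <- simulate_cohort(cfg, truth, population = 1)
    out$cohort <- cohort
    out$truth <- truth
    write_genotypes(cohort$genotypes, file.path(config$out_dir, "genotypes.tsv"))
    write.table(cohort$phenotype, file.path(config$out_dir, "phenotype.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth$variants, file.path(config$out_dir, "variant_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$simulate <- c(input = nrow(truth$variants),
                         kept = ncol(cohort$genotypes), dropped = 0)
  }

  if (isTRUE(st$pwas)) {
    stopifnot(!is.null(out$cohort))
    say("stage pwas: combined dominant/recessive burden test")
    fit <- pwas(status ~ sex + pc1 + pc2, data = out$cohort$phenotype,
                genotypes = out$cohort, scores = out$truth)
    out$pwas <- fit
    write.table(fit$results, file.path(config$out_dir, "pwas_associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$pwas <- c(input = fit$n_genes, kept = sum(fit$results$significant),
                     dropped = sum(fit$results$flag != ""))
  }

  if (isTRUE(st$gwasfilter)) {
    stopifnot(!is.null(out$cohort))
    say("stage gwasfilter: per-variant scan, MAF and coherence filters")
    ss <- export_summary_stats(out$cohort)
    write_summary_stats(ss, file.path(config$out_dir, "summary_stats.tsv"))
    kept <- filter_maf(ss, config$maf_threshold)
    ann <- map_variants_to_genes(kept, gene_intervals(cfg), cg_mode = TRUE)
    support <- gene_coherence_filter(ann, coherence = config$coherence,
                                     sig_threshold = config$sig_exome)
    infl <- genomic_inflation(ss$p[!is.na(ss$p)])
    out$summary_stats <- ss
    out$gene_support <- support
    out$inflation <- infl
    write.table(support, file.path(config$out_dir, "gene_support.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$gwasfilter <- c(input = nrow(ss), kept = nrow(kept),
                           dropped = nrow(ss) - nrow(kept))
  }

  if (isTRUE(st$credsets)) {
    stopifnot(!is.null(out$summary_stats))
    say("stage credsets: single-causal approximate posteriors per gene")
    pip_tab <- approx_single_causal_pips(out$summary_stats, out$cohort$variants)
    cs <- credible_sets(pip_tab, target = config$cs_target)
    cs_genes <- cs_to_genes(cs, gene_intervals(cfg))
    out$credible_sets <- cs
    out$cs_genes <- cs_genes
    cs_tab <- do.call(rbind, lapply(cs, function(s) {
      data.frame(locus = attr(s, "locus_id"), rank = s$rank,
                 variant_id = s$variant_id, pip = s$pip, cum_pip = s$cum_pip,
                 stringsAsFactors = FALSE)
    }))
    write.table(cs_tab, file.path(config$out_dir, "credible_sets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$credsets <- c(input = nrow(pip_tab), kept = nrow(cs_tab),
                         dropped = nrow(pip_tab) - nrow(cs_tab))
  }

  if (isTRUE(st$concord)) {
    stopifnot(!is.null(out$truth))
    say("stage concord: replicate cohort from the drifted population")
    cohort2 <- simulate_cohort(cfg, out$truth, population = 2)
    ss2 <- export_summary_stats(cohort2)
    mt <- match_variants(out$summary_stats, ss2)
    rep_ok <- !is.na(mt$matches$beta_a) & !is.na(mt$matches$beta_b)
    conc <- concordance_report(mt$matches[rep_ok, , drop = FALSE],
                               moderate_beta = config$moderate_beta)
    out$concordance <- conc
    write.table(mt$matches, file.path(config$out_dir, "variant_matches.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$concord <- c(input = nrow(out$summary_stats),
                        kept = nrow(mt$matches),
                        dropped = nrow(out$summary_stats) - nrow(mt$matches))
  }

  if (isTRUE(st$evidence)) {
    say("stage evidence: core-list assembly and overlap statistics")
    tab <- table3_evidence()
    core <- assemble_core(tab)
    ot <- synthetic_ot_scores()
    drivers <- synthetic_driver_sets()
    ot_hi <- ot_threshold_filter(ot, config$ga_cut)
    k <- length(intersect(ot_hi$gene, drivers$TSG))
    ov <- hypergeometric_overlap(N = 18053, K = length(drivers$TSG),
                                 n = nrow(ot_hi), k = k)
    out$core <- core
    out$overlap <- ov
    write.table(core$table, file.path(config$out_dir, "core_gene_list.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts$evidence <- c(input = core$n_candidates, kept = core$n_core,
                         dropped = core$n_excluded)
  }

  manifest <- list(
    package = "genecentric",
    version = as.character(packageVersion("genecentric")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "out_dir")],
    record_counts = lapply(counts, as.list)
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  structure(c(out, list(manifest = manifest, out_dir = config$out_dir)),
            class = "pipeline_result")
}

# Approximate single-causal posterior per gene: treating each gene's
# variants as one locus with a flat prior and at most one causal variant,
# PIP_j is the normalized likelihood ratio exp(z_j^2/2) computed via
# log-sum-exp.  A demonstration posterior for synthetic runs, not a
# replacement for proper fine-mapping (which this package consumes as
# input).
approx_single_causal_pips <- function(summary_stats, variants) {
  ss <- summary_stats[!is.na(summary_stats$beta), , drop = FALSE]
  gene <- variants$gene[match(ss$variant_id, variants$variant_id)]
  ss <- ss[!is.na(gene), , drop = FALSE]
  gene <- gene[!is.na(gene)]
  z2 <- (ss$beta / ss$se)^2 / 2
  pip <- unlist(lapply(split(z2, gene), function(v) {
    w <- exp(v - max(v))
    w / sum(w)
  }), use.names = FALSE)
  # split() regroups by gene in sorted order; align the records the same way
  # (order() is stable, so within-gene record order is preserved)
  ss_sorted <- ss[order(gene), , drop = FALSE]
  data.frame(locus = sort(gene), chrom = ss_sorted$chrom, pos = ss_sorted$pos,
             ref = ss_sorted$ref, alt = ss_sorted$alt,
             variant_id = ss_sorted$variant_id, pip = pip,
             stringsAsFactors = FALSE)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", x$out_dir, "\n")
  for (nm in names(x$manifest$record_counts)) {
    rc <- x$manifest$record_counts[[nm]]
    cat(sprintf("  %-10s input %-7s kept %-7s dropped %s\n", nm,
                rc$input, rc$kept, rc$dropped))
  }
  invisible(x)
}
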