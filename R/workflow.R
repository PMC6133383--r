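#' Run the full simulate -> assign -> test -> validate -> methylation
#' pipeline
#'
#' Orchestrates an end-to-end analysis on synthetic data: simulates gene
#' truth, parental counts for a discovery cohort and an independent
#' validation cohort drawn from the same gene truth, applies the expression
#' filters, fits the parent-of-origin asymmetry test in both cohorts,
#' computes direction concordance for the discovery-significant genes, and
#' corroborates imprinted candidates against simulated methylation at ICRs
#' placed next to the truly imprinted genes (with matched non-ICR control
#' regions). Optionally exercises the read-level route
#' (genotypes -> reads -> assignment) instead of taking simulated counts
#' directly.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written there atomically (counts, results, concordance, DMR summary,
#'   support table, JSON manifest).
#' @param use_reads Route the discovery counts through read simulation and
#'   haplotype assignment (slower; identical result at zero read error).
#' @param min_parental,parental_rule,fdr_threshold,major_share_threshold
#'   Passed to \code{\link{poe_test}}.
#' @param min_logcpm,min_individuals Passed to \code{\link{filter_genes}}.
#' @return A list of class \code{imprintscan_run}: \code{genes} (truth),
#'   \code{counts}, \code{fit}, \code{fit_validation}, \code{concordance},
#'   \code{single_parent}, \code{assignment_summary}, \code{dmr_summary},
#'   \code{support}, \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir = NULL, use_reads = FALSE,
                         min_parental = 5L, parental_rule = "sum",
                         fdr_threshold = 0.05, major_share_threshold = 0.8,
                         min_logcpm = 1, min_individuals = 20L) {
  stopifnot(inherits(config, "sim_config"))
  genes <- simulate_gene_specs(config)
  counts <- simulate_parental_counts(config, genes)
  if (use_reads && nrow(counts)) {
    geno <- simulate_phased_genotypes(config, genes)
    reads <- simulate_reads(counts, geno, error_rate = 0,
                            seed = config$seed)
    counts <- aggregate_counts(assign_reads(reads, geno), genes)
  }
  filtered <- filter_genes(counts, genes, min_logcpm = min_logcpm,
                           min_individuals = min_individuals)
  fit <- poe_test(filtered, min_parental = min_parental,
                  parental_rule = parental_rule,
                  fdr_threshold = fdr_threshold,
                  major_share_threshold = major_share_threshold)
  # validation cohort: same gene truth, independent individuals and noise
  vconfig <- config
  vconfig$n_individuals <- config$n_individuals_validation
  vconfig$seed <- stage_seed(config$seed, 100003L)
  vcounts <- simulate_parental_counts(vconfig, genes)
  vfiltered <- filter_genes(vcounts, genes, min_logcpm = min_logcpm,
                            min_individuals = min(min_individuals,
                                                  vconfig$n_individuals))
  vfit <- poe_test(vfiltered, min_parental = min_parental,
                   parental_rule = parental_rule,
                   fdr_threshold = fdr_threshold,
                   major_share_threshold = major_share_threshold)
  sig <- fit$results$gene_id[!is.na(fit$results$q_value) &
                               fit$results$q_value < fdr_threshold]
  conc <- if (length(sig) &&
              length(intersect(sig, vfit$results$gene_id))) {
    concordance(fit, vfit, genes = sig)
  } else NULL
  # methylation: one ICR next to each truly imprinted gene, plus matched
  # non-ICR control regions next to balanced genes
  imprinted <- genes[!is.na(genes$silenced_parent), , drop = FALSE]
  balanced <- genes[genes$class_label == "biallelic_balanced", , drop = FALSE]
  n_ctrl <- min(nrow(balanced), max(nrow(imprinted), 1L))
  dmrs <- NULL
  dmr_summary <- NULL
  support <- NULL
  if (nrow(imprinted) || n_ctrl) {
    mk <- function(g, class, tag) {
      if (nrow(g) == 0L) return(NULL)
      data.frame(region_id = paste0(tag, "_", g$gene_id),
                 chrom = g$chrom,
                 start = g$start - 3000L, end = g$start - 1000L,
                 class = class, stringsAsFactors = FALSE)
    }
    ctrl <- utils::head(balanced, n_ctrl)
    half <- nrow(ctrl) %/% 2L
    dmrs <- rbind(
      mk(imprinted, "icr", "icr"),
      if (half > 0) mk(ctrl[seq_len(half), , drop = FALSE],
                       "unmethylated", "ctrl"),
      if (nrow(ctrl) > half) mk(ctrl[(half + 1):nrow(ctrl), , drop = FALSE],
                                "methylated", "ctrl")
    )
    meth <- simulate_methylation(dmrs, config)
    dmr_summary <- summarize_dmr(meth, dmrs)
    map <- data.frame(gene_id = imprinted$gene_id,
                      region_id = paste0("icr_", imprinted$gene_id),
                      stringsAsFactors = FALSE)
    support <- candidate_support(fit, dmr_summary, map)
  }
  manifest <- list(
    package = "imprintscan",
    version = as.character(utils::packageVersion("imprintscan")),
    config = unclass(config),
    thresholds = list(min_parental = min_parental,
                      parental_rule = parental_rule,
                      fdr_threshold = fdr_threshold,
                      major_share_threshold = major_share_threshold,
                      min_logcpm = min_logcpm,
                      min_individuals = min_individuals,
                      use_reads = use_reads),
    rows = list(genes = nrow(genes), counts = nrow(counts),
                filtered = nrow(filtered),
                results = nrow(fit$results),
                validation_results = nrow(vfit$results),
                dmr_summary = if (is.null(dmr_summary)) 0L
                              else nrow(dmr_summary)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  bundle <- structure(list(
    genes = genes, counts = counts, filtered = filtered,
    fit = fit, fit_validation = vfit, concordance = conc,
    single_parent = single_parent_genes(filtered),
    assignment_summary = if (nrow(counts)) summarize_assignment(counts)
                         else NULL,
    dmrs = dmrs, dmr_summary = dmr_summary, support = support,
    manifest = manifest
  ), class = "imprintscan_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    atomic_write(counts, file.path(out_dir, "counts.tsv"))
    atomic_write(fit$results, file.path(out_dir, "results.tsv"))
    atomic_write(vfit$results, file.path(out_dir, "results_validation.tsv"))
    if (!is.null(conc)) {
      atomic_write(conc$table, file.path(out_dir, "concordance.tsv"))
    }
    if (!is.null(dmr_summary)) {
      atomic_write(dmr_summary, file.path(out_dir, "dmr_summary.tsv"))
    }
    if (!is.null(support) && nrow(support)) {
      atomic_write(support, file.path(out_dir, "support.tsv"))
    }
    atomic_write(manifest, file.path(out_dir, "manifest.json"),
                 writer = function(x, p) {
                   jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                                        pretty = TRUE, null = "null")
                 })
  }
  bundle
}

#' Human-readable report of a pipeline run
#'
#' Markdown summary: per-category gene counts, top genes ordered by p-value
#' (ties broken by gene id), validation concordance and methylation
#' support. Ordering is deterministic.
#'
#' @param bundle An \code{imprintscan_run} from \code{\link{run_pipeline}}.
#' @param top_n Number of top genes to list (default 10).
#' @return Character vector of markdown lines (invisible when printed via
#'   \code{cat}).
#' @export
report <- function(bundle, top_n = 10L) {
  stopifnot(inherits(bundle, "imprintscan_run"))
  r <- bundle$fit$results
  lines <- c("# Parent-of-origin expression asymmetry report", "")
  cats <- c("single_parent", "candidate_imprinted", "asymmetric_only",
            "not_significant", "untestable")
  tab <- table(factor(r$category, levels = cats))
  lines <- c(lines, "## Gene categories", "",
             sprintf("- %s: %d", cats, as.integer(tab)), "")
  testable <- r[!is.na(r$p_value), , drop = FALSE]
  testable <- testable[order(testable$p_value, testable$gene_id), ,
                       drop = FALSE]
  top <- utils::head(testable, top_n)
  lines <- c(lines, "## Top genes by p-value", "")
  if (nrow(top)) {
    lines <- c(lines,
      "| gene | M>P | P>M | p | q | pooled major share | category |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %d | %d | %.3g | %.3g | %.3f | %s |",
              top$gene_id, top$n_mat_greater, top$n_pat_greater,
              top$p_value, top$q_value, top$pooled_major_share,
              top$category))
  } else {
    lines <- c(lines, "(no testable genes)")
  }
  if (!is.null(bundle$concordance)) {
    lines <- c(lines, "",
      sprintf("Validation direction concordance: %.3f (%d genes compared, %d untestable)",
              bundle$concordance$fraction,
              sum(!is.na(bundle$concordance$table$agree)),
              length(bundle$concordance$untestable)))
  }
  if (!is.null(bundle$support) && nrow(bundle$support)) {
    lines <- c(lines, "",
      sprintf("Methylation support: %d/%d candidate genes supported by a partially methylated region",
              sum(bundle$support$support == "supported"),
              nrow(bundle$support)))
  }
  lines
}

#' @export
print.imprintscan_run <- function(x, ...) {
  cat(report(x), sep = "\n")
  invisible(x)
}
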