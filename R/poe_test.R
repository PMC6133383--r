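#' Two-level exact binomial sign test for parent-of-origin expression
#' asymmetry
#'
#' For every gene, individuals with a parental gene count below
#' \code{min_parental} are dropped; each remaining individual contributes
#' only the sign of its binomial Z-score (\code{\link{individual_z}}), i.e.
#' whether maternal or paternal expression dominates. Exact ties
#' (\code{m == p}, \eqn{Z_i = 0}) are excluded. Under the null of symmetric
#' expression, the number of individuals favouring the maternal parent among
#' the \code{n} non-tied individuals is Binomial(n, 1/2); the gene-level
#' p-value is the exact two-sided test (\code{\link{sign_test_pvalue}}).
#' Because only signs are pooled, no overdispersion model is required.
#' P-values are adjusted by Benjamini-Hochberg (\code{\link{bh_fdr}}) and
#' genes are classified:
#' \describe{
#'   \item{single_parent}{pooled expression from exactly one parent
#'     (the other parent's pooled count is 0);}
#'   \item{candidate_imprinted}{\code{q < fdr_threshold} and the pooled
#'     majority-parent share is at least \code{major_share_threshold} --
#'     expression predominantly from one parental chromosome, as expected
#'     for (possibly leaky) imprinting;}
#'   \item{asymmetric_only}{\code{q < fdr_threshold} but substantial
#'     expression from both parents (e.g. a cis-eQTL on one haplotype);}
#'   \item{not_significant}{everything else;}
#'   \item{untestable}{no individual passes the count filter and tie
#'     exclusion (\code{n = 0}).}
#' }
#'
#' @param counts Parental count table with columns \code{individual_id},
#'   \code{gene_id}, \code{m}, \code{p} (a \code{u} column is allowed and
#'   ignored), typically from \code{\link{aggregate_counts}} +
#'   \code{\link{filter_genes}} or \code{\link{simulate_parental_counts}}.
#' @param min_parental Minimum parental gene count per individual
#'   (default 5); interpretation set by \code{parental_rule}.
#' @param parental_rule \code{"sum"} (default) requires \code{m + p >=
#'   min_parental}; \code{"each"} requires both \code{m >= min_parental} and
#'   \code{p >= min_parental}.
#' @param fdr_threshold FDR level for significance (default 0.05).
#' @param major_share_threshold Pooled majority-parent share required to
#'   call a significant gene \code{candidate_imprinted} (default 0.8).
#' @return An object of class \code{"poe_test"}: a list with
#'   \code{results} (one row per gene: \code{gene_id}, \code{n_mat_greater},
#'   \code{n_pat_greater}, \code{n}, \code{p_value}, \code{q_value},
#'   \code{majority_fraction}, \code{pooled_m}, \code{pooled_p},
#'   \code{pooled_major_share}, \code{direction}, \code{category}),
#'   the thresholds used, and the eligible counts (for plotting).
#'   Supports \code{print}, \code{summary}, \code{coef} and \code{plot}.
#' @examples
#' cfg <- sim_config(n_individuals = 60, n_genes = 40, seed = 42,
#'                   informative_rate = 0.5)
#' genes <- simulate_gene_specs(cfg)
#' counts <- simulate_parental_counts(cfg, genes)
#' fit <- poe_test(counts)
#' fit
#' head(coef(fit))
#' @export
poe_test <- function(counts, min_parental = 5L,
                     parental_rule = c("sum", "each"),
                     fdr_threshold = 0.05, major_share_threshold = 0.8) {
  parental_rule <- match.arg(parental_rule)
  stopifnot(is.data.frame(counts))
  need <- c("individual_id", "gene_id", "m", "p")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  if (min_parental < 1) stop("'min_parental' must be >= 1")
  res_cols <- c("gene_id", "n_mat_greater", "n_pat_greater", "n", "p_value",
                "q_value", "majority_fraction", "pooled_m", "pooled_p",
                "pooled_major_share", "direction", "category")
  if (nrow(counts) == 0L) {
    results <- as.data.frame(setNames(rep(list(character(0)), 1), "gene_id"),
                             stringsAsFactors = FALSE)
    results$n_mat_greater <- integer(0); results$n_pat_greater <- integer(0)
    results$n <- integer(0); results$p_value <- numeric(0)
    results$q_value <- numeric(0); results$majority_fraction <- numeric(0)
    results$pooled_m <- integer(0); results$pooled_p <- integer(0)
    results$pooled_major_share <- numeric(0)
    results$direction <- character(0); results$category <- character(0)
    return(structure(list(results = results[res_cols],
                          thresholds = list(min_parental = min_parental,
                                            parental_rule = parental_rule,
                                            fdr_threshold = fdr_threshold,
                                            major_share_threshold = major_share_threshold),
                          n_individuals = 0L, counts = counts),
                     class = "poe_test"))
  }
  eligible <- if (parental_rule == "sum") {
    counts$m + counts$p >= min_parental
  } else {
    counts$m >= min_parental & counts$p >= min_parental
  }
  gene_ids <- sort(unique(counts$gene_id))
  el <- counts[eligible, , drop = FALSE]
  gf <- factor(el$gene_id, levels = gene_ids)
  n_mat <- as.integer(rowsum(as.integer(el$m > el$p), gf)[, 1])
  n_pat <- as.integer(rowsum(as.integer(el$p > el$m), gf)[, 1])
  pooled_m <- as.integer(rowsum(el$m, gf)[, 1])
  pooled_p <- as.integer(rowsum(el$p, gf)[, 1])
  # rowsum drops empty levels only if present; guard via table alignment
  if (length(n_mat) != length(gene_ids)) {
    tab <- function(x) {
      v <- integer(length(gene_ids)); names(v) <- gene_ids
      s <- rowsum(x, gf); v[rownames(s)] <- s[, 1]; v
    }
    n_mat <- unname(tab(as.integer(el$m > el$p)))
    n_pat <- unname(tab(as.integer(el$p > el$m)))
    pooled_m <- unname(tab(el$m))
    pooled_p <- unname(tab(el$p))
  }
  n <- n_mat + n_pat
  testable <- n > 0
  p_value <- rep(NA_real_, length(gene_ids))
  p_value[testable] <- sign_test_pvalue(pmin(n_mat, n_pat)[testable],
                                        n[testable])
  q_value <- bh_fdr(p_value)
  majority_fraction <- ifelse(testable, pmax(n_mat, n_pat) / n, NA_real_)
  pooled_tot <- pooled_m + pooled_p
  pooled_major_share <- ifelse(pooled_tot > 0,
                               pmax(pooled_m, pooled_p) / pooled_tot,
                               NA_real_)
  direction <- ifelse(!testable, NA_character_,
               ifelse(n_mat > n_pat, "maternal",
               ifelse(n_pat > n_mat, "paternal", "none")))
  category <- rep("not_significant", length(gene_ids))
  category[!testable] <- "untestable"
  single <- testable & pooled_tot > 0 &
    (pooled_m == 0L | pooled_p == 0L) & pmax(pooled_m, pooled_p) > 0L
  sig <- testable & !is.na(q_value) & q_value < fdr_threshold
  category[sig] <- "asymmetric_only"
  category[sig & !is.na(pooled_major_share) &
             pooled_major_share >= major_share_threshold] <- "candidate_imprinted"
  category[single] <- "single_parent"
  results <- data.frame(
    gene_id = gene_ids,
    n_mat_greater = n_mat, n_pat_greater = n_pat, n = n,
    p_value = p_value, q_value = q_value,
    majority_fraction = majority_fraction,
    pooled_m = pooled_m, pooled_p = pooled_p,
    pooled_major_share = pooled_major_share,
    direction = direction, category = category,
    stringsAsFactors = FALSE
  )
  ord <- order(results$p_value, results$gene_id, na.last = TRUE)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  structure(list(
    results = results,
    thresholds = list(min_parental = as.integer(min_parental),
                      parental_rule = parental_rule,
                      fdr_threshold = fdr_threshold,
                      major_share_threshold = major_share_threshold),
    n_individuals = length(unique(counts$individual_id)),
    counts = counts
  ), class = "poe_test")
}

#' Test a single gene for parent-of-origin asymmetry
#'
#' Convenience wrapper running \code{\link{poe_test}} on the rows of one
#' gene (no FDR adjustment across genes; \code{q_value} equals
#' \code{p_value}).
#'
#' @param counts Parental count rows for one gene.
#' @param ... Passed to \code{\link{poe_test}}.
#' @return A one-row results data frame.
#' @export
test_gene <- function(counts, ...) {
  stopifnot(is.data.frame(counts))
  if (nrow(counts) && length(unique(counts$gene_id)) != 1L) {
    stop("test_gene() expects counts for exactly one gene")
  }
  poe_test(counts, ...)$results
}

#' @export
print.poe_test <- function(x, ...) {
  r <- x$results
  cat("Parent-of-origin expression asymmetry test (exact binomial sign test)\n")
  cat(sprintf("  %d gene(s), %d individual(s); min parental count %d (%s), FDR < %g\n",
              nrow(r), x$n_individuals, x$thresholds$min_parental,
              x$thresholds$parental_rule, x$thresholds$fdr_threshold))
  if (nrow(r)) {
    tab <- table(factor(r$category,
                        levels = c("single_parent", "candidate_imprinted",
                                   "asymmetric_only", "not_significant",
                                   "untestable")))
    cat("  categories:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
    top <- utils::head(r[!is.na(r$p_value), ], 5L)
    if (nrow(top)) {
      cat("  top genes by p-value:\n")
      print(top[, c("gene_id", "n_mat_greater", "n_pat_greater", "p_value",
                    "q_value", "category")], row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
summary.poe_test <- function(object, ...) {
  r <- object$results
  out <- list(
    thresholds = object$thresholds,
    n_individuals = object$n_individuals,
    n_genes = nrow(r),
    category_counts = table(factor(r$category,
      levels = c("single_parent", "candidate_imprinted", "asymmetric_only",
                 "not_significant", "untestable"))),
    significant = r[!is.na(r$q_value) &
                      r$q_value < object$thresholds$fdr_threshold, ,
                    drop = FALSE]
  )
  class(out) <- "summary.poe_test"
  out
}

#' @export
print.summary.poe_test <- function(x, ...) {
  cat(sprintf("poe_test summary: %d genes, %d individuals\n",
              x$n_genes, x$n_individuals))
  cat(sprintf("  FDR threshold %g, min parental %d (%s), major-share %g\n",
              x$thresholds$fdr_threshold, x$thresholds$min_parental,
              x$thresholds$parental_rule, x$thresholds$major_share_threshold))
  print(x$category_counts)
  cat(sprintf("  %d gene(s) significant at FDR < %g\n",
              nrow(x$significant), x$thresholds$fdr_threshold))
  if (nrow(x$significant)) {
    print(utils::head(x$significant[, c("gene_id", "n_mat_greater",
      "n_pat_greater", "p_value", "q_value", "pooled_major_share",
      "category")], 10L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.poe_test <- function(object, ...) {
  r <- object$results
  m <- as.matrix(r[, c("n_mat_greater", "n_pat_greater", "n", "p_value",
                       "q_value", "majority_fraction",
                       "pooled_major_share")])
  rownames(m) <- r$gene_id
  m
}

#' Plot a fitted parent-of-origin asymmetry test
#'
#' With \code{gene = NULL}, draws a diverging bar chart of the number of
#' individuals with more maternal (up) versus more paternal (down)
#' expression for each significant gene, ordered by the maternal-paternal
#' difference. With a gene id, draws the per-individual maternal versus
#' paternal count scatter for that gene.
#'
#' @param x A \code{poe_test} object.
#' @param gene Optional gene id.
#' @param ... Further graphical parameters (ignored).
#' @return Invisibly, the data plotted.
#' @export
plot.poe_test <- function(x, gene = NULL, ...) {
  r <- x$results
  if (!is.null(gene)) {
    cc <- x$counts[x$counts$gene_id == gene, , drop = FALSE]
    if (!nrow(cc)) stop("gene not found in counts: ", gene)
    lim <- range(c(cc$m, cc$p, 1))
    plot(cc$m, cc$p, xlab = "maternal count", ylab = "paternal count",
         main = gene, pch = 19, col = adjustcolor("navy", 0.6),
         xlim = lim, ylim = lim)
    abline(0, 1, lty = 2, col = "grey40")
    return(invisible(cc))
  }
  sig <- r[!is.na(r$q_value) & r$q_value < x$thresholds$fdr_threshold, ,
           drop = FALSE]
  if (!nrow(sig)) {
    plot.new(); text(0.5, 0.5, "no significant genes")
    return(invisible(sig))
  }
  sig <- sig[order(sig$n_mat_greater - sig$n_pat_greater), , drop = FALSE]
  h <- rbind(maternal = sig$n_mat_greater, paternal = -sig$n_pat_greater)
  bp <- barplot(h["maternal", ], ylim = range(c(h, 0)) * 1.1,
                names.arg = rep("", nrow(sig)), col = "firebrick",
                border = NA, ylab = "individuals (M>P up, P>M down)")
  barplot(h["paternal", ], add = TRUE, col = "grey50", border = NA,
          names.arg = rep("", nrow(sig)))
  text(bp, par("usr")[3], labels = sig$gene_id, srt = 60, adj = c(1, 1),
       xpd = TRUE, cex = 0.6)
  abline(h = 0)
  invisible(sig)
}

#' Direction concordance of asymmetry between two datasets
#'
#' Compares the dominant parental direction (more individuals with greater
#' maternal vs greater paternal expression) per gene between two fitted
#' \code{\link{poe_test}} objects (e.g. a discovery tissue and a validation
#' tissue). A gene agrees when \code{sign(n_mat_greater - n_pat_greater)}
#' is nonzero and equal in both datasets.
#'
#' @param fit_a,fit_b \code{poe_test} objects (or their \code{results} data
#'   frames) sharing gene ids.
#' @param genes Optional character vector restricting the comparison (e.g.
#'   the significant genes of the discovery dataset).
#' @return List with \code{table} (per-gene directions and agreement),
#'   \code{fraction} (agreement among genes testable in both with a nonzero
#'   direction), and \code{untestable} (gene ids excluded because either
#'   dataset lacked a direction).
#' @export
concordance <- function(fit_a, fit_b, genes = NULL) {
  ra <- if (inherits(fit_a, "poe_test")) fit_a$results else fit_a
  rb <- if (inherits(fit_b, "poe_test")) fit_b$results else fit_b
  stopifnot(is.data.frame(ra), is.data.frame(rb))
  shared <- intersect(ra$gene_id, rb$gene_id)
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) == 0L) stop("no shared genes between the two result sets")
  ia <- match(shared, ra$gene_id); ib <- match(shared, rb$gene_id)
  da <- sign(ra$n_mat_greater[ia] - ra$n_pat_greater[ia])
  db <- sign(rb$n_mat_greater[ib] - rb$n_pat_greater[ib])
  da[ra$n[ia] == 0L] <- NA; db[rb$n[ib] == 0L] <- NA
  usable <- !is.na(da) & !is.na(db) & da != 0 & db != 0
  agree <- usable & (da == db)
  tab <- data.frame(gene_id = shared,
                    direction_a = da, direction_b = db,
                    agree = ifelse(usable, agree, NA),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       fraction = if (any(usable)) mean(agree[usable]) else NA_real_,
       untestable = sort(shared[!usable]))
}
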