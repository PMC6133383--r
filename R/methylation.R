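# Methylation corroboration at imprinting control regions (ICRs).
#
# An ICR is methylated on exactly one parental chromosome, so in bulk
# tissue its CpGs sit near 50% methylation (beta between 0.25 and 0.75),
# unlike ordinary promoters/CpG islands which are near 0 or 1.

#' Convert methylation M-values to beta values
#'
#' \eqn{\beta = 2^M / (2^M + 1)}, the inverse of the logit2 transform
#' \eqn{M = \log_2(\beta / (1 - \beta))}; strictly increasing, mapping
#' \eqn{M = 0} to \eqn{\beta = 0.5}.
#'
#' @param M Numeric vector of finite M-values.
#' @return Beta values in (0, 1).
#' @examples
#' m_to_beta(0)        # 0.5
#' m_to_beta(log2(3))  # 0.75
#' @export
m_to_beta <- function(M) {
  if (length(M) == 0L) return(numeric(0))
  if (!is.numeric(M) || any(!is.finite(M))) stop("'M' must be finite numeric")
  # 2^M/(2^M+1) = 1/(1+2^-M): use the stable branch per sign
  ifelse(M >= 0, 1 / (1 + 2^(-M)), 2^M / (2^M + 1))
}

#' Convert beta values to M-values
#'
#' @param beta Numeric vector in (0, 1).
#' @return M-values; round-trips with \code{\link{m_to_beta}} to 1e-12.
#' @export
beta_to_m <- function(beta) {
  if (length(beta) == 0L) return(numeric(0))
  if (!is.numeric(beta) || any(!is.finite(beta)) ||
      any(beta <= 0 | beta >= 1)) {
    stop("'beta' must lie strictly inside (0, 1)")
  }
  log2(beta / (1 - beta))
}

#' Summarize CpG methylation within candidate imprinting control regions
#'
#' For each region, CpGs are intersected by coordinate (regions use BED
#' 0-based half-open starts; CpG positions are 1-based), each CpG is reduced
#' to its median beta across individuals (M-scaled records are converted
#' first), and \code{fraction_partial} is the share of region CpGs whose
#' median lies inside the partial-methylation band (inclusive endpoints).
#' A region is \code{consistent_with_imprinting} when it has at least
#' \code{min_cpgs} CpGs and \code{fraction_partial >= min_fraction};
#' regions with too few CpGs are \code{insufficient_cpgs}.
#'
#' @param cpgs CpG table: \code{cpg_id}, \code{chrom}, \code{pos} (1-based),
#'   \code{individual_id} (optional), \code{value}, \code{scale}
#'   (\code{"beta"} or \code{"M"}).
#' @param dmrs Region table: \code{region_id}, \code{chrom}, \code{start},
#'   \code{end} (BED 0-based half-open).
#' @param band Partial-methylation band, default \code{c(0.25, 0.75)}.
#' @param min_cpgs Minimum CpGs for a classifiable region (default 3).
#' @param min_fraction Minimum \code{fraction_partial} for consistency
#'   (default 0.5).
#' @return Data frame: \code{region_id}, \code{n_cpgs},
#'   \code{fraction_partial}, \code{classification}.
#' @export
summarize_dmr <- function(cpgs, dmrs, band = c(0.25, 0.75),
                          min_cpgs = 3L, min_fraction = 0.5) {
  stopifnot(is.data.frame(cpgs), is.data.frame(dmrs),
            length(band) == 2L, band[1] <= band[2])
  out <- data.frame(region_id = dmrs$region_id,
                    n_cpgs = 0L, fraction_partial = NA_real_,
                    classification = "insufficient_cpgs",
                    stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0L) return(out)
  if (nrow(cpgs) > 0L) {
    val <- cpgs$value
    if (!is.null(cpgs$scale)) {
      isM <- cpgs$scale == "M"
      if (any(isM)) val[isM] <- m_to_beta(val[isM])
    }
    key <- paste(cpgs$chrom, cpgs$pos, cpgs$cpg_id, sep = "\r")
    med <- tapply(val, key, stats::median)
    uk <- strsplit(names(med), "\r", fixed = TRUE)
    cpg_med <- data.frame(chrom = vapply(uk, `[`, character(1), 1L),
                          pos = as.integer(vapply(uk, `[`, character(1), 2L)),
                          beta = as.numeric(med), stringsAsFactors = FALSE)
    cg <- GenomicRanges::GRanges(cpg_med$chrom,
                                 IRanges::IRanges(cpg_med$pos, width = 1L))
    rg <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1L, dmrs$end))
    hits <- GenomicRanges::findOverlaps(cg, rg)
    if (length(hits)) {
      ri <- S4Vectors::subjectHits(hits)
      partial <- cpg_med$beta[S4Vectors::queryHits(hits)] >= band[1] &
                 cpg_med$beta[S4Vectors::queryHits(hits)] <= band[2]
      f <- factor(ri, levels = seq_len(nrow(dmrs)))
      n <- as.integer(table(f))
      s <- tapply(as.integer(partial), f, sum)
      npart <- as.integer(ifelse(is.na(s), 0L, s))
      out$n_cpgs <- n
      out$fraction_partial <- ifelse(n > 0, npart / n, NA_real_)
    }
  }
  out$classification <- ifelse(out$n_cpgs < min_cpgs, "insufficient_cpgs",
    ifelse(out$fraction_partial >= min_fraction,
           "consistent_with_imprinting", "not_consistent"))
  out
}

#' Join candidate imprinted genes with methylation support at mapped regions
#'
#' Candidate imprinted genes often lie in or near a characterized ICR of
#' their imprinted cluster (the region need not overlap the gene itself);
#' the gene-to-region map encodes that prior knowledge. A candidate is
#' \code{supported} when at least one mapped region is
#' \code{consistent_with_imprinting}, \code{unsupported} when all mapped
#' regions are inconsistent or have too few CpGs, and \code{unmapped} when
#' no region is mapped to it.
#'
#' @param fit A \code{\link{poe_test}} object or its results data frame.
#' @param dmr_summaries Output of \code{\link{summarize_dmr}}.
#' @param gene_region_map Data frame with columns \code{gene_id},
#'   \code{region_id}.
#' @param categories Result categories to corroborate (default
#'   \code{c("candidate_imprinted", "single_parent")}).
#' @return Data frame: \code{gene_id}, \code{category}, \code{region_id}
#'   (comma-joined when several), \code{support}.
#' @export
candidate_support <- function(fit, dmr_summaries, gene_region_map,
                              categories = c("candidate_imprinted",
                                             "single_parent")) {
  r <- if (inherits(fit, "poe_test")) fit$results else fit
  stopifnot(is.data.frame(r), is.data.frame(dmr_summaries),
            is.data.frame(gene_region_map))
  cand <- r[r$category %in% categories, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(gene_id = character(0), category = character(0),
                      region_id = character(0), support = character(0),
                      stringsAsFactors = FALSE))
  }
  support <- character(nrow(cand))
  regions <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rid <- gene_region_map$region_id[gene_region_map$gene_id == cand$gene_id[i]]
    if (length(rid) == 0L) {
      support[i] <- "unmapped"; regions[i] <- NA_character_
    } else {
      cls <- dmr_summaries$classification[match(rid, dmr_summaries$region_id)]
      support[i] <- if (any(cls == "consistent_with_imprinting", na.rm = TRUE))
        "supported" else "unsupported"
      regions[i] <- paste(rid, collapse = ",")
    }
  }
  out <- data.frame(gene_id = cand$gene_id, category = cand$category,
                    region_id = regions, support = support,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}
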