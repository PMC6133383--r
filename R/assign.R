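# Haplotype assignment of read observations and gene-level filters.
#
# A read is assignable only through "informative" SNPs: sites that are
# heterozygous in the individual and whose alleles have known parental
# origin. Matching observed alleles against the maternal and paternal
# haplotype yields the origin call; any ambiguity (conflicting SNPs, an
# allele matching neither haplotype, no informative SNP) is "unknown".

# Internal: per-call status against the phased haplotypes.
# Returns factor levels: mat / pat / mismatch / noninformative / nocall.
call_status <- function(reads, genotypes) {
  sites <- genotypes$sites
  n <- nrow(reads)
  status <- rep("nocall", n)
  has_call <- !is.na(reads$snp_id)
  if (any(has_call)) {
    si <- match(reads$snp_id[has_call], sites$snp_id)
    if (anyNA(si)) {
      stop("read observations reference unknown variant ids: ",
           paste(utils::head(unique(reads$snp_id[has_call][is.na(si)]), 3),
                 collapse = ", "))
    }
    ii <- match(reads$individual_id[has_call], genotypes$individuals)
    if (anyNA(ii)) stop("read observations reference unknown individuals")
    mat_code <- genotypes$maternal[cbind(si, ii)]
    pat_code <- genotypes$paternal[cbind(si, ii)]
    informative <- sites$po_known[si] & (mat_code != pat_code)
    obs <- reads$observed_allele[has_call]
    obs_code <- ifelse(obs == sites$ref[si], 0L,
                       ifelse(obs == sites$alt[si], 1L, NA_integer_))
    st <- rep("noninformative", sum(has_call))
    mm <- informative & is.na(obs_code)
    st[mm] <- "mismatch"
    st[informative & !is.na(obs_code) & obs_code == mat_code] <- "mat"
    st[informative & !is.na(obs_code) & obs_code == pat_code] <- "pat"
    # at an informative site obs_code equals one haplotype or is NA, so the
    # three assignments above are exhaustive
    status[has_call] <- st
  }
  status
}

#' Classify a single read observation as maternal, paternal or unknown
#'
#' A read is \code{maternal} if at least one informative SNP call matches
#' the maternal allele and none matches the paternal allele (symmetrically
#' for \code{paternal}); it is \code{unknown} if it covers no informative
#' SNP (homozygous sites or sites without parent-of-origin information), if
#' any call matches neither phased allele (likely sequencing error), or if
#' calls conflict across SNPs.
#'
#' @param read Data frame of allele calls for one read: columns
#'   \code{read_id}, \code{individual_id}, \code{snp_id},
#'   \code{observed_allele}. A read with no informative SNP may be given as
#'   a single row with \code{snp_id = NA}.
#' @param genotypes A \code{phased_genotypes} object.
#' @return One of \code{"maternal"}, \code{"paternal"}, \code{"unknown"}.
#' @export
classify_read <- function(read, genotypes) {
  stopifnot(is.data.frame(read), nrow(read) >= 1L,
            length(unique(read$read_id)) == 1L)
  st <- call_status(read, genotypes)
  n_mat <- sum(st == "mat"); n_pat <- sum(st == "pat")
  if (any(st == "mismatch")) return("unknown")
  if (n_mat > 0 && n_pat == 0) return("maternal")
  if (n_pat > 0 && n_mat == 0) return("paternal")
  "unknown"
}

#' Assign a table of read observations to parental origin
#'
#' Vectorized application of the \code{\link{classify_read}} rule to a full
#' read-record table (one row per allele call; reads covering no informative
#' SNP appear as a row with \code{snp_id = NA}).
#'
#' @param reads Read-record data frame: \code{read_id}, \code{individual_id},
#'   \code{gene_id}, \code{snp_id}, \code{observed_allele}.
#' @param genotypes A \code{phased_genotypes} object.
#' @return Data frame with one row per read: \code{read_id},
#'   \code{individual_id}, \code{gene_id}, \code{origin}.
#' @export
assign_reads <- function(reads, genotypes) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) {
    return(data.frame(read_id = character(0), individual_id = character(0),
                      gene_id = character(0), origin = character(0),
                      stringsAsFactors = FALSE))
  }
  st <- call_status(reads, genotypes)
  f <- factor(reads$read_id, levels = unique(reads$read_id))
  n_mat <- rowsum(as.integer(st == "mat"), f)[, 1]
  n_pat <- rowsum(as.integer(st == "pat"), f)[, 1]
  n_mm <- rowsum(as.integer(st == "mismatch"), f)[, 1]
  origin <- ifelse(n_mm > 0, "unknown",
            ifelse(n_mat > 0 & n_pat == 0, "maternal",
            ifelse(n_pat > 0 & n_mat == 0, "paternal", "unknown")))
  first <- !duplicated(f)
  data.frame(read_id = levels(f),
             individual_id = reads$individual_id[first],
             gene_id = reads$gene_id[first],
             origin = unname(origin),
             stringsAsFactors = FALSE)
}

#' Aggregate assigned reads to per-gene per-individual parental counts
#'
#' @param assigned Output of \code{\link{assign_reads}}.
#' @param genes Gene model table with a \code{gene_id} column; reads whose
#'   \code{gene_id} is absent are skipped with a warning reporting the count.
#' @return Parental count table (\code{individual_id}, \code{gene_id},
#'   \code{m}, \code{p}, \code{u}); \code{m + p + u} equals the number of
#'   retained reads in each cell.
#' @export
aggregate_counts <- function(assigned, genes) {
  stopifnot(is.data.frame(assigned), is.data.frame(genes))
  empty <- data.frame(individual_id = character(0), gene_id = character(0),
                      m = integer(0), p = integer(0), u = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(assigned) == 0L) return(empty)
  keep <- assigned$gene_id %in% genes$gene_id
  if (any(!keep)) {
    warning(sum(!keep), " read(s) skipped: gene id absent from gene models")
    assigned <- assigned[keep, , drop = FALSE]
  }
  if (nrow(assigned) == 0L) return(empty)
  key <- interaction(assigned$individual_id, assigned$gene_id, drop = TRUE,
                     sep = "\r")
  m <- rowsum(as.integer(assigned$origin == "maternal"), key)[, 1]
  p <- rowsum(as.integer(assigned$origin == "paternal"), key)[, 1]
  u <- rowsum(as.integer(assigned$origin == "unknown"), key)[, 1]
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(
    individual_id = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, `[`, character(1), 2L),
    m = as.integer(m), p = as.integer(p), u = as.integer(u),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id, out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expression and chromosome filters for the parental count table
#'
#' Removes genes on the X and Y chromosomes (imprinting tests are
#' confounded there by X-inactivation and hemizygosity), and retains a gene
#' only if its total expression reaches \code{log2(CPM) >= min_logcpm} in at
#' least \code{min_individuals} individuals. CPM uses the individual's
#' library size, i.e. the sum of \code{m + p + u} over all genes (computed
#' before any gene removal). Individuals with a zero library size are
#' excluded with a warning.
#'
#' @param counts Parental count table.
#' @param genes Gene models with \code{gene_id} and \code{chrom}.
#' @param min_logcpm log2-CPM threshold (default 1).
#' @param min_individuals Minimum number of individuals reaching the
#'   threshold (default 20).
#' @return The filtered count table.
#' @export
filter_genes <- function(counts, genes, min_logcpm = 1, min_individuals = 20L) {
  stopifnot(is.data.frame(counts), is.data.frame(genes))
  if (nrow(counts) == 0L) return(counts)
  chrom <- genes$chrom[match(counts$gene_id, genes$gene_id)]
  sex <- !is.na(chrom) & chrom %in% c("chrX", "chrY", "X", "Y")
  counts <- counts[!sex, , drop = FALSE]
  if (nrow(counts) == 0L) return(counts)
  total <- counts$m + counts$p + counts$u
  lib <- tapply(total, counts$individual_id, sum)
  zero <- names(lib)[lib == 0]
  if (length(zero)) {
    warning(length(zero), " individual(s) with zero library size excluded")
    keep_ind <- !(counts$individual_id %in% zero)
    counts <- counts[keep_ind, , drop = FALSE]
    total <- total[keep_ind]
  }
  if (nrow(counts) == 0L) return(counts)
  cpm <- total * 1e6 / as.numeric(lib[counts$individual_id])
  hit <- log2(cpm) >= min_logcpm
  n_ok <- tapply(hit, counts$gene_id, sum)
  keep_genes <- names(n_ok)[n_ok >= min_individuals]
  out <- counts[counts$gene_id %in% keep_genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary statistics for parental origin of transcripts
#'
#' Cohort-level summaries of how much expression could be assigned to a
#' parent: per-gene unknown-origin fraction and parental fraction, and
#' per-individual parental fraction, each with mean, SD and range.
#'
#' @param counts Parental count table (non-empty).
#' @return Data frame with columns \code{statistic}, \code{mean}, \code{sd},
#'   \code{min}, \code{max}.
#' @export
summarize_assignment <- function(counts) {
  stopifnot(is.data.frame(counts), nrow(counts) > 0L)
  total <- counts$m + counts$p + counts$u
  par <- counts$m + counts$p
  per_gene_tot <- tapply(total, counts$gene_id, sum)
  per_gene_par <- tapply(par, counts$gene_id, sum)
  per_ind_tot <- tapply(total, counts$individual_id, sum)
  per_ind_par <- tapply(par, counts$individual_id, sum)
  ok_g <- per_gene_tot > 0
  ok_i <- per_ind_tot > 0
  gene_unknown <- 1 - per_gene_par[ok_g] / per_gene_tot[ok_g]
  gene_parental <- per_gene_par[ok_g] / per_gene_tot[ok_g]
  ind_parental <- per_ind_par[ok_i] / per_ind_tot[ok_i]
  row <- function(name, x) {
    data.frame(statistic = name, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("per_gene_unknown_fraction", gene_unknown),
    row("per_gene_parental_fraction", gene_parental),
    row("per_individual_parental_fraction", ind_parental)
  )
  rownames(out) <- NULL
  out
}

#' Genes expressed from a single parental haplotype
#'
#' A gene is paternal-only if it has paternal expression in at least one
#' individual and no maternal expression in any individual; symmetrically
#' for maternal-only. The two lists are disjoint by construction.
#'
#' @param counts Parental count table (typically after
#'   \code{\link{filter_genes}}).
#' @return List with character vectors \code{paternal_only} and
#'   \code{maternal_only}.
#' @export
single_parent_genes <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (nrow(counts) == 0L) {
    return(list(paternal_only = character(0), maternal_only = character(0)))
  }
  sm <- tapply(counts$m, counts$gene_id, sum)
  sp <- tapply(counts$p, counts$gene_id, sum)
  list(
    paternal_only = sort(names(sp)[sp > 0 & sm == 0]),
    maternal_only = sort(names(sm)[sm > 0 & sp == 0])
  )
}
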