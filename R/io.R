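# File interchange: phased VCF, BED intervals, TSV tables.
#
# VCF has no standard for which phased allele is which parent, so the
# emitted files declare the convention in a header key
# (##haplotype_order=maternal|paternal) and readers refuse files that
# declare a different order. Sites whose alleles lack parent-of-origin
# information carry the INFO flag POUNK.

#' Write phased genotypes to VCF
#'
#' Emits a VCF 4.2 file with phased GT fields (\code{maternal|paternal},
#' declared by the \code{##haplotype_order} header key) and the INFO flag
#' \code{POUNK} on sites without parent-of-origin information.
#'
#' @param genotypes A \code{phased_genotypes} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_phased_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "phased_genotypes"))
  s <- genotypes$sites
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##haplotype_order=maternal|paternal",
    "##INFO=<ID=POUNK,Number=0,Type=Flag,Description=\"Parent of origin of alleles unknown at this site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype, maternal|paternal\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$individuals), collapse = "\t")
  )
  body <- character(0)
  if (nrow(s)) {
    gt <- matrix(paste0(genotypes$maternal, "|", genotypes$paternal),
                 nrow = nrow(s))
    body <- paste(s$chrom, s$pos, s$snp_id, s$ref, s$alt, ".", "PASS",
                  ifelse(s$po_known, ".", "POUNK"), "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read phased genotypes from VCF
#'
#' Parses a phased VCF written under the
#' \code{##haplotype_order=maternal|paternal} convention (the header key is
#' required) into a \code{phased_genotypes} object. Gene ids are assigned
#' to sites by coordinate overlap with the supplied gene models.
#'
#' @param path VCF file path.
#' @param genes Optional gene model table (\code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}; BED 0-based half-open) used to annotate
#'   sites with \code{gene_id}.
#' @return A \code{phased_genotypes} object.
#' @export
read_phased_vcf <- function(path, genes = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  ho <- grep("^##haplotype_order=", meta, value = TRUE)
  if (length(ho) == 0L) {
    stop("VCF lacks the ##haplotype_order header key; parental phase ambiguous")
  }
  if (!identical(sub("^##haplotype_order=", "", ho[1]), "maternal|paternal")) {
    stop("unsupported haplotype order: ", ho[1])
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  mat <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(fix))
  pat <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(fix))
  if (any(substr(gt, 2L, 2L) != "|")) {
    stop("unphased genotype encountered; phased GT (|) required")
  }
  sites <- data.frame(
    snp_id = fix$ID,
    gene_id = NA_character_,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    po_known = !grepl("(^|;)POUNK(;|$)",
                      ifelse(is.na(fix$INFO), ".", fix$INFO)),
    stringsAsFactors = FALSE
  )
  if (!is.null(genes) && nrow(sites)) {
    sg <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos, width = 1L))
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
    hits <- GenomicRanges::findOverlaps(sg, gg, select = "first")
    sites$gene_id <- genes$gene_id[hits]
  }
  structure(list(sites = sites, maternal = mat, paternal = pat,
                 individuals = colnames(gt) %||% character(0)),
            class = "phased_genotypes")
}

#' Write intervals as BED
#'
#' @param x Data frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and a name column (\code{gene_id} or
#'   \code{region_id}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- x$gene_id %||% x$region_id %||% rep(".", nrow(x))
  write.table(data.frame(x$chrom, x$start, x$end, name),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of named intervals
#'
#' @param path BED file path.
#' @param name_col Name for the 4th column (default \code{"gene_id"}).
#' @return Data frame: \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open, as in the file) and the name column.
#' @export
read_bed <- function(path, name_col = "gene_id") {
  b <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)[, 1:4]
  names(b) <- c("chrom", "start", "end", name_col)
  b[c(name_col, "chrom", "start", "end")]
}

#' Write a data frame as TSV
#' @param x Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by \code{\link{write_tsv}}
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# Write via a temporary file in the same directory, then rename: a crashed
# run never leaves a half-written table at the final path.
atomic_write <- function(x, path, writer = write_tsv) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(x, tmp)
  if (!file.rename(tmp, path)) stop("could not move output into place: ", path)
  invisible(path)
}
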