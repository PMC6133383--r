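# Small hand-built fixtures shared across test files.

# A phased_genotypes object from explicit pieces.
make_geno <- function(sites, maternal, paternal, individuals) {
  structure(list(sites = sites,
                 maternal = matrix(as.integer(maternal), nrow = nrow(sites)),
                 paternal = matrix(as.integer(paternal), nrow = nrow(sites)),
                 individuals = individuals),
            class = "phased_genotypes")
}

# Two individuals, four sites on one gene:
#   s1 het, po known          (informative; mat=A, pat=G for ind1)
#   s2 het, po known          (informative; mat=T, pat=C for ind1)
#   s3 homozygous, po known   (never informative)
#   s4 het, po unknown        (never informative)
toy_geno <- function() {
  sites <- data.frame(
    snp_id = c("s1", "s2", "s3", "s4"),
    gene_id = "g1",
    chrom = "chr1",
    pos = c(101L, 201L, 301L, 401L),
    ref = c("A", "T", "C", "G"),
    alt = c("G", "C", "T", "A"),
    po_known = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  make_geno(sites,
            maternal = cbind(c(0, 0, 1, 0), c(1, 1, 0, 1)),
            paternal = cbind(c(1, 1, 1, 1), c(0, 0, 0, 0)),
            individuals = c("i1", "i2"))
}

one_read <- function(read_id, individual_id, snp_id, observed_allele,
                     gene_id = "g1") {
  data.frame(read_id = read_id, individual_id = individual_id,
             gene_id = gene_id, snp_id = snp_id,
             observed_allele = observed_allele, stringsAsFactors = FALSE)
}

# Parental count table from a compact per-gene matrix spec:
# rows = individuals, entries = list(m=..., p=..., u=...)
make_counts <- function(gene_id, m, p, u = rep(0L, length(m)),
                        individuals = sprintf("i%02d", seq_along(m))) {
  data.frame(individual_id = individuals, gene_id = gene_id,
             m = as.integer(m), p = as.integer(p), u = as.integer(u),
             stringsAsFactors = FALSE)
}

# Brute-force read classifier: enumerates the two haplotype sequences over
# the read's called sites and checks which are fully consistent. Written
# independently of the vectorized implementation.
brute_classify <- function(read, geno) {
  calls <- read[!is.na(read$snp_id), , drop = FALSE]
  if (nrow(calls) == 0L) return("unknown")
  ind <- match(calls$individual_id[1], geno$individuals)
  si <- match(calls$snp_id, geno$sites$snp_id)
  informative <- geno$sites$po_known[si] &
    geno$maternal[cbind(si, ind)] != geno$paternal[cbind(si, ind)]
  calls <- calls[informative, , drop = FALSE]
  si <- si[informative]
  if (nrow(calls) == 0L) return("unknown")
  allele_of <- function(code, j) {
    ifelse(code == 0L, geno$sites$ref[j], geno$sites$alt[j])
  }
  mat_seq <- allele_of(geno$maternal[cbind(si, ind)], si)
  pat_seq <- allele_of(geno$paternal[cbind(si, ind)], si)
  if (any(calls$observed_allele != mat_seq &
          calls$observed_allele != pat_seq)) {
    return("unknown")
  }
  mat_ok <- all(calls$observed_allele == mat_seq)
  pat_ok <- all(calls$observed_allele == pat_seq)
  if (mat_ok && !pat_ok) "maternal"
  else if (pat_ok && !mat_ok) "paternal"
  else "unknown"
}
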