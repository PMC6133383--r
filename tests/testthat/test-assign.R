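test_that("classify_read follows the informative-SNP matching rules", {
  geno <- toy_geno()
  # one informative SNP matching the maternal allele
  expect_equal(classify_read(one_read("r1", "i1", "s1", "A"), geno),
               "maternal")
  expect_equal(classify_read(one_read("r2", "i1", "s1", "G"), geno),
               "paternal")
  # two informative SNPs, one maternal-matching, one paternal-matching:
  # conflict -> unknown
  conflict <- rbind(one_read("r3", "i1", "s1", "A"),
                    one_read("r3", "i1", "s2", "C"))
  expect_equal(classify_read(conflict, geno), "unknown")
  # read covering only a homozygous SNP -> unknown
  expect_equal(classify_read(one_read("r4", "i1", "s3", "T"), geno),
               "unknown")
  # read covering only a site without parent-of-origin info -> unknown
  expect_equal(classify_read(one_read("r5", "i1", "s4", "G"), geno),
               "unknown")
  # allele matching neither haplotype (sequencing error) -> unknown,
  # even alongside a clean maternal match
  err <- rbind(one_read("r6", "i1", "s1", "A"),
               one_read("r6", "i1", "s2", "G"))
  expect_equal(classify_read(err, geno), "unknown")
  # no informative SNP covered at all
  expect_equal(classify_read(one_read("r7", "i1", NA, NA), geno), "unknown")
  # unknown variant id is an input error
  expect_error(classify_read(one_read("r8", "i1", "nope", "A"), geno),
               "unknown variant")
  # phase differs per individual: same allele, other parent for i2
  expect_equal(classify_read(one_read("r9", "i2", "s1", "A"), geno),
               "paternal")
})

test_that("classify_read agrees with a brute-force haplotype enumerator", {
  cfg <- sim_config(n_individuals = 6, n_genes = 8, seed = 77,
                    n_het_snps = 4, het_freq = 0.6,
                    po_unknown_fraction = 0.2)
  g <- simulate_gene_specs(cfg)
  geno <- simulate_phased_genotypes(cfg, g, ensure_informative = FALSE)
  set.seed(99)
  bases <- c("A", "C", "G", "T")
  for (i in 1:1000) {
    ind <- sample(geno$individuals, 1)
    gene <- sample(g$gene_id, 1)
    srows <- which(geno$sites$gene_id == gene)
    ncall <- sample(1:3, 1)
    picks <- sample(srows, min(ncall, length(srows)))
    # mostly real haplotype alleles, sometimes a random base
    obs <- vapply(picks, function(s) {
      if (runif(1) < 0.15) sample(bases, 1)
      else {
        code <- if (runif(1) < 0.5) geno$maternal[s, match(ind, geno$individuals)]
                else geno$paternal[s, match(ind, geno$individuals)]
        if (code == 0) geno$sites$ref[s] else geno$sites$alt[s]
      }
    }, character(1))
    read <- data.frame(read_id = "rx", individual_id = ind, gene_id = gene,
                       snp_id = geno$sites$snp_id[picks],
                       observed_allele = obs, stringsAsFactors = FALSE)
    expect_equal(classify_read(read, geno), brute_classify(read, geno),
                 label = paste("case", i))
  }
})

test_that("aggregate_counts counts origins per cell and conserves reads", {
  geno <- toy_geno()
  reads <- rbind(
    do.call(rbind, lapply(1:3, function(i) one_read(paste0("m", i), "i1", "s1", "A"))),
    one_read("p1", "i1", "s1", "G"),
    do.call(rbind, lapply(1:6, function(i) one_read(paste0("u", i), "i1", "s3", "T")))
  )
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 0L,
                      end = 1000L, stringsAsFactors = FALSE)
  cnt <- aggregate_counts(assign_reads(reads, geno), genes)
  expect_equal(cnt$m, 3L)
  expect_equal(cnt$p, 1L)
  expect_equal(cnt$u, 6L)
  expect_equal(cnt$m + cnt$p + cnt$u, 10L)
  # empty read table -> empty counts
  empty <- aggregate_counts(
    assign_reads(reads[0, ], geno), genes)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("individual_id", "gene_id", "m", "p", "u"))
  # reads with an absent gene id are skipped with a warning
  stray <- one_read("x1", "i1", "s1", "A", gene_id = "gX")
  expect_warning(
    cnt2 <- aggregate_counts(assign_reads(rbind(reads, stray), geno), genes),
    "skipped")
  expect_equal(sum(cnt2$m + cnt2$p + cnt2$u), 10L)
})

test_that("synthetic reads round-trip to the simulator counts exactly", {
  cfg <- sim_config(n_individuals = 15, n_genes = 8, seed = 41,
                    informative_rate = 0.25, mean_depth = 6)
  g <- simulate_gene_specs(cfg)
  cnt <- simulate_parental_counts(cfg, g)
  geno <- simulate_phased_genotypes(cfg, g)
  rec <- aggregate_counts(assign_reads(simulate_reads(cnt, geno), geno), g)
  expected <- cnt[cnt$m + cnt$p + cnt$u > 0, ]
  expected <- expected[order(expected$gene_id, expected$individual_id), ]
  rownames(expected) <- NULL
  expect_identical(rec, expected)
})

test_that("parent swap exchanges m and p and the single-parent lists", {
  cfg <- sim_config(n_individuals = 12, n_genes = 10, seed = 6,
                    informative_rate = 0.3, mean_depth = 8,
                    class_mixture = c(imprinted_maternal_silenced = 0.3,
                                      imprinted_paternal_silenced = 0.3,
                                      biallelic_balanced = 0.4))
  g <- simulate_gene_specs(cfg)
  cnt <- simulate_parental_counts(cfg, g)
  geno <- simulate_phased_genotypes(cfg, g)
  reads <- simulate_reads(cnt, geno)
  swapped <- geno
  swapped$maternal <- geno$paternal
  swapped$paternal <- geno$maternal
  a <- aggregate_counts(assign_reads(reads, geno), g)
  b <- aggregate_counts(assign_reads(reads, swapped), g)
  expect_identical(a$m, b$p)
  expect_identical(a$p, b$m)
  expect_identical(a$u, b$u)
  la <- single_parent_genes(a); lb <- single_parent_genes(b)
  expect_identical(la$maternal_only, lb$paternal_only)
  expect_identical(la$paternal_only, lb$maternal_only)
})

test_that("filter_genes removes sex chromosomes and low-expressed genes at the boundary", {
  # 306 individuals; library size 1e6 per individual so CPM == count
  n_ind <- 306
  inds <- sprintf("i%03d", 1:n_ind)
  mk_gene <- function(gene_id, expr_in) {
    u <- ifelse(seq_len(n_ind) <= expr_in, 2L, 1L)  # log2CPM 1 vs 0
    data.frame(individual_id = inds, gene_id = gene_id, m = 0L, p = 0L,
               u = u, stringsAsFactors = FALSE)
  }
  filler <- data.frame(individual_id = inds, gene_id = "gBig", m = 0L,
                       p = 0L, u = 1000000L - 5L, stringsAsFactors = FALSE)
  counts <- rbind(mk_gene("gKeep", 20), mk_gene("gDrop", 19),
                  mk_gene("gZero", 0), mk_gene("gX", 306), filler)
  counts$u[counts$gene_id == "gZero"] <- 0L
  # top up each library to exactly 1e6
  lib <- tapply(counts$m + counts$p + counts$u, counts$individual_id, sum)
  counts$u[counts$gene_id == "gBig"] <-
    counts$u[counts$gene_id == "gBig"] + (1000000L - as.integer(lib[inds]))
  genes <- data.frame(gene_id = c("gKeep", "gDrop", "gZero", "gX", "gBig"),
                      chrom = c("chr1", "chr1", "chr1", "chrX", "chr2"),
                      stringsAsFactors = FALSE)
  out <- filter_genes(counts, genes)
  kept <- unique(out$gene_id)
  expect_true("gKeep" %in% kept)    # log2CPM >= 1 in exactly 20 individuals
  expect_false("gDrop" %in% kept)   # ... in only 19
  expect_false("gZero" %in% kept)   # all-zero gene
  expect_false("gX" %in% kept)      # chrX removed regardless of expression
  expect_true("gBig" %in% kept)
})

test_that("summarize_assignment reports parental and unknown fractions", {
  cnt <- make_counts("g1", m = 1, p = 1, u = 8)
  s <- summarize_assignment(cnt)
  expect_equal(s$mean[s$statistic == "per_gene_parental_fraction"], 0.2)
  expect_equal(s$mean[s$statistic == "per_gene_unknown_fraction"], 0.8)
  cnt2 <- rbind(make_counts("g1", m = 3, p = 4, u = 0),
                make_counts("g2", m = 1, p = 0, u = 0))
  s2 <- summarize_assignment(cnt2)
  expect_true(all(s2$mean[s2$statistic != "per_gene_unknown_fraction"] == 1))
  # simulator calibration: mean per-gene parental fraction ~ informative_rate
  cfg <- sim_config(n_individuals = 30, n_genes = 300, seed = 15,
                    informative_rate = 0.018)
  s3 <- summarize_assignment(simulate_parental_counts(cfg,
                                                      simulate_gene_specs(cfg)))
  expect_lt(abs(s3$mean[s3$statistic == "per_gene_parental_fraction"] - 0.018),
            0.005)
})

test_that("single_parent_genes builds disjoint lists and honours any maternal read", {
  cnt <- rbind(
    make_counts("gPat", m = c(0, 0), p = c(4, 0)),
    make_counts("gNot", m = c(1, 0), p = c(4, 3)),
    make_counts("gMat", m = c(2, 1), p = c(0, 0))
  )
  l <- single_parent_genes(cnt)
  expect_equal(l$paternal_only, "gPat")
  expect_equal(l$maternal_only, "gMat")
  expect_length(intersect(l$paternal_only, l$maternal_only), 0)
  # fully imprinted simulated genes are all recovered on the correct side
  cfg <- sim_config(n_individuals = 40, n_genes = 20, seed = 12,
                    class_mixture = c(imprinted_maternal_silenced = 0.5,
                                      imprinted_paternal_silenced = 0.5),
                    informative_rate = 0.2)
  g <- simulate_gene_specs(cfg)
  sim <- simulate_parental_counts(cfg, g)
  ls <- single_parent_genes(sim)
  expect_setequal(ls$paternal_only,
                  g$gene_id[g$silenced_parent == "maternal"])
  expect_setequal(ls$maternal_only,
                  g$gene_id[g$silenced_parent == "paternal"])
})
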