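test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(class_mixture = c(biallelic_balanced = 0.5)),
               "sum to 1")
  expect_error(sim_config(class_mixture = c(bogus = 1)), "known gene classes")
  expect_error(sim_config(leak_rate = 0.5), "leak_rate")
  expect_error(sim_config(eqtl_ratio = 1), "eqtl_ratio")
  expect_error(sim_config(informative_rate = 0), "informative_rate")
})

test_that("gene specs follow the mixture deterministically and imprinted classes have one silenced parent", {
  cfg <- sim_config(n_genes = 200, seed = 9)
  g <- simulate_gene_specs(cfg)
  expect_equal(nrow(g), 200)
  tab <- table(g$class_label)
  expect_equal(as.integer(tab[["biallelic_balanced"]]), 180)
  expect_equal(as.integer(tab[["biallelic_eqtl"]]), 10)
  imp <- g[g$class_label %in% c("imprinted_maternal_silenced",
                                "imprinted_paternal_silenced",
                                "leaky_imprinted"), ]
  expect_true(all(imp$silenced_parent %in% c("maternal", "paternal")))
  expect_true(all(is.na(g$silenced_parent[startsWith(g$class_label, "biallelic")])))
  expect_true(all(g$leak_rate[g$class_label == "imprinted_maternal_silenced"] == 0))
  # identical config => identical output
  expect_identical(g, simulate_gene_specs(sim_config(n_genes = 200, seed = 9)))
})

test_that("simulator output is byte-identical under a fixed seed", {
  cfg <- sim_config(n_individuals = 2, n_genes = 1,
                    class_mixture = c(biallelic_balanced = 1),
                    n_het_snps = 1, seed = 7)
  g <- simulate_gene_specs(cfg)
  run_once <- function() {
    geno <- simulate_phased_genotypes(cfg, g)
    cnt <- simulate_parental_counts(cfg, g)
    f1 <- tempfile(); f2 <- tempfile()
    write_phased_vcf(geno, f1)
    write_tsv(cnt, f2)
    on.exit(unlink(c(f1, f2)))
    list(vcf = readLines(f1), tsv = readLines(f2))
  }
  expect_identical(run_once(), run_once())
})

test_that("parent-of-origin-unknown site flagging matches its configured rate", {
  # 2,000 genes x 5 SNPs = 10,000 sites at unknown-fraction 0.10
  cfg <- sim_config(n_individuals = 2, n_genes = 2000, n_het_snps = 5,
                    po_unknown_fraction = 0.10, seed = 21)
  geno <- simulate_phased_genotypes(cfg, simulate_gene_specs(cfg))
  frac <- mean(!geno$sites$po_known)
  expect_equal(nrow(geno$sites), 10000)
  expect_lt(abs(frac - 0.10), 0.01)
})

test_that("unknown-fraction 1 makes every downstream read unknown", {
  cfg <- sim_config(n_individuals = 4, n_genes = 3, seed = 2,
                    po_unknown_fraction = 1, informative_rate = 0.5,
                    mean_depth = 5)
  g <- simulate_gene_specs(cfg)
  geno <- simulate_phased_genotypes(cfg, g)
  cnt <- simulate_parental_counts(cfg, g)
  expect_true(all(!geno$sites$po_known))
  reads <- suppressWarnings(simulate_reads(cnt, geno))
  assigned <- assign_reads(reads, geno)
  expect_true(all(assigned$origin == "unknown"))
})

test_that("counts conserve totals and fully imprinted genes are silent on one side", {
  cfg <- sim_config(n_individuals = 50, n_genes = 20, seed = 13,
                    class_mixture = c(imprinted_maternal_silenced = 0.5,
                                      imprinted_paternal_silenced = 0.5),
                    informative_rate = 0.2)
  g <- simulate_gene_specs(cfg)
  cnt <- simulate_parental_counts(cfg, g)
  expect_true(all(cnt$m >= 0 & cnt$p >= 0 & cnt$u >= 0))
  # leak 0: the silenced parent's count is exactly zero everywhere
  sil <- g$silenced_parent[match(cnt$gene_id, g$gene_id)]
  expect_true(all(cnt$m[sil == "maternal"] == 0))
  expect_true(all(cnt$p[sil == "paternal"] == 0))
})

test_that("pooled maternal share is calibrated for a balanced gene at cohort scale", {
  cfg <- sim_config(n_individuals = 306, n_genes = 10, seed = 1,
                    class_mixture = c(biallelic_balanced = 1),
                    mean_depth = 50)
  cnt <- simulate_parental_counts(cfg, simulate_gene_specs(cfg))
  share <- sum(cnt$m) / sum(cnt$m + cnt$p)
  expect_lt(abs(share - 0.5), 0.01)
})

test_that("per-class pooled maternal share converges to its parameter at high depth", {
  cfg <- sim_config(n_individuals = 50, n_genes = 8, seed = 5,
                    class_mixture = c(biallelic_balanced = 0.25,
                                      leaky_imprinted = 0.25,
                                      imprinted_paternal_silenced = 0.25,
                                      biallelic_eqtl = 0.25),
                    mean_depth = 1e4, informative_rate = 0.5,
                    leak_rate = 0.05, eqtl_ratio = 0.7,
                    regulator_het_freq = 1)
  g <- simulate_gene_specs(cfg)
  cnt <- simulate_parental_counts(cfg, g)
  cls <- g$class_label[match(cnt$gene_id, g$gene_id)]
  sil <- g$silenced_parent[match(cnt$gene_id, g$gene_id)]
  share <- function(sel) sum(cnt$m[sel]) / sum(cnt$m[sel] + cnt$p[sel])
  expect_lt(abs(share(cls == "biallelic_balanced") - 0.5), 0.01)
  # fully imprinted: leak 0, silenced parent exactly silent
  expect_identical(share(cls == "imprinted_paternal_silenced"), 1)
  expect_lt(abs(share(cls == "biallelic_eqtl") - 0.7), 0.01)
  for (gid in g$gene_id[g$class_label == "leaky_imprinted"]) {
    expected <- if (g$silenced_parent[g$gene_id == gid] == "maternal")
      0.05 else 0.95
    expect_lt(abs(share(cnt$gene_id == gid) - expected), 0.01)
  }
})

test_that("mean per-gene unknown-origin fraction matches the informative rate", {
  # informative_rate 0.018: mean unknown fraction ~0.982 over 500 genes
  cfg <- sim_config(n_individuals = 30, n_genes = 500, seed = 4,
                    informative_rate = 0.018, mean_depth = 50)
  cnt <- simulate_parental_counts(cfg, simulate_gene_specs(cfg))
  tot <- tapply(cnt$m + cnt$p + cnt$u, cnt$gene_id, sum)
  par <- tapply(cnt$m + cnt$p, cnt$gene_id, sum)
  expect_lt(abs(mean(1 - par / tot) - 0.982), 0.005)
})

test_that("read simulation round-trips through assignment and flags forced cases", {
  cfg <- sim_config(n_individuals = 10, n_genes = 5, seed = 31,
                    informative_rate = 0.3, mean_depth = 4)
  g <- simulate_gene_specs(cfg)
  cnt <- simulate_parental_counts(cfg, g)
  geno <- simulate_phased_genotypes(cfg, g)
  reads <- simulate_reads(cnt, geno)
  # m=3, p=0, u=2 style forced check on one populated cell
  cell <- cnt[cnt$m + cnt$p + cnt$u > 0, ][1, ]
  rr <- reads[reads$individual_id == cell$individual_id &
              reads$gene_id == cell$gene_id, ]
  expect_equal(nrow(rr), cell$m + cell$p + cell$u)
  assigned <- assign_reads(rr, geno)
  expect_equal(sum(assigned$origin == "maternal"), cell$m)
  expect_equal(sum(assigned$origin == "paternal"), cell$p)
})

test_that("injected allele-flip error misclassifies reads at about its rate", {
  cfg <- sim_config(n_individuals = 10, n_genes = 4, seed = 8,
                    informative_rate = 1, mean_depth = 25)
  g <- simulate_gene_specs(cfg)
  cnt <- simulate_parental_counts(cfg, g)
  geno <- simulate_phased_genotypes(cfg, g)
  clean <- assign_reads(simulate_reads(cnt, geno, error_rate = 0), geno)
  noisy <- assign_reads(simulate_reads(cnt, geno, error_rate = 0.01), geno)
  expect_gt(nrow(clean), 900)
  wrong <- mean(noisy$origin != clean$origin)
  # a flipped allele lands on the other haplotype: error rate ~1%, bound 2%
  expect_lte(wrong, 0.02)
  expect_gt(wrong, 0)  # at ~1,000 reads some flips are expected
})

test_that("simulated methylation respects its class structure", {
  dmrs <- data.frame(region_id = c("icr1", "low1", "high1"),
                     chrom = "chr1",
                     start = c(1000L, 5000L, 9000L),
                     end = c(2000L, 6000L, 10000L),
                     class = c("icr", "unmethylated", "methylated"),
                     stringsAsFactors = FALSE)
  cfg0 <- sim_config(seed = 3, methylation_noise_sd = 0,
                     n_individuals_validation = 5)
  meth0 <- simulate_methylation(dmrs, cfg0)
  expect_true(all(meth0$value[startsWith(meth0$cpg_id, "cpg0000")] %in%
                    c(0.5, 0.05, 0.95)))
  icr0 <- meth0$value[meth0$pos > 1000 & meth0$pos <= 2000]
  expect_true(all(icr0 == 0.5))          # zero noise: exactly 0.5
  cfg <- sim_config(seed = 3, methylation_noise_sd = 0.05,
                    n_individuals_validation = 10)
  icr_many <- simulate_methylation(
    data.frame(region_id = sprintf("icr%03d", 1:25), chrom = "chr2",
               start = seq(0L, by = 10000L, length.out = 25),
               end = seq(1000L, by = 10000L, length.out = 25),
               class = "icr", stringsAsFactors = FALSE), cfg)
  # >= 99% of ICR CpG draws inside the partial band (Gaussian tail at 5 sd)
  expect_gte(mean(icr_many$value >= 0.25 & icr_many$value <= 0.75), 0.99)
  expect_true(all(icr_many$value >= 0 & icr_many$value <= 1))
  low <- simulate_methylation(dmrs[2, ], cfg)
  expect_lt(median(low$value), 0.25)     # unmethylated stays near 0
  expect_error(simulate_methylation(
    data.frame(region_id = c("a", "b"), chrom = "chr1",
               start = c(0L, 500L), end = c(1000L, 1500L),
               class = "icr", stringsAsFactors = FALSE), cfg),
    "non-overlapping")
})
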