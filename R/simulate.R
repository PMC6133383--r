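#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. Defaults emulate
#' the study conditions of a large founder-population LCL cohort: 306
#' individuals, sparse informative heterozygous SNPs so that on average only
#' about 1.8\% of transcripts per gene can be assigned to a parent, and a
#' gene-class mixture dominated by balanced biallelic expression.
#'
#' @param n_individuals Number of individuals in the cohort (default 306).
#' @param n_genes Number of genes to simulate.
#' @param seed Integer seed; together with the config it fully determines
#'   all simulator output.
#' @param class_mixture Named numeric vector of gene-class proportions over
#'   \code{imprinted_maternal_silenced}, \code{imprinted_paternal_silenced},
#'   \code{leaky_imprinted}, \code{biallelic_balanced},
#'   \code{biallelic_eqtl}. Must sum to 1 (within 1e-9).
#' @param mean_depth Expected informative (parentally assignable) transcript
#'   count per individual per gene.
#' @param n_het_snps Number of exonic SNP sites simulated per gene.
#' @param informative_rate Probability that a transcript covers an
#'   informative SNP; its complement is the unknown-origin fraction
#'   (default 0.018, matching a cohort where ~98\% of transcripts cannot be
#'   assigned to a parent).
#' @param leak_rate Expected share of parental expression from the silenced
#'   haplotype for \code{leaky_imprinted} genes; must be < 0.5. Fully
#'   imprinted classes use leak 0.
#' @param eqtl_ratio Expected maternal share for \code{biallelic_eqtl} genes
#'   in individuals heterozygous for the simulated regulatory variant; in
#'   (0, 1).
#' @param dispersion Negative-binomial dispersion of total transcript counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson totals.
#' @param het_freq Probability that an individual is heterozygous at a
#'   simulated SNP site.
#' @param po_unknown_fraction Fraction of SNP sites flagged
#'   parent-of-origin-unknown (site-level; such sites are never
#'   informative).
#' @param regulator_het_freq Probability that an individual is heterozygous
#'   for the regulatory variant of a \code{biallelic_eqtl} gene.
#' @param methylation_noise_sd Standard deviation of beta-scale noise for
#'   simulated CpG methylation.
#' @param n_individuals_validation Cohort size for the simulated validation
#'   tissue (default 99).
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_individuals = 306L,
                       n_genes = 1000L,
                       seed = 1L,
                       class_mixture = c(biallelic_balanced = 0.90,
                                         biallelic_eqtl = 0.05,
                                         imprinted_maternal_silenced = 0.02,
                                         imprinted_paternal_silenced = 0.02,
                                         leaky_imprinted = 0.01),
                       mean_depth = 50,
                       n_het_snps = 5L,
                       informative_rate = 0.018,
                       leak_rate = 0.05,
                       eqtl_ratio = 0.7,
                       dispersion = 0.2,
                       het_freq = 0.5,
                       po_unknown_fraction = 0.10,
                       regulator_het_freq = 0.5,
                       methylation_noise_sd = 0.05,
                       n_individuals_validation = 99L) {
  if (n_individuals < 1 || n_genes < 0) {
    stop("'n_individuals' must be >= 1 and 'n_genes' >= 0")
  }
  known <- c("imprinted_maternal_silenced", "imprinted_paternal_silenced",
             "leaky_imprinted", "biallelic_balanced", "biallelic_eqtl")
  if (is.null(names(class_mixture)) || !all(names(class_mixture) %in% known)) {
    stop("'class_mixture' must be named with known gene classes")
  }
  if (abs(sum(class_mixture) - 1) > 1e-9) {
    stop("'class_mixture' proportions must sum to 1")
  }
  if (any(class_mixture < 0)) stop("'class_mixture' proportions must be >= 0")
  if (leak_rate < 0 || leak_rate >= 0.5) stop("'leak_rate' must be in [0, 0.5)")
  if (eqtl_ratio <= 0 || eqtl_ratio >= 1) stop("'eqtl_ratio' must be in (0, 1)")
  if (informative_rate <= 0 || informative_rate > 1) {
    stop("'informative_rate' must be in (0, 1]")
  }
  if (po_unknown_fraction < 0 || po_unknown_fraction > 1) {
    stop("'po_unknown_fraction' must be in [0, 1]")
  }
  if (mean_depth <= 0) stop("'mean_depth' must be positive")
  if (n_het_snps < 1) stop("'n_het_snps' must be >= 1")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (het_freq <= 0 || het_freq > 1) stop("'het_freq' must be in (0, 1]")
  if (methylation_noise_sd < 0) stop("'methylation_noise_sd' must be >= 0")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_genes = as.integer(n_genes),
    seed = as.integer(seed),
    class_mixture = class_mixture,
    mean_depth = mean_depth,
    n_het_snps = as.integer(n_het_snps),
    informative_rate = informative_rate,
    leak_rate = leak_rate,
    eqtl_ratio = eqtl_ratio,
    dispersion = dispersion,
    het_freq = het_freq,
    po_unknown_fraction = po_unknown_fraction,
    regulator_het_freq = regulator_het_freq,
    methylation_noise_sd = methylation_noise_sd,
    n_individuals_validation = as.integer(n_individuals_validation)
  ), class = "sim_config")
}

sim_individual_ids <- function(n) sprintf("ind%04d", seq_len(n))

#' Generate per-gene ground-truth class specifications
#'
#' Assigns each simulated gene a class (fully imprinted with the maternal or
#' paternal copy silenced, leaky imprinted, balanced biallelic, or biallelic
#' with a cis-eQTL imbalance), a silenced parent where applicable, and the
#' count-model parameters. Class counts follow the configured mixture by
#' largest-remainder apportionment so the realized composition is
#' deterministic given the config.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A data frame with one row per gene: \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (BED-style 0-based half-open), \code{class_label},
#'   \code{silenced_parent} (\code{NA} for biallelic classes),
#'   \code{leak_rate}, \code{eqtl_ratio}, \code{mean_depth},
#'   \code{n_het_snps}, \code{informative_rate}. This table is the truth
#'   label set for recovery testing.
#' @export
simulate_gene_specs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  if (ng == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      class_label = character(0),
                      silenced_parent = character(0),
                      leak_rate = numeric(0), eqtl_ratio = numeric(0),
                      mean_depth = numeric(0), n_het_snps = integer(0),
                      informative_rate = numeric(0),
                      stringsAsFactors = FALSE))
  }
  mix <- config$class_mixture
  # largest-remainder apportionment of class counts
  raw <- mix * ng
  cnt <- floor(raw)
  rem <- ng - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  labels <- rep(names(cnt), times = cnt)
  labels <- with_seed(stage_seed(config$seed, 11L), sample(labels))
  silenced <- rep(NA_character_, ng)
  silenced[labels == "imprinted_maternal_silenced"] <- "maternal"
  silenced[labels == "imprinted_paternal_silenced"] <- "paternal"
  leaky <- which(labels == "leaky_imprinted")
  if (length(leaky)) {
    silenced[leaky] <- with_seed(stage_seed(config$seed, 12L),
      sample(c("maternal", "paternal"), length(leaky), replace = TRUE))
  }
  leak <- ifelse(labels == "leaky_imprinted", config$leak_rate,
                 ifelse(is.na(silenced), NA_real_, 0))
  chrom <- paste0("chr", (seq_len(ng) - 1L) %% 22L + 1L)
  start <- as.integer(1e5 + ((seq_len(ng) - 1L) %/% 22L) * 1e5)
  data.frame(
    gene_id = sprintf("gene%05d", seq_len(ng)),
    chrom = chrom,
    start = start,
    end = start + 10000L,
    class_label = labels,
    silenced_parent = silenced,
    leak_rate = leak,
    eqtl_ratio = ifelse(labels == "biallelic_eqtl", config$eqtl_ratio,
                        NA_real_),
    mean_depth = config$mean_depth,
    n_het_snps = config$n_het_snps,
    informative_rate = config$informative_rate,
    stringsAsFactors = FALSE
  )
}

#' Simulate per-individual per-gene parental transcript counts
#'
#' Total transcripts per individual x gene are negative-binomial with mean
#' \code{mean_depth / informative_rate}; each transcript covers an
#' informative SNP with probability \code{informative_rate} (otherwise it is
#' of unknown parental origin); informative transcripts are maternal with a
#' class-dependent probability: 0.5 for balanced biallelic genes,
#' \code{leak_rate} (or \code{1 - leak_rate}) for genes whose maternal (or
#' paternal) copy is silenced, and \code{eqtl_ratio} for eQTL genes in
#' individuals heterozygous for the regulatory variant (0.5 otherwise).
#'
#' @param config A \code{\link{sim_config}}.
#' @param genes Gene truth table from \code{\link{simulate_gene_specs}}.
#' @return Data frame with columns \code{individual_id}, \code{gene_id},
#'   \code{m}, \code{p}, \code{u} (maternal / paternal / unknown-origin
#'   transcript counts); one row per individual x gene.
#' @export
simulate_parental_counts <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(genes))
  ni <- config$n_individuals
  ng <- nrow(genes)
  inds <- sim_individual_ids(ni)
  if (ng == 0L) {
    return(data.frame(individual_id = character(0), gene_id = character(0),
                      m = integer(0), p = integer(0), u = integer(0),
                      stringsAsFactors = FALSE))
  }
  N <- ni * ng
  gi <- rep(seq_len(ng), each = ni)        # gene-major layout
  with_seed(stage_seed(config$seed, 1L), {
    p_mat <- rep(0.5, N)
    lab <- genes$class_label[gi]
    sil <- genes$silenced_parent[gi]
    leak <- genes$leak_rate[gi]
    imp <- !is.na(sil)
    p_mat[imp & sil == "maternal"] <- leak[imp & sil == "maternal"]
    p_mat[imp & sil == "paternal"] <- 1 - leak[imp & sil == "paternal"]
    is_eqtl <- lab == "biallelic_eqtl"
    if (any(is_eqtl)) {
      het <- rbinom(sum(is_eqtl), 1L, config$regulator_het_freq) == 1L
      p_mat[is_eqtl] <- ifelse(het, genes$eqtl_ratio[gi][is_eqtl], 0.5)
    }
    mu <- genes$mean_depth[gi] / genes$informative_rate[gi]
    total <- if (config$dispersion > 0) {
      rnbinom(N, size = 1 / config$dispersion, mu = mu)
    } else {
      rpois(N, mu)
    }
    informative <- rbinom(N, total, genes$informative_rate[gi])
    m <- rbinom(N, informative, p_mat)
    data.frame(
      individual_id = rep(inds, times = ng),
      gene_id = genes$gene_id[gi],
      m = as.integer(m),
      p = as.integer(informative - m),
      u = as.integer(total - informative),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate pedigree-phased genotypes at exonic SNPs
#'
#' For each gene, \code{n_het_snps} biallelic SNP sites are placed inside
#' the gene body. Per individual, heterozygosity at a site is Bernoulli
#' (\code{het_freq}); the alternate allele lands on the maternal or paternal
#' haplotype with equal probability. A configurable fraction of sites is
#' flagged parent-of-origin-unknown at the site level (mirroring alleles
#' that could not be assigned a transmitting parent during phasing); such
#' sites are never informative.
#'
#' With \code{ensure_informative = TRUE} (the default) the generator
#' guarantees, whenever \code{po_unknown_fraction < 1}, that every gene has
#' at least one parent-of-origin-known site and that every individual is
#' heterozygous at at least one known site per gene, so every simulated
#' parental transcript can carry an informative allele observation and the
#' read-level round trip is exact.
#'
#' @param config A \code{\link{sim_config}}.
#' @param genes Gene table from \code{\link{simulate_gene_specs}}.
#' @param ensure_informative Guarantee one informative SNP per
#'   individual x gene (see Details).
#' @return An object of class \code{phased_genotypes}: a list with
#'   \code{sites} (data frame: \code{snp_id}, \code{gene_id}, \code{chrom},
#'   \code{pos} 1-based, \code{ref}, \code{alt}, \code{po_known}),
#'   \code{maternal} and \code{paternal} (site x individual 0/1 allele-code
#'   matrices), and \code{individuals}.
#' @export
simulate_phased_genotypes <- function(config, genes, ensure_informative = TRUE) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(genes))
  ni <- config$n_individuals
  ng <- nrow(genes)
  if (ng > 0 && any(genes$n_het_snps < 1)) {
    stop("every gene needs n_het_snps >= 1")
  }
  inds <- sim_individual_ids(ni)
  ns_per_gene <- if (ng) genes$n_het_snps else integer(0)
  ns <- sum(ns_per_gene)
  gidx <- rep(seq_len(ng), times = ns_per_gene)
  with_seed(stage_seed(config$seed, 2L), {
    within <- unlist(lapply(ns_per_gene, function(k) {
      sort(sample.int(10000L, k))
    }), use.names = FALSE)
    pos <- if (ns) genes$start[gidx] + within else integer(0)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, ns, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    po_known <- runif(ns) >= config$po_unknown_fraction
    if (ensure_informative && config$po_unknown_fraction < 1 && ns) {
      for (g in seq_len(ng)) {          # >= 1 po-known site per gene
        rows <- which(gidx == g)
        if (!any(po_known[rows])) po_known[sample(rows, 1L)] <- TRUE
      }
    }
    het <- matrix(rbinom(ns * ni, 1L, config$het_freq), ns, ni)
    orient <- matrix(rbinom(ns * ni, 1L, 0.5), ns, ni)  # alt on maternal?
    hom_alt <- matrix(rbinom(ns * ni, 1L, 0.5), ns, ni)
    maternal <- ifelse(het == 1L, orient, hom_alt)
    paternal <- ifelse(het == 1L, 1L - orient, hom_alt)
    if (ensure_informative && config$po_unknown_fraction < 1 && ns) {
      for (g in seq_len(ng)) {          # >= 1 informative site per ind x gene
        rows <- which(gidx == g & po_known)
        inf_any <- colSums(maternal[rows, , drop = FALSE] !=
                           paternal[rows, , drop = FALSE]) > 0
        fix <- which(!inf_any)
        if (length(fix)) {
          s <- rows[1L]
          o <- rbinom(length(fix), 1L, 0.5)
          maternal[s, fix] <- o
          paternal[s, fix] <- 1L - o
        }
      }
    }
    sites <- data.frame(
      snp_id = sprintf("snp%06d", seq_len(ns)),
      gene_id = if (ns) genes$gene_id[gidx] else character(0),
      chrom = if (ns) genes$chrom[gidx] else character(0),
      pos = as.integer(pos),
      ref = ref,
      alt = alt,
      po_known = po_known,
      stringsAsFactors = FALSE
    )
    rownames(sites) <- NULL
    structure(list(sites = sites,
                   maternal = maternal,
                   paternal = paternal,
                   individuals = inds),
              class = "phased_genotypes")
  })
}

#' Simulate allele-specific read records from parental counts
#'
#' Each maternal (paternal) transcript emits one read record carrying the
#' allele observed at one informative SNP of its gene, matching the maternal
#' (paternal) haplotype of that individual; unknown-origin transcripts emit
#' records covering no informative SNP. With \code{error_rate = 0},
#' assigning these reads back to parents recovers the input counts exactly,
#' provided every individual has an informative SNP in each expressed gene
#' (guaranteed by the default genotype generator). A per-read allele-flip
#' error can be injected to study misclassification.
#'
#' @param counts Parental count table (\code{individual_id}, \code{gene_id},
#'   \code{m}, \code{p}, \code{u}).
#' @param genotypes A \code{phased_genotypes} object covering the genes in
#'   \code{counts}.
#' @param error_rate Probability that a read's observed allele is flipped to
#'   the opposite haplotype's allele.
#' @param seed Optional integer seed for the read-level sampling; defaults
#'   to a fixed internal seed so output is reproducible.
#' @return Data frame of read records: \code{read_id}, \code{individual_id},
#'   \code{gene_id}, \code{snp_id}, \code{observed_allele} (\code{NA} for
#'   reads covering no informative SNP).
#' @export
simulate_reads <- function(counts, genotypes, error_rate = 0, seed = 1L) {
  stopifnot(is.data.frame(counts), inherits(genotypes, "phased_genotypes"))
  if (error_rate < 0 || error_rate > 1) stop("'error_rate' must be in [0, 1]")
  sites <- genotypes$sites
  ind_idx <- match(counts$individual_id, genotypes$individuals)
  if (any(is.na(ind_idx))) stop("counts contain individuals absent from genotypes")
  out <- vector("list", nrow(counts))
  with_seed(stage_seed(seed, 3L), {
    rid <- 0L
    site_rows_by_gene <- split(seq_len(nrow(sites)), sites$gene_id)
    for (i in seq_len(nrow(counts))) {
      m <- counts$m[i]; p <- counts$p[i]; u <- counts$u[i]
      ntot <- m + p + u
      if (ntot == 0L) next
      ind <- ind_idx[i]
      rows <- site_rows_by_gene[[counts$gene_id[i]]]
      inf <- rows[sites$po_known[rows] &
                  genotypes$maternal[rows, ind] != genotypes$paternal[rows, ind]]
      snp <- rep(NA_character_, ntot)
      obs <- rep(NA_character_, ntot)
      npar <- m + p
      if (npar > 0L) {
        if (length(inf) == 0L) {
          warning("no informative SNP for ", counts$individual_id[i], " x ",
                  counts$gene_id[i], "; its parental reads will be unknown")
        } else {
          pick <- inf[sample.int(length(inf), npar, replace = TRUE)]
          off <- (ind - 1L) * nrow(sites)   # linear index into site x ind
          code <- c(genotypes$maternal[pick[seq_len(m)] + off],
                    genotypes$paternal[pick[m + seq_len(p)] + off])
          if (error_rate > 0) {
            flip <- runif(npar) < error_rate
            code[flip] <- 1L - code[flip]
          }
          snp[seq_len(npar)] <- sites$snp_id[pick]
          obs[seq_len(npar)] <- ifelse(code == 0L, sites$ref[pick],
                                       sites$alt[pick])
        }
      }
      out[[i]] <- data.frame(
        read_id = sprintf("r%09d", rid + seq_len(ntot)),
        individual_id = counts$individual_id[i],
        gene_id = counts$gene_id[i],
        snp_id = snp,
        observed_allele = obs,
        stringsAsFactors = FALSE
      )
      rid <- rid + ntot
    }
  })
  if (length(out) == 0L || all(vapply(out, is.null, logical(1)))) {
    return(data.frame(read_id = character(0), individual_id = character(0),
                      gene_id = character(0), snp_id = character(0),
                      observed_allele = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Simulate CpG methylation beta values over candidate regions
#'
#' CpGs inside regions of class \code{"icr"} (imprinting control regions,
#' methylated on exactly one parental chromosome) are drawn around beta 0.5;
#' CpGs in \code{"unmethylated"} and \code{"methylated"} regions are drawn
#' near 0 and 1 respectively. Gaussian noise of the configured standard
#' deviation is added and values are truncated to [0, 1].
#'
#' @param dmrs Data frame of non-overlapping regions: \code{region_id},
#'   \code{chrom}, \code{start}, \code{end} (BED, 0-based half-open),
#'   \code{class} in \code{c("icr", "unmethylated", "methylated")}.
#' @param config A \code{\link{sim_config}} (uses
#'   \code{methylation_noise_sd}, \code{n_individuals_validation},
#'   \code{seed}).
#' @param n_cpgs_per_region CpGs simulated inside each region.
#' @return Data frame: \code{cpg_id}, \code{chrom}, \code{pos} (1-based),
#'   \code{individual_id}, \code{value}, \code{scale} (always
#'   \code{"beta"}).
#' @export
simulate_methylation <- function(dmrs, config, n_cpgs_per_region = 8L) {
  stopifnot(is.data.frame(dmrs), inherits(config, "sim_config"))
  if (nrow(dmrs) == 0L) {
    return(data.frame(cpg_id = character(0), chrom = character(0),
                      pos = integer(0), individual_id = character(0),
                      value = numeric(0), scale = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!all(dmrs$class %in% c("icr", "unmethylated", "methylated"))) {
    stop("unknown DMR class; use icr / unmethylated / methylated")
  }
  ov <- order(dmrs$chrom, dmrs$start)
  d <- dmrs[ov, ]
  same <- d$chrom[-1] == d$chrom[-nrow(d)]
  if (nrow(d) > 1 && any(same & d$start[-1] < d$end[-nrow(d)])) {
    stop("DMR intervals must be non-overlapping")
  }
  ni <- config$n_individuals_validation
  inds <- sim_individual_ids(ni)
  k <- as.integer(n_cpgs_per_region)
  nr <- nrow(dmrs)
  with_seed(stage_seed(config$seed, 4L), {
    ridx <- rep(seq_len(nr), each = k)
    frac <- (seq_len(k) - 0.5) / k
    pos <- as.integer(floor(dmrs$start[ridx] +
             frac * pmax(1, dmrs$end[ridx] - dmrs$start[ridx]))) + 1L
    centre <- c(icr = 0.5, unmethylated = 0.05, methylated = 0.95)
    mu <- centre[dmrs$class[ridx]]
    ncpg <- nr * k
    val <- rep(mu, times = ni) +
      rnorm(ncpg * ni, 0, config$methylation_noise_sd)
    val <- pmin(1, pmax(0, val))
    data.frame(
      cpg_id = rep(sprintf("cpg%06d", seq_len(ncpg)), times = ni),
      chrom = rep(dmrs$chrom[ridx], times = ni),
      pos = rep(pos, times = ni),
      individual_id = rep(inds, each = ncpg),
      value = val,
      scale = "beta",
      stringsAsFactors = FALSE
    )
  })
}
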