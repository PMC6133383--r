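---
title: "Detecting imprinted genes from parent-of-origin expression asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting imprinted genes from parent-of-origin expression asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
```

## The problem

An imprinted gene is expressed predominantly from one parental chromosome.
With pedigree-phased genotypes, every allele of every SNP can (in
principle) be labelled with the parent that transmitted it, and an RNA-seq
read that overlaps a heterozygous, parent-of-origin-resolved SNP can be
assigned to the maternal or the paternal haplotype. The practical obstacle
is sparsity: most reads overlap no such informative site, so the
assignable fraction of expression is small (on the order of 2% per gene)
and varies enormously across genes and individuals. Any test built on
these counts must therefore be robust to very uneven, overdispersed
per-individual depths.

## The two-level sign test

`poe_test()` operates in two stages.

**Within individuals.** For individual $i$ at a gene, with maternal count
$m_i$ and paternal count $p_i$ and $n_i = m_i + p_i$, the binomial Z-score
is

$$Z_i = \frac{m_i - n_i/2}{\sqrt{n_i/4}}.$$

Only individuals with $n_i \ge$ `min_parental` (default 5) enter, and only
the *sign* of $Z_i$ is retained; exact ties ($m_i = p_i$, $Z_i = 0$) are
excluded. Reducing each individual to a sign discards depth information on
purpose: a per-individual binomial model of the counts themselves would
need an overdispersion parameter (biological replicates of ASE counts are
not binomial), whereas the sign is correctly calibrated under the null no
matter how overdispersed the counts are.

**Across individuals.** Under symmetric expression each non-tied
individual independently favours either parent with probability ½, so the
count of maternal-favouring individuals among the $n$ non-tied ones is
$\mathrm{Binomial}(n, \tfrac12)$. The gene-level p-value is the exact
two-sided test with the smaller tail doubled and capped at 1. Genes with
$n = 0$ are reported `untestable` rather than assigned $p = 1$: an absent
measurement is not evidence of symmetry.

P-values are adjusted by the Benjamini–Hochberg step-up procedure
(`bh_fdr()`, delegating to `stats::p.adjust`). BH is the field default for
expression screens; the choice is exposed rather than hard-coded into the
results, which carry raw p-values as well.

### Classification

Significant genes ($q <$ `fdr_threshold`, default 0.05) are classified
from their pooled counts $\Sigma m, \Sigma p$ over the eligible
individuals:

* `single_parent` — one pooled count is exactly 0 (and the other
  positive): expression from a single parental chromosome.
* `candidate_imprinted` — the pooled majority-parent share
  $\max(\Sigma m, \Sigma p)/(\Sigma m + \Sigma p)$ is at least
  `major_share_threshold` (default 0.8). Imprinted genes are often
  "leaky" (a small residue from the nominally silenced allele, from
  biallelic isoforms or a minority of escaping cells), so requiring
  complete silencing would miss them; requiring a large majority share
  separates them from cis-regulatory imbalance.
* `asymmetric_only` — significant skew with substantial expression from
  both parents, the signature expected of a heterozygous cis-eQTL rather
  than imprinting.

The 0.8 share threshold is a package decision, not an estimate: published
category assignments of this kind also lean on literature curation, which
no threshold reproduces. It is configurable, and the raw
`pooled_major_share` is always reported so users can re-categorize.

### Numerical behaviour of the p-value

The tail sum $\sum_{i \le k} \binom{n}{i} 2^{-n}$ is accumulated in log
space (`lchoose` plus log-sum-exp). At the scales involved
($p \sim 10^{-41}$ for $k=2, n=150$) each term is representable in double
precision, but the implementation avoids any dependence on that: the
log-space path is exact to floating-point rounding for all $n$, and the
test suite verifies agreement with an arbitrary-precision rational oracle
to 10 significant digits for every $(k, n)$ with $n \le 300$. Symmetry
$p(k, n) = p(n-k, n)$ holds exactly by construction because the smaller
tail is selected before summation.

## Read-to-parent assignment

`classify_read()` uses only informative SNPs — heterozygous in the
individual *and* parent-of-origin-known. A read is maternal if at least
one informative call matches the maternal allele and none matches the
paternal allele; symmetrically for paternal; everything else is unknown.
Two deliberately conservative rules, both package decisions where the
procedure could be ambiguous:

* calls that conflict across SNPs within a read → unknown (a genotype or
  phasing error should not manufacture a parental call);
* a call matching neither phased allele (sequencing error) → unknown,
  discarding the read from the assignable pool.

Reads are matched to genes by the gene id on the read record; coordinate
overlap assignment is out of scope. Gene filters follow the usual
expression-screen conventions: X and Y chromosome genes removed (X
inactivation and hemizygosity mimic parental asymmetry), and a gene is
kept only if $\log_2 \mathrm{CPM} \ge 1$ in at least 20 individuals, with
CPM computed from each individual's total (m+p+u) library. The "at least
20 individuals" reading is the only coherent direction for this filter
and is what `filter_genes()` implements; both the threshold and the count
are arguments.

`min_parental` is applied to $m + p$ per individual (default), with an
`"each"` rule (both $m \ge$ and $p \ge$ the floor) available as an
option; the sum rule is the default because the each-parent rule would
exclude precisely the fully imprinted genes the screen targets.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which the pipeline's operating characteristics are measured.

* **Cohort**: 306 individuals by default (validation cohort 99).
* **Counts**: totals per individual × gene are negative-binomial with
  mean `mean_depth / informative_rate` and dispersion 0.2 (variance
  $\mu + 0.2\mu^2$), a conventional level for bulk RNA-seq; each
  transcript is informative with probability `informative_rate` (default
  0.018, so ~98.2% of transcripts are of unknown origin, matching the
  sparsity regime the analysis is designed for).
* **Gene classes**: fully imprinted maternal-silenced and
  paternal-silenced (leak 0), leaky imprinted (default leak 0.05),
  balanced biallelic (maternal share 0.5), and biallelic-eQTL genes whose
  maternal share is `eqtl_ratio` (default 0.7) in individuals
  heterozygous for a simulated regulatory variant and 0.5 otherwise. The
  default mixture is 90% balanced / 5% eQTL / 5% imprinted-like —
  imprinting is rare genome-wide, and the mixture mainly sets the
  background against which false positives are counted.
* **Genotypes**: per gene, `n_het_snps` biallelic sites; heterozygosity
  is Bernoulli(`het_freq` = 0.5) per individual; a site-level fraction
  (default 10%) is flagged parent-of-origin-unknown, mirroring alleles
  that pedigree phasing could not assign. By default the generator
  guarantees at least one informative SNP per individual × gene (when the
  unknown fraction is below 1): the count model already decides how many
  transcripts are informative, so the genotypes must be able to carry
  those observations, and this guarantee is what makes the read-level
  round trip (simulate reads → classify → aggregate) exactly the identity
  at zero read error. The adjustment touches at most one site per
  individual × gene and leaves the flagged-site fraction effectively at
  its nominal value for genes with several SNPs.
* **Methylation**: CpGs in ICR-class regions are drawn around beta 0.5,
  non-ICR regions near 0 or 1, with truncated Gaussian noise (default sd
  0.05). Depth of the emulation is deliberately shallow — the analysis
  consumes only per-CpG medians against the 0.25–0.75 band.

What the generator does **not** emulate: mapping bias, PCR duplicates,
isoform structure, linkage between neighbouring genes, relatedness between
individuals, batch effects, or array probe artefacts. Tests passing on
synthetic data therefore demonstrate the statistical machinery — error
control, power at specified effect sizes, exact bookkeeping — not
robustness to those upstream artefacts, which are assumed corrected before
the data reach this package.

All simulator output is a deterministic function of the configuration,
including its seed; stage-specific seeds are derived internally so that,
e.g., counts and genotypes are reproducible independently.

## Methylation corroboration

`m_to_beta()` implements $\beta = 2^M/(2^M+1)$, the inverse of
$M = \log_2(\beta/(1-\beta))$; the two round-trip to 1e-12 and map the
partial band $\beta \in [0.25, 0.75]$ exactly onto
$M \in [-\log_2 3, \log_2 3]$. Band endpoints are inclusive — the weaker
reading of "between". A region is `consistent_with_imprinting` when at
least `min_cpgs` (3) CpGs fall in it and at least `min_fraction` (0.5) of
their cross-individual medians lie in the band; both thresholds are
explicit configuration, since no principled universal value exists for
how much of a DMR must be partially methylated. CpG positions are 1-based
and regions BED-style 0-based half-open; intersection goes through
GenomicRanges. `candidate_support()` joins candidates to mapped regions
supplied by the user (an ICR can regulate a gene at a distance, so the
map is prior knowledge, not overlap).

## Validation across datasets

`concordance()` compares the sign of (maternal-favouring −
paternal-favouring individuals) per gene between two fitted objects. Genes
untestable in either dataset, or with a perfectly split direction, are
reported separately rather than counted as disagreement.

## Problem sizes in the test suite

The suite measures the operating characteristics at sizes chosen to make
sampling noise negligible relative to the margins being asserted: type-I
error on 10,000 balanced genes × 100 individuals at depth 50; recovery of
100 leaky imprinted genes (leak 0.05) among 900 balanced genes; direction
concordance between two cohorts of 100 individuals over 100 imprinted
genes; 1,000 simulated regions for methylation classification; the exact
oracle sweep covers every $(k, n)$ up to $n = 300$.

## Known limitations

* No kinship adjustment: signs are pooled across individuals as if
  independent, which overstates confidence in a deeply related pedigree.
* The test detects *asymmetry*; distinguishing imprinting from strong
  cis-regulatory imbalance rests on the pooled-share heuristic and, in
  real use, external evidence (methylation, known imprinted clusters).
* Single-parent calls are sensitive to genotyping errors in real data (a
  single miscalled read breaks the "zero in all individuals" criterion);
  the sign test is the robust workhorse.
* Methylation support uses bulk array values that cannot be assigned to a
  haplotype; a partially methylated region is consistent with, not proof
  of, imprinting.
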