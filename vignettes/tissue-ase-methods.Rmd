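---
title: "Methods: multi-tissue allele-specific expression with tissueASE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue allele-specific expression with tissueASE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueASE)
library(dplyr)
```

## Scope and data model

`tissueASE` analyses allelic read counts at high-confidence heterozygous
SNPs measured across tissues of one individual, by up to three assays:
RNA-seq, targeted deep mmPCR-seq (multiplex PCR plus deep sequencing,
which decouples per-site depth from gene expression level), and exome DNA
sequencing (used only as a genotyping/mappability control). The package
starts from counts: alignment, variant calling and expression
quantification are upstream and out of scope.

Three tables carry the data. *Sites* hold coordinates, alleles, variant
class (`control`, `deleterious_nsSNP`, `nonsense`), minor allele
frequency (MAF), a privacy flag (absent from reference panels) and an
intragenic flag. *Count records* hold `ref/alt/other` read counts keyed
by (site, tissue, replicate, assay); only two observed alleles are
modelled, any third or fourth base accumulating in `other_count`, and
multi-allelic VCF records are skipped. Counts are strand-agnostic. *ASE
calls* add the allelic ratio `alt / (ref + alt)`, the exact binomial
p-value, and the QC flags. High-confidence sites are those called
heterozygous concordantly in every DNA sample of the VCF; discordant
sites are dropped rather than flagged.

## The bias-corrected exact binomial test

Reads carrying the reference allele align to the reference genome
slightly more often than reads carrying the alternate allele, so even
under perfectly balanced expression the expected reference-read fraction
exceeds one half. The test replaces 0.5 with the empirical reference-read
probability $\hat p$, pooled over all sites passing the depth filters:
$\hat p = \sum r_i / \sum (r_i + a_i)$, clamped to $[10^{-6}, 1-10^{-6}]$.
Pooling "across all sites" deliberately includes truly imbalanced sites;
as long as ASE directions are roughly symmetric their contributions
cancel, and the estimate tracks the mapping asymmetry. Two choices are
fixed here that the estimator's description leaves open:

* **Scope.** The default is one estimate per sample (tissue × assay),
  since mapping-bias distributions differ between libraries; a global
  pooled estimate is available (`scope = "global"`).
* **Which records feed the estimate.** Depth filters only. Conditioning
  on the significance filter would let the alternative leak into the
  null, so significance is never applied before estimation.

The per-site test is `r ~ Binomial(r + a, p̂)` with a two-sided p-value
by the minimum-likelihood rule: the sum of probabilities of all outcomes
whose probability does not exceed the observed outcome's (with the usual
`1 + 1e-7` relative tolerance for ties). Unlike doubling one tail, this
construction is well defined for any $\hat p$ and agrees exactly with
brute-force enumeration, which the test suite checks for every total up
to 50. Because the binomial is discrete, the test is slightly
conservative: at depth 200 the measured type-I error at $\alpha = 0.05$
is ≈ 0.047.

## The QC cascade

A call must clear, in order: base quality (applied while decoding pileup
text; bases below Phred 10 never enter the counts), per-allele depth ≥ 5,
total depth ≥ 20, bi-allelic expression, and intragenic location.
Significance is recorded as a flag but does not affect `qc_pass`; it
gates `is_ase` at the assay-specific α (0.05 RNA-seq, 0.01 mmPCR-seq,
reflecting mmPCR's much larger depth). Two parameterisations deserve
comment:

* The bi-allelic filter is stated qualitatively in the field; we
  operationalise it as `other_count / (ref + alt + other) > 0.05`
  (`max_other_fraction`, configurable). Five percent sits well above
  sequencing-error rates yet catches genuine tri-allelic signals or
  systematic misalignment.
* An alternative depth rule — total ≥ 10 with no per-allele floor — is
  in circulation for RNA-seq call sets; it is reachable via
  `filter_params(min_allele_depth = 0, min_total_depth = 10)`, but the
  more specific 5/20 rule is the default.

## Cross-tissue classification

For each site with QC-passing calls in at least `min_tissues = 3`
tissues, the profile is the vector of per-tissue allelic ratios,
summarised by its mean $m$ and its dispersion $s$, the **population**
standard deviation. The tissue panel is the complete object of study, not
a sample from a larger population, and $n$ is small, so the divide-by-$n$
form is used. The classifier is a deterministic partition:

* no ASE: $0.35 < m < 0.65$ and $s < 0.2$;
* shared ASE: $m < 0.35$ or $m > 0.65$, $s < 0.2$, and at least
  `min_significant_tissues = 1` tissue with $p < 0.01$;
* variable ASE: $s > 0.2$ and at least one significant tissue;
* otherwise unclassified, including every exact tie with a cutoff (the
  inequalities are strict).

Two published formulations of these rules conflict internally, and the
package resolves both on geometric grounds. First, the dispersion cutoff
is sometimes written as a *variance* of 0.2 — but ratios bounded in
$[0,1]$ cannot have variance above 0.25, the companion plots label the
axis as a standard deviation, and the reproducibility sweep spans
0.05–0.3; the cutoff is therefore interpreted as a standard deviation.
Second, the shared-ASE band is sometimes printed as
$0.35 < m < 0.65$, which would make "imbalanced" sites balanced; the
intended condition is its complement, $m < 0.35$ or $m > 0.65$. Both
interpretations are configurable (`class_params()`), and significance
counts are carried alongside the label so a stricter no-ASE definition
(requiring non-significance) can be applied downstream.

Monoallelic expression is detected separately: every tissue ratio at or
beyond `mono_threshold = 0.95` toward the same allele, in at least 5
testable tissues. The threshold is a package choice — far enough from the
shared-ASE regime (mean ≈ 0.2/0.8) to separate imprinting-like silencing
from strong ASE — and is configurable. Direction-of-effect flips are
summarised from per-site ratio ranges with fixed thresholds: a *major*
flip spans < 0.2 to > 0.8, *large* < 0.4 to > 0.8, *moderate* < 0.2 to
> 0.6, the most extreme class winning.

Pairwise tissue correlation (Spearman by default, pairwise-complete) and
average-linkage clustering on $1 - r$ provide the expression/allelic
concordance view; Spearman is preferred because FPKM-like inputs are
heavy-tailed and the statistic is invariant under monotone transforms.

## Replicates

Technical replicates are merged by summing counts ("merged" replicate
id); the binomial test on merged counts is by construction the test on
summed counts. Concordance is Pearson $r$ of allelic ratios over shared
QC-passing (site, tissue) pairs, plus the mean absolute ratio difference
binned by the smaller replicate depth (default bins
[20,100), [100,200), [200,500), [500,2000), [2000,∞)). The
classification-reproducibility sweep classifies profiles independently
from each replicate over a grid of balanced-band pairs (0.4–0.6,
0.35–0.65) × eight dispersion cutoffs (0.05–0.3), optionally excluding
designated tissues, and reports the fraction of sites with identical
3-class labels and identical binary labels (ASE = shared ∪ variable).
Sites unclassified in either replicate at a grid point are excluded from
that point's denominator; each replicate is classified with the full rule
set, p-values included.

## The simulator

`simulate_dataset()` emulates the generative structure the pipeline is
built for, with defaults fixed once from the study design it mirrors:

* ten somatic tissues, two technical replicates, 500 sites;
* ASE classes in proportions 0.72 / 0.20 / 0.05 / 0.03
  (no / shared / variable / monoallelic), echoing the observed
  172 : 52 : 8 split with a small monoallelic mass. Shared sites draw a
  per-tissue true alternate fraction around 0.2 (or 0.8; direction
  random) with tissue sd 0.03; variable sites scatter tissue means around
  0.5 with sd 0.3 (clamped to [0.02, 0.98]); monoallelic sites sit at
  0.99/0.01 everywhere;
* variant classes control : deleterious : nonsense at 205 : 74 : 50.
  Nonsense sites model NMD on the RNA side: their alternate-fraction mean
  is overridden to 0.15 (rare) or 0.30 (common) — qualitative stand-ins,
  as no numeric means are published — while their DNA fraction stays 0.5.
  The site's *effective* class therefore becomes shared ASE, and the
  recovery evaluation accounts for this re-routing;
* mapping bias as a read-sampling distortion: with bias factor
  $\beta \ge 1$ the observed alternate-read probability is
  $\theta = \mu / (\beta(1-\mu) + \mu)$, so at $\mu = 0.5$ the reference
  fraction is $\beta/(\beta+1)$ — the quantity the bias estimator must
  recover. Default $\beta = 1.05$;
* replicate noise via beta-binomial counts with intra-class correlation
  $\rho = 0.005$, inflatable per tissue (default 0.05 for designated
  high-noise tissues) to emulate low post-mortem RNA quality;
* depth: mmPCR negative-binomial, mean 2000 (deep targeted sequencing
  decoupled from expression); RNA-seq per-gene log-normal expression with
  per-tissue variation feeding a Poisson (so RNA power *does* track
  expression); exome DNA mean 80, from exactly two DNA samples.

What the simulator does **not** emulate: read-level artefacts (soft
clipping, duplicates), allele-specific mappability beyond the single
odds factor, splice structure, primer-efficiency variation in mmPCR, and
linkage between neighbouring sites. Passing recovery tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not robustness to every alignment pathology in real
data.

## Numerical and degenerate-input choices

* Binomial p-values are enumerated per (total, $\hat p$) group and
  shared across records; accumulated rounding at the modal outcome is
  snapped to exactly 1.
* Records with zero informative reads get `NA` p-values and never pass
  the depth filters.
* Fisher's exact test is computed by direct hypergeometric enumeration
  (two-sided, sum of tables no more probable than observed); the odds
  ratio is the raw cross-product ratio, with Haldane's 0.5 correction
  applied and flagged only when a zero cell makes it undefined.
* Group comparisons use Welch's t-test by default ("Student's t-test"
  in loose usage rarely means pooled variance, and Welch is safe under
  unequal spread); pooled variance is available via `var_equal = TRUE`.
  Two identical constant groups return $t = 0$, $p = 1$.
* The clustering leaf order ties are resolved by `hclust`'s
  deterministic ordering, making outputs reproducible byte for byte.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` size their simulations as the
package's own verification choices: 500 sites × 8 tissues at mmPCR depth
~2000 for class recovery (≥ 95% required); 10,000 null sites at depth 200
for the test's size; 10,000 sites × depth 100 per bias factor for bias
recovery (± 0.01); 200 sites × 5 tissues for replicate concordance; and
200 simulation replicates of a 120-site two-tissue cohort for the NMD
ordering (rare nonsense < common nonsense < control, each replicate
providing ≥ 25 sites per contrasted group).

## Known limitations

* The binomial test ignores overdispersion; with very deep mmPCR data,
  tiny deviations from $\hat p$ become significant, which is exactly why
  classification layers effect-size (ratio and dispersion) cutoffs on
  top of p-values. A beta-binomial *test* is deliberately out of scope —
  the simulator uses the beta-binomial, the caller does not.
* One individual, no phasing: the package reports allelic imbalance per
  site, not haplotype-resolved regulatory effects, and cannot separate
  imprinting from cis-regulatory ASE.
* Cohort contrasts report nominal p-values; no multiple-testing
  correction across tissues is applied.
* The pileup reader trusts its input text: overlapping read pairs are
  assumed already de-duplicated upstream.
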