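---
title: "Methods: models, generator design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generator design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somage)
```

# Overview

`somage` relates somatic genomic and epigenomic alterations to patient age
in tumor exome cohorts. The pipeline has seven stages:

1. **MAF filtering** — three exclusion criteria applied to MAF-like
   somatic mutation tables.
2. **Trinucleotide profiling** — per-patient 96-channel
   pyrimidine-normalized mutation profiles.
3. **Signature refitting** — non-negative least-squares exposures against
   a fixed 30-signature catalog.
4. **Alteration loads** — per-patient SNP, disrupted-gene, CNV and
   methylation burden statistics.
5. **Age-association statistics** — Spearman screens with bootstrap
   confidence intervals and Benjamini–Hochberg (BH) control.
6. **Subgrouping and enrichment** — mean-threshold signature subgroups and
   single-sample GSEA (ssGSEA) pathway projection.
7. **Synthetic data** — a generator with archived ground truth so every
   stage is testable without downloads.

This vignette documents the statistical models, the rationale behind the
generator's default parameters, and the numerical decisions.

# Filtering model

Three record-level exclusions are applied in a fixed order, with a count
recorded after each step:

1. **Same-patient deduplication.** Two samples of one patient (e.g. a
   primary-tumor and a recurrence aliquot) can report the same somatic
   event. Records are keyed on
   (patient, chromosome, position, reference allele, alternate allele);
   within a key the record from the lexicographically smallest sample
   barcode is kept, which makes the result independent of input row order.
2. **Multi-gene ambiguity.** Records annotated to more than one gene
   (semicolon-separated symbols) cannot be attributed to a single locus
   and are dropped.
3. **Tandem-repeat contexts.** A record is dropped when its reference
   context contains a tandem run of a 1–5 base unit with at least
   (6, 4, 3, 3, 3) consecutive copies respectively. Such contexts are
   enriched for alignment artifacts. `N` bases never extend a run. The
   shipped implementation is a vectorized dynamic program over character
   matrices; the test suite checks it against a literal substring-counting
   oracle on 10,000 random contexts.

# Trinucleotide profiles and signature refitting

Each single-nucleotide substitution is mapped to one of 96 channels: the
six pyrimidine-referenced substitution classes (C>A, C>G, C>T, T>A, T>C,
T>G) crossed with the 16 flanking-base pairs. Purine-referenced events are
reverse-complemented (both alleles and both flanks, flanks swapped), so
the mapping is strand-symmetric; this involution is verified exhaustively
over all 12 substitutions × 16 flank pairs.

Given a patient profile $p \in \mathbb{R}^{96}_{\ge 0}$ (counts) and a
catalog $S \in \mathbb{R}^{96 \times 30}$ of column-normalized signatures,
exposures solve

$$\min_{a \ge 0} \; \lVert p - S a \rVert_2^2 .$$

The problem is a convex bound-constrained quadratic, solved with
`stats::optim(method = "L-BFGS-B")` and the analytic gradient
$\nabla f(a) = 2(S^\top S a - S^\top p)$. Numerical choices:

- $S^\top S$ and $S^\top p$ are precomputed, so each objective/gradient
  evaluation is $O(K^2)$ rather than $O(96K)$.
- Initialization $a_i = \sum_j p_j / K$ is scale-aware; convexity makes
  the solution independent of it (tested with random restarts).
- The convergence tolerance is `factr = 1e7` (L-BFGS-B's default,
  a relative tolerance of about $2\times10^{-9}$). Much tighter settings
  push the line search below attainable floating-point precision for
  objectives of magnitude $10^8$ and fail spuriously, without improving
  the fit: across the test suite the refit objective stays within
  $1 + 10^{-6}$ times the objective of an active-set NNLS reference
  implementation.
- Exposures are reported in mutation-count units; fractions are obtained
  by normalizing rows of the exposure table.

## Shipped signature catalog

The package ships a synthetic, deterministic 30-signature catalog
(`synthetic_catalog_path()`), built from sparse Dirichlet backgrounds
plus concentrated motif mass for the signatures the pipeline exercises:
an age-like C>T-at-CpG signature (SI1), APOBEC-like signatures (SI2,
SI13), a smoking-like C>A signature (SI4), a flat signature (SI5), two
mismatch-repair-like signatures (SI6, SI26). Motifs were chosen so the
worst pairwise cosine similarity among the exercised signatures stays low
enough that a 3-signature mixture of 20,000 multinomial draws is
recovered within ±0.03 of truth (verified property, not a tuned seed).
The catalog is a fixture: it makes the *methods* testable; it is not a
biological reference, and any 96 × K catalog in the same TSV layout can
be substituted.

# Load statistics

- **SNP load**: retained records per patient.
- **Disrupted gene count**: distinct genes carrying a moderate
  (missense, in-frame indel) or severe (nonsense, frameshift, splice
  site, nonstop, translation start site) variant.
- **CNV load**: sum of absolute thresholded calls (values in −2…2).
- **Methylation change rate**: per gene, beta values are z-scored across
  the cohort; a patient's rate is the sum of absolute z-scores. The
  absolute value captures deviation in either direction; a signed variant
  is available behind a flag for directional analyses.

# Statistics

- **Spearman tests** use `stats::cor.test`, i.e. the exact null
  distribution for small tie-free samples and the Edgeworth (AS 89)
  approximation otherwise; at $n = 7$ the p-value is checked against full
  permutation enumeration (5,040 permutations). P-values of exactly 0
  (approximation underflow under perfect monotone association) are
  accepted as valid BH input.
- **Bootstrap confidence intervals** are percentile intervals over
  case-resampled Spearman correlations (default $B = 1000$), seeded and
  restoring the caller's RNG state. Degenerate resamples (constant
  vectors) are skipped and counted. Measured coverage at nominal 95% is
  ≥ 90% over 200 simulated cohorts, the expected behavior of percentile
  intervals for a correlation at $n = 60$.
- **BH control** uses `stats::p.adjust(method = "BH")`, checked against a
  literal step-up oracle.
- **Rank-sum and count comparisons** use `stats::wilcox.test` (exact for
  tie-free groups of ≤ 25) and `stats::fisher.test`.
- **Local median curves** summarize load versus age within ±10-year
  windows; windows with fewer than 3 observations report `NA`, and the
  median's confidence band is bootstrapped.
- Signature subgroups use cohort-mean thresholds with a **strict**
  inequality (ties classify as "low"), making the partition invariant to
  common rescaling of exposures.

## ssGSEA

The ssGSEA projection is implemented directly (no enrichment package is
delegated to, since the scoring rule itself is under test). For one
patient, genes are ordered by decreasing value; walking down that list
the score accumulates the difference between the weighted in-set ECDF
(weights $|r_j|^\alpha$ on ascending mid-ranks, default $\alpha = 0.25$)
and the unweighted out-of-set ECDF. Ranks, not raw values, carry the
weight, so any strictly monotone transform of the inputs leaves scores
unchanged. Degenerate sets (covering every gene) score 0 and disjoint
sets score `NA`, both flagged. The implementation is tested term-by-term
against a literal ECDF-accumulation oracle.

# Synthetic-cohort generator

The generator's purpose is falsifiable end-to-end testing: every latent
quantity (true exposure fractions, latent age variable, injected
artifacts) is archived so downstream estimates can be compared to truth.

**Age coupling by Gaussian copula.** Ages are uniform on 40–85 via the
probability transform of a latent normal $z_{\text{age}}$. A signature
with target Spearman correlation $\rho_s$ gets a latent normal with
Pearson correlation $r = 2\sin(\pi \rho_s / 6)$ to $z_{\text{age}}$ (the
exact normal-copula relation), and the patient's mixture fraction is a
strictly monotone logit-tilt of that latent. Because both maps are
monotone, the *rank* correlation with age equals the target in
expectation — no tuning loop is needed.

**Default parameters** emulate a tobacco-exposed squamous-cell lung
cohort: log-normal mutation counts with median 300 (exome scale);
mixture dominated by the smoking-like signature
(SI4 = 0.45, SI1 = 0.25, SI6 = 0.18, SI26 = 0.12); weak opposite-sign
age couplings for the mismatch-repair pair (−0.13 for SI6, +0.11 for
SI26) and a weak negative methylation-age coupling (−0.11) — effect
sizes typical of the age-association literature rather than convenient
large effects. Clinical category frequencies (gender 0.74/0.26; smoking
history 0.04/0.28/0.17/0.50/0.01 across the five TCGA categories; stage
0.49/0.32/0.175/0.015; transversion-high 0.82/0.18) match a squamous
lung cohort's published composition.

**Filter-exercising artifacts** are injected at realistic rates: a 0.2
per-record probability of a duplicate same-patient sample record (so
dedup removes $p/(1+p) \approx 17\%$), 0.001 two-gene annotations, and
0.088 repeat-failing contexts, reproducing the order of magnitude of the
removal trajectory observed in real exome MAFs. Injected repeat contexts
place a 6-copy mononucleotide run away from the central base so the
record's channel is still well defined before removal.

**Matrices.** CNV calls are sparse Bernoulli events with values in
{−2, −1, 1, 2}; methylation betas follow a logit-normal model whose
per-patient dispersion is copula-coupled to age when a methylation-age
correlation is requested.

# Problem sizes and runtimes

The shipped test and acceptance workloads are desk-scale by design:
10,000-context filter oracles run in seconds; 100 exposure refits of
20,000-mutation profiles run in well under two minutes; end-to-end
synthetic cohorts use 300 patients with ~120 mutations each
(≈ 36,000 records), which exercises every stage while keeping the whole
suite under a few minutes on one CPU.

# Limitations

- The shipped catalog is synthetic; analyses of real cohorts should load
  a published reference catalog in the same TSV layout.
- Exposure refitting assumes the catalog is complete; mutations from
  processes absent from the catalog are absorbed by the closest available
  signatures.
- The repeat filter sees only the provided reference context window, not
  the full genome; runs extending beyond the window are truncated.
- Bootstrap percentile intervals undercover slightly at small $n$;
  coverage is validated at ≥ 90% for nominal 95%, not at the nominal
  level itself.
- ssGSEA scores are comparable within a run (same gene universe and
  $\alpha$), not across universes.
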