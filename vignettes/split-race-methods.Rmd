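---
title: "Methods: simulating and calling split single-cell 3'-RACE data"
author: "splitrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calling split single-cell 3'-RACE data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitrace)
```

## The problem

The clustered protocadherins (Pcdh-α, -β, -γ) are tandem arrays of
cell-surface adhesion genes, each isoform driven by its own promoter.
Individual neurons activate a small, apparently stochastic subset of these
promoters, often from only one parental chromosome, so the expressed isoform
combination acts as a molecular identity tag. The β cluster (22 single-exon
genes in mouse) is the hardest to assay: with no spliced constant exon, a
conventional RT-PCR amplicon cannot be distinguished from genomic DNA.

The split single-cell 3'-RACE design solves this by (i) anchoring
amplification at the poly(A) tail, which only transcripts possess, and (ii)
splitting each cell's cDNA into three PCR tubes before nested amplification.
In an F1 hybrid of two sequenced strains (B6 × JF1), direct sequencing of
each tube's product at strain-discriminating variant sites reads out the
parental allele. A transcript detected in all three tubes (`3/3`), always
from the same allele, is monoallelic with high confidence; low-copy sampling
artifacts cannot reproduce across independent tubes.

This package implements the complete quantitative side of that design as
reusable, tested components: a generative simulator with known ground truth,
the allele-calling and QC rules, the statistical models, and the sequence
computations behind probe and primer design.

## The generative model

For each cell, allele $a \in \{A, B\}$ and isoform $i$:

* expression: $Z_{a,i} \sim \mathrm{Bernoulli}(q)$, independently per allele
  and isoform. The default $q = 0.052$ makes the expected number of distinct
  expressed genes per diploid cell $22\,(1 - (1-q)^2) \approx 2.2$, the
  repertoire size the assay estimates for the β cluster. Independence is the
  minimal assumption; no generative law is established for promoter choice.
* capture: each expressed $(a, i)$ pair contributes
  $C_{a,i} \sim \mathrm{ZTPois}(\mu)$ captured cDNA molecules ($\mu = 3$ by
  default). Zero truncation reflects conditioning on the pair being
  expressed; the small mean produces the realistic mixture of `3/3`, `2/3`
  and `1/3` tube patterns. No copy-number measurements exist for this assay,
  so $\mu$ is calibrated only to reproduce qualitative pattern frequencies.
* polyadenylation: every molecule draws a cleavage position from the gene's
  polyA-site usage weights. The default synthetic map gives each gene three
  sites — a major site, a minor site 4 nt away (same signal, shifted
  cleavage) and a rarer distal site — emulating the within-cell 3'-terminus
  heterogeneity observed in real Purkinje cells.
* splitting: molecules are assigned to the $k = 3$ tubes uniformly and
  independently (equal-volume aliquots ⇒ multinomial splitting). Molecule
  conservation across tubes is an invariant the test suite checks.
* amplification: a tube is positive for a gene iff it holds ≥ 1 template
  molecule *and* an independent $\mathrm{Bernoulli}(a)$ amplification
  succeeds ($a = 0.95$ by default).
* sequencing: within a positive tube, a variant site reads heterozygous when
  the minor allele's template fraction is ≥ $h = 0.20$ (a conventional
  Sanger minor-peak sensitivity), otherwise it reads the majority allele's
  base. Abundant control transcripts (`Pcp2`, `actin`, ~50 copies per
  allele) are simulated alongside, and one no-cell negative control is
  interleaved per 7 cells, mirroring the reference experiment's plate
  layout.

All randomness flows through R's RNG; `simulate_experiment()` seeds it once,
so a run is byte-identical given its seed.

```{r}
ex <- simulate_experiment(28, seed = 1)
ex
head(ex$dataset, 4)
```

## Allele calling and QC

`call_alleles()` reduces the tube-level table to one call per (cell, gene):

* any heterozygous site in any positive tube ⇒ **biallelic** — this is the
  expected readout for the abundant `actin` control;
* different clean tubes reading opposite pure alleles ⇒ **biallelic**: both
  alleles were demonstrably present in the cell's pooled cDNA. The split
  design implies this rule even though only within-tube heterozygosity is
  usually discussed;
* all readable tubes agreeing on one pure allele ⇒ **monoallelic-A/B**;
* sites disagreeing within a single tube ⇒ **inconsistent** (excluded from
  all fractions); bases matching neither allele are flagged as sequencing
  errors and excluded site-wise, and a product with no readable site is
  **insufficient**.

These five outcomes partition every product. The headline monoallelic
fraction is restricted to `3/3` products — partial (`2/3`, `1/3`) products
receive calls but cannot exclude single-molecule sampling, so they stay out
of the numerator and denominator.

The QC gate (`qc_gate()`) admits a cell only if `Pcp2` (cell-identity
marker) and `actin` (RT/amplification control) are positive in *all* tubes
and `actin` reads biallelic. "Intense expression" of the controls is
operationalised as all-tube positivity; with $a = 0.95$ a realistic minority
of simulated cells fails QC, as in real experiments.

## The statistical core

**Artifact null.** If each tube amplified only a single molecule whose
allele is an independent fair draw, a truly biallelic transcript would look
monoallelic in all $k$ tubes with probability $2 (1/2)^k$ — 25 % at
$k = 3$. `chi_square_monoallelic()` tests the observed (monoallelic,
biallelic) counts against this null with a plain 1-df Pearson goodness-of-fit
statistic, no continuity correction (the classical two-category test; the
choice is recorded in the output). `monte_carlo_artifact_rate()` generalises
the null to arbitrary copy-number regimes through the simulator; at one
molecule per allele the split design detects the second allele either as a
heterozygous tube or as opposite pure tubes, so the artifactual `3/3` rate
is exactly zero — enumeration and simulation agree.

**Repertoire estimation.** With $n$ fully consistent products observed over
$N$ QC-passed cells on a panel of $m$ assayed genes,
`genes_per_cell(n, N)` = $n/N$ genes per cell on the panel, and
`extrapolate_repertoire()` scales by $22/m$ under the stated no-distortion
assumption. The estimator input is the *count of products* (gene–cell
pairs), not the count of positive cells: the expected number of products per
cell on an $m$-gene panel is $m\,(1-(1-q)^2)$, which extrapolates exactly to
the cluster-wide repertoire $22\,(1-(1-q)^2)$, whereas the fraction of cells
with ≥ 1 positive gene does not. In the reference dataset the two numerators
coincide (18), so the printed arithmetic (0.64, then 2.3) is reproduced
either way. Reporting conventions (2 decimals for the rate, 1 for the
extrapolation) match the printed values.

**Diversity.** One isoform per allele and distinguishable alleles give
$n(n-1)$ ordered pairs per cluster — 132, 462 and 342 for 12, 22 and 19
isoforms — and `total_diversity()` multiplies across clusters in exact
double-precision integer range (20,856,528 > 20 million).

```{r}
fx <- build_reference_dataset(quiet = TRUE)
reference_statistics(fx)[c("monoallelic", "rate_per_panel",
                           "repertoire_per_cell", "diversity")]
```

## The reference dataset

`build_reference_dataset()` transcribes the published 28-cell Purkinje
experiment: the 18 fully consistent products with their calls (17
monoallelic, 1 biallelic), the named partial products, the five no-cell
controls and the printed aggregate counts (including the 7 B6 / 10 JF1
parental totals, known only in aggregate — per-product parental origin is
stored as `NA`, never imputed). The printed source is internally
inconsistent in three places (a product listed twice; 14 distinct listed
`3/3` cells against printed counts of 15 and 18; per-pattern cell counts
summing to 22 against a printed 21). The fixture keeps every number as
printed and emits a warning for each discrepancy rather than reconciling
them.

## Probe and primer computations

"Similarity" between sequences is operationalised as percent identity, in
two deliberate flavours:

* whole-sequence comparisons (`global_percent_identity()`,
  `find_discriminating_variants()`) use a global pairwise alignment
  (match +1, mismatch −1, gap open −2, gap extend −0.5; terminal gaps
  excluded from the identity denominator). The scoring is fixed and recorded
  here for reproducibility; the test suite checks the alignment scores
  against an independently written affine-gap dynamic programme.
* probe-window scans (`find_pan_probe_region()`,
  `find_specific_probe_region()`) use *ungapped* windows, because a
  hybridisation probe binds contiguously: a window's identity to a sequence
  is its best ungapped match fraction over all placements. A pan-family
  window must reach ≥ 84 % against every family member (worst case); an
  isoform-specific window must stay ≤ 65 % against every off-target (best
  case). The two criteria are mutually exclusive on the same comparison set,
  which the suite verifies. Whether the published 84 %/65 % figures refer to
  global or best-local identity is not stated; the definitions used here are
  recorded with every report.

Polyadenylation analysis scans for the canonical hexamers `AATAAA`/`ATTAAA`
wholly within 10–40 nt upstream of a cleavage position, and
`cluster_3prime_termini()` groups observed cleavage positions by
single-linkage with a gap tolerance: tolerance 0 separates
adjacent-nucleotide heterogeneity (same signal, cleavage shifted by one
base) from distinct sites, and the cluster count is non-increasing in the
tolerance. Coordinates are 1-based inclusive throughout; all computations
are on the sense strand of the supplied sequences (the antisense nature of
the actual probes is a labelling concern only).

## What the simulator does and does not capture

The generator reproduces the statistical structure the inference relies on:
stochastic per-allele promoter choice, low-copy capture, multinomial tube
splitting, amplification dropout, Sanger-like heterozygous calling and
polyA-site mixtures. It does not model PCR chemistry or efficiency kinetics,
chromatogram waveforms, cell-picking contamination, RNA degradation, or any
spatial correlation between neighbouring cells. Passing recovery tests
therefore shows the *inference rules* are correct under the stated model,
not that real experiments meet the model's assumptions — the QC gate and the
split-tube consistency requirement are precisely the defences the real assay
uses where they do not.

## Numerical choices and problem sizes

* Zero-truncated Poisson sampling uses the inverse-CDF restricted above
  $P(0)$, exact for all $\mu$.
* At the default capture regime ($\mu = 3$, $a = 0.95$) the probability that
  an expressed gene yields a `3/3` product is only ≈ 0.23 (all three tubes
  must be covered and amplify), so `3/3`-based repertoire recovery is
  validated in the high-capture regime ($\mu = 30$, $a = 1$), where
  detection is essentially complete; the closed-form mean
  $22\,(1-(1-q)^2)$ is checked at the default regime directly on the
  simulation ground truth.
* Test problem sizes — 10,000 cells for the closed-form mean, 500 cells for
  truth-class recovery, 2,000 cells for repertoire recovery, 100,000
  Monte-Carlo replicates for the artifact null — were chosen so Monte-Carlo
  error sits well inside each asserted tolerance (e.g. ±0.05 ≈ 3.5 standard
  errors at 10,000 cells).
* Ties in 3'-terminus cluster representatives resolve to the smallest
  position; window scans return results sorted by their qualifying identity
  so the best candidate is first.

## Known limitations

* The per-allele independence of isoform choice is an assumption; any
  promoter-exclusion or coupling mechanism would change the biallelic truth
  rate $q^2/(1-(1-q)^2)$ the defaults imply.
* The repertoire extrapolation inherits the no-frequency-distortion
  assumption of the original estimator; isoform-biased expression would bias
  it.
* The artifact null's "general" regime fixes the number of captured
  molecules per allele rather than integrating over the capture
  distribution; it is meant for sensitivity analysis, not as a fitted model.
* Probe scans consider the supplied comparison set only (cluster paralogs);
  genome-wide off-target screening is out of scope.
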