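---
title: "Methods: integrated miRNA:mRNA time-course network inference"
author: "mirnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA:mRNA time-course network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnet)
```

## The problem and the model

`mirnet` reconstructs phase-resolved microRNA regulatory networks from a
paired expression time course of the kind used to dissect growth-factor
induced differentiation: lens epithelial explants treated with FGF2 and
profiled at 0, 2, 4, 12 and 24 hours in biological duplicate, with mRNA
abundance measured on expression arrays (log2 intensities) and miRNA
abundance on qPCR cards (Ct values). The 2–4 h window is the *early*
response phase (cell-cycle exit signalling) and the 12–24 h window the
*late* phase (onset of fiber-cell differentiation); the package treats the
phase split generically as the first and second half of the post-treatment
grid.

The analysis chain is:

1. **Differential expression.** Per feature, a one-way fixed-effects ANOVA
   across the time-point groups, and per post-treatment time point a log2
   fold change against the t = 0 baseline,
   $\log_2 FC(t) = \overline{x}_t - \overline{x}_0$. A time point is
   *up*/*down* when the linear ratio meets the threshold (inclusive):
   1.25-fold for array mRNA data, 2-fold for qPCR miRNA data. A feature
   passes the filter when ANOVA p < 0.05 and it is modulated at a minimum
   number of time points (2 for miRNAs, 1 for mRNAs).
2. **Temporal classification.** Each miRNA's fold-change profile is
   Pearson-correlated with four idealised templates — early classes deviate
   at 2 and 4 h and return to baseline, late classes deviate at 12 and
   24 h — and assigned to the best template subject to $r \ge r_{min}$, a
   permutation test, and phase-consistent modulation.
3. **Target prediction.** Canonical seed matching on 3′-UTR sense strands:
   6mer (reverse complement of miRNA positions 2–7), 7mer-m8 (positions
   2–8), 7mer-A1 (6mer plus an `A` opposite position 1, required in the UTR
   regardless of the miRNA's first base), and 8mer (7mer-m8 plus that `A`).
   Occurrences are typed maximally; an 8mer locus is never double-reported
   as its nested 7mers.
4. **Inverse pairing.** For each of the four miRNA classes, target genes
   are the predicted targets that are differentially expressed in the
   *opposite* direction at ≥ 1 time point of the *same* phase. Each pairing
   reports its edges, the fraction of the phase/direction DE genes covered,
   and the Pearson correlation between the miRNA-set and target-set median
   profiles.
5. **Network layer.** The union of phase edge sets forms a bipartite
   miRNA→gene network. Connectivity is distinct-partner degree (a regulator
   hitting a gene in both phases counts once in the total); nodes are
   ranked by it. Hubs are maximal sets of ≥ 3 miRNAs jointly regulating
   ≥ 2 common genes of a user-supplied functional group, and genomic miRNA
   clusters are single-linkage chains of loci within a 20 kb window on one
   chromosome — the scale of polycistronic clusters such as the rat chr6q32
   locus, where three co-regulated miRNAs lie within ~13 kb.
6. **Enrichment.** Plain hypergeometric over-representation of target lists
   against GMT gene sets with Benjamini–Hochberg FDR, the generic form of
   GO/KEGG term analysis. The universe defaults to the genes on the
   expression matrix, not the genome.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `fc_mrna` | 1.25 | linear ratio | conventional array cutoff for subtle transcriptome shifts |
| `fc_mirna` | 2.0 | linear ratio | one Ct unit; qPCR differences below 2-fold are unreliable |
| `alpha` | 0.05 | – | per-feature ANOVA and permutation cutoff; no multiplicity correction by default (a BH option exists) |
| `min_timepoints` (miRNA) | 2 | count | requires reproducible modulation across the time course |
| `r_min` | 0.8 | correlation | template shapes are coarse; 0.8 keeps only unambiguous matches |
| `n_permutations` | 10 000 | count | resolves p ≈ 2.5 × 10⁻⁵ with plus-one correction |
| `site_types` | ≥ 7mer-A1 | – | plain 6mers carry little specificity and are excluded by default |
| `window_bp` | 20 000 | bp | polycistronic miRNA cluster scale |

## Numerical and design choices

* **Replicate-level template matching.** Correlation and the permutation
  test run on replicate-resolved fold-change profiles
  (time points × replicates entries), not on the 4-point replicate mean.
  With only four post-treatment time points a label permutation of the mean
  profile has 4! = 24 distinct states, so a plus-one-corrected permutation
  p can never fall below 2/25 = 0.08 and no feature could ever be accepted
  at α = 0.05. Expanding over replicates both restores resolution (8! label
  states for a duplicate design) and encodes the requirement that a match
  be reproducible across replicates. Template values are constant within a
  time point, so the expansion does not change what shape is being matched.
* **Inclusive thresholds with a 1 × 10⁻⁸ tolerance.** Fold-change and band
  boundaries are inclusive; the tolerance only absorbs floating-point
  representation of values like `log2(1.25)`.
* **Band percentages are truncated, coverage percentages rounded.** Peak
  fold-change bands (≥ 3-fold up, 2–3-fold up, ≥ 2-fold down; a peak ratio
  of exactly 3 belongs to the ≥ 3-fold band) are reported as percentages of
  the class total truncated toward zero, so the three bands can never sum
  past 100%. Coverage percentages round to the nearest integer and the
  cross-phase overlap percentage uses the *sum* of the two phase totals as
  denominator, reported to one decimal.
* **Probe collapse.** Analysis is keyed on gene symbols; where several
  probes interrogate a gene, the probe with the highest median intensity is
  kept and the choice is recorded. Unmapped probes are set aside with a
  message, never dropped silently.
* **Undetermined Ct values** are imputed at a detection ceiling (Ct 40) and
  flagged; features flagged in more than 25% of samples are excluded with a
  reported count.
* **Zero-variance features** have an undefined F statistic and are assigned
  ANOVA p = 1 with a warning; perfectly separated features (zero
  within-group variance, non-zero between) get p = 0.
* **Ties.** Template ties break by the larger mean |log2 FC| in the
  template's active phase, then by template name; ranking ties break
  lexicographically, making the output invariant to input order.
* **Hub enumeration is exact.** Maximal co-regulating miRNA sets are found
  by closing over gene pairs of the group (every maximal set containing a
  shared gene pair is the full regulator set of that pair), then pruning
  non-maximal candidates; a cap on the number of gene pairs guards the
  search and fails with an instruction to tighten the group.

## What the synthetic generator emulates

`simulate_dataset()` plants the full causal structure the pipeline is
supposed to recover: temporal classes for 204 miRNAs in the proportions
50/16/36/29/73 (the fifth group flat), ~2.8-fold miRNA modulation at the
active time points, seed sites of types ≥ 7mer-A1 embedded at recorded UTR
positions, repression transferred additively on the log2 scale in
proportion to site count and regulator deviation, miRNA-independent direct
effects, duplicate probes for a fraction of genes, Gaussian array noise,
and Ct-scale qPCR noise around a fixed `U6` reference row. Flat miRNAs and
direct-effect-only genes act as planted negatives. Defaults use 2000 genes
with 1 kb UTRs and 5–15 targets per miRNA — sizes at which every stage's
behaviour is measurable in seconds on one CPU.

Two masking constraints are enforced at generation rather than repaired
afterwards: direct effects are only assigned to genes without planted
sites, and no gene accepts both an up- and a down-regulator of the same
phase. Both situations would make the planted truth self-contradictory —
the net fold change of such a gene can be exactly zero, so no method could
recover the planted edge from expression data, and recovery metrics would
measure the generator's self-cancellation rather than the pipeline.

The generator does **not** emulate probe-level effects, array
normalisation artefacts, amplification chemistry, miRNA biogenesis
dynamics, repression saturation, or 3′-compensatory/non-canonical sites.
Passing recovery tests on this data therefore demonstrates correctness of
the inference chain under its own model assumptions, not performance on
real microarray/TLDA data, where fold changes are compressed and targeting
is context-dependent.

## Noise defaults

Array noise magnitudes are free parameters of the generator, not estimates
of any particular dataset: `noise_sd_log2 = 0.2` is a typical
between-replicate residual spread for well-behaved two-colour or GeneChip
experiments after normalisation, and `ct_noise_sd = 0.2` a typical
technical Ct spread for pre-amplified TaqMan cards. With a 1.5 log2 effect
these defaults give a realistic but unsaturated signal-to-noise regime.

## Limitations

* Pairing is correlational: an inverse edge is a prediction, not a causal
  claim, and genes can enter a phase target set through incidental
  background seed matches.
* With four post-treatment time points the analytic significance of a
  4-point correlation is essentially meaningless; the permutation approach
  works at the replicate level but still cannot distinguish shapes that
  agree on the rank order of all eight entries.
* The SOM view is exploratory only; nothing downstream consumes it.
* Cross-species identifier reconciliation is delegated to the annotation
  map; no orthology inference is attempted.
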