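# mirnet

Integrated miRNA:mRNA time-course network inference in R.

`mirnet` is for transcriptomics groups that profile a perturbation time
course twice — mRNA on expression arrays and miRNA on qPCR cards — and want
to turn the two matrices into a phase-resolved microRNA regulatory network.
The motivating design is growth-factor induced differentiation (FGF2-treated
lens epithelial explants sampled at 0, 2, 4, 12 and 24 h in biological
duplicate), but any time grid with a baseline and replicated post-treatment
points works.

## What it computes

For feature *f* at post-treatment time *t*, differential expression is
log2 FC(*t*) = x̄(*f*,*t*) − x̄(*f*,0) with a one-way ANOVA across time-point
groups; features passing *p* < 0.05 plus a fold-change/modulation rule
(≥ 1.25-fold for mRNA at ≥ 1 time point; ≥ 2-fold for miRNA at ≥ 2 time
points) are kept. miRNAs are assigned to *early-up / early-down / late-up /
late-down* classes by Pearson correlation with idealised temporal templates
(early classes deviate at 2–4 h and return to baseline; late classes at
12–24 h), gated by a permutation test on replicate-level profiles. Targets
are predicted by canonical seed matching on 3′-UTRs (site types 6mer,
7mer-A1, 7mer-m8, 8mer; ≥ 7mer-A1 retained by default), and each miRNA
class is paired with the predicted targets regulated in the **opposite**
direction in the **same** phase. The union of the four pairings is a
bipartite miRNA→gene network with distinct-partner connectivity
(targets per miRNA, upstream regulators per gene, split early/late),
connectivity rankings, hub detection (≥ 3 miRNAs jointly regulating ≥ 2
functionally related genes), genomic miRNA clustering (20 kb chaining), and
hypergeometric over-representation of target lists against GMT gene sets.

A synthetic-data generator (`simulate_dataset()`) plants all of this
structure — temporal classes, embedded seed sites, additive log2
repression, direct effects, array and Ct noise — together with a ground
truth, so the whole chain is testable end to end without external data.

## Worked example

```r
library(mirnet)
sim <- simulate_dataset(simulation_config(rng_seed = 1))
rep <- run_pipeline(run_config(sim = sim, rng_seed = 1))
rep
#> miRNA:mRNA time-course inference report
#>   classified miRNAs: early_up=50, early_down=16, late_up=35, late_down=29 (total 130)
#>   phase target totals: early=726 late=741 (overlap 313, 21.3%)
#>   fold-change bands: up_3fold=42 (32%), up_2to3fold=43 (33%), down_2fold=45 (34%)
#>   network: 6664 edges; top miRNA miR-sim-014 (74 targets); top gene gene00889 (19 regulators)
#>   genomic clusters: chr6[miR-sim-001,miR-sim-002,miR-sim-003]

rank_top(rep$network, "miRNA", 3)
#>            id early late total rank
#> 1 miR-sim-014    74     0    74    1
#> 2 miR-sim-026    71     0    71    2
#> 3 miR-sim-036    70     0    70    3
```

The report reads: of the 204 simulated miRNAs, 130 were classified into the
four temporal classes (one planted late-up miRNA missed the correlation
cutoff); their inversely regulated predicted targets number 726 genes in the
early phase and 741 in the late phase, 313 genes appearing in both; the
planted chr6 cluster of three neighbouring miRNA loci is recovered. Compared
against `sim$truth`, class recovery is 99.5% and planted inverse-edge recall
98.5% under the default noise settings.

Real data enter through files instead of `sim`: a probe-level log2 TSV
(`read_expression_tsv()`), a Ct TSV with a `U6` reference row
(`layout = "ct_with_reference"` applies log2(abundance) = Ct_ref − Ct),
probe annotation, UTR and mature-miRNA FASTA, miRNA BED and optional GMT
sets — see `?run_config`.

## Package layout

* `R/simulate.R` – synthetic time-course generator with planted truth
* `R/io_tables.R`, `R/io_sequences.R` – TSV/FASTA/BED/GMT/SIF/GraphML I/O
* `R/diffexp.R` – ANOVA, fold-change calls, modulation rule, banding
* `R/temporal.R` – templates, matching, PCA/clustering/SOM overviews
* `R/targets.R` – seed-site scan, prediction tables, UTR fragmentation
* `R/pairing.R` – phase-wise inverse pairing and summaries
* `R/network.R` – connectivity, ranking, hubs, genomic clusters
* `R/enrich.R` – over-representation analysis
* `R/pipeline.R` – orchestration and the reporting arithmetic
* `vignettes/mirnet-methods.Rmd` – model, assumptions, design choices
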