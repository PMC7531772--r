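# phylorep

Phylogenetic comparative analysis of gene repertoire evolution.

## What it is for

Comparative genomicists repeatedly face the same question: is a
functional gene set (say, the apoptosis network) *specifically* depleted
in one clade (say, Ecdysozoa — flies, nematodes and relatives), or does
its thinner repertoire just reflect global genome reduction and shared
ancestry?  And is repertoire richness linked to the domain architecture
of a master regulator (p53's TAD, DNA-binding, TET and SAM domains)
across the tree?  `phylorep` packages the full chain of analyses needed
to answer this from a rooted species tree, an orthogroup count matrix
(taxa × orthogroups), locus-level domain-architecture records, a curated
gene-set-to-orthogroup map, and a clade partition:

| Stage | Function | Model / statistic |
|---|---|---|
| Gain/loss histories | `dollo_reconstruct()` | Dollo parsimony: one gain at the MRCA of carriers, minimal losses (oracle-verified) |
| Clade enrichment | `clade_enrichment_scan()` | Fisher–Pitman permutation test per orthogroup (exact when `choose(n, n_A) <= 20000`), BH FDR |
| Genome-reduction control | `depletion_contrast()` | d = ln((count_A + 1)/(count_B + 1)); focal vs background Wilcoxon rank-sum |
| Phylogenetic signal | `blomberg_k()`, `pagel_lambda()` | K = (observed/expected MSE ratio); λ̂ = argmax profile likelihood on [0, 1] |
| Domain → repertoire | `pgls_fit()`, `pgls_scan()` | GLS with Brownian covariance C: β̂ = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y |
| Global association | `cca_fit()`, `cca_permutation_test()` | chi-square-metric CCA, pseudo-F = (CI/q)/(RI/(n−q−1)), permutation p |
| Synthetic data | `simulate_dataset()` | Yule tree, Dollo characters, Poisson counts with clade-biased depletion δ |
| Orchestration | `run_pipeline()`, `render_report()` | deterministic, seeded, JSON report |

Everything is seeded and deterministic; the synthetic-data generator
produces every input format the pipeline reads, with a truth table for
power/recovery studies.

## Worked example

```r
library(phylorep)
report <- run_pipeline(list(seed = 1, simulate = list()))
cat(render_report(report), sep = "\n")
```

```
phylorep pipeline report (version 0.1.0, seed 1)
gene set: 137 curated genes; 56 unmapped; 81 mapped onto 59 distinct orthogroups (22 sharing an orthogroup)
enrichment: 30 of 59 focal orthogroups enriched in retained_clade and 0 in loss_clade (FDR < 0.1)
depletion: focal vs background log-ratio Wilcoxon W = 23748, p = 7.26e-10 (59 focal, 500 background)
signal (repertoire size): K = 0.87, lambda =    1
signal (genome size): K = 0.805, lambda =    1
ols repertoire ~ genome size: r2 = 0.621, slope = 72.3, p = 3.84e-07
dollo: root repertoire 59 orthogroups (additive total 126); 203 losses, 97 within the loss clade; domain losses 9
cca: F(4, 24) =  1.4, p = 0.002
pgls: 8 of 59 focal orthogroups predicted by >= 1 domain (FDR < 0.1)
```

Reading this: the default synthetic profile plants δ = 0.2 depletion on
half of 59 focal orthogroups inside a 9-taxon loss clade, on top of a
clade-wide genome-size reduction.  The enrichment scan recovers the
depleted orthogroups (30 of 59 significant, none in the reverse
direction); the Wilcoxon contrast shows the focal set is more depleted
than the 500-orthogroup background (so the signal is not just global
genome shrinkage, even though repertoire size does track genome size,
r² = 0.62); Dollo reconstruction attributes 97 of 203 orthogroup losses
to branches inside the loss clade; and the CCA permutation test finds a
global association between the four domain counts and repertoire
composition (F(4, 24) = 1.4, p = 0.002), with 8 orthogroups individually
predicted by a domain after phylogenetic and genome-size correction.

To analyse real data instead, point the config's `files` block at a
Newick tree, count-matrix TSV, domain-architecture TSV, clade TSV and
gene-set TSV (formats documented in the function help pages), or call
the stage functions directly.

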