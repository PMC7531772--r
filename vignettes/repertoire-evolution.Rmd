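---
title: "Linking gene-repertoire evolution to domain architecture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking gene-repertoire evolution to domain architecture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylorep)
```

# The scientific problem

Animal genomes differ enormously in how many copies of a gene family they
retain.  A recurring pattern in comparative genomics is clade-wise
*depletion*: an entire lineage (for example the molting animals,
Ecdysozoa) carries systematically fewer members of some functional gene
set — such as the apoptosis network — than its sister lineages, while a
master-regulator locus (p53) in the same lineage has lost most of its
accessory protein domains (transactivation, tetramerisation,
sterile-alpha-motif), retaining only the DNA-binding domain.  Deciding
whether such a pattern reflects genuine, set-specific gene loss rather
than (a) global genome reduction, (b) duplications elsewhere in the tree,
or (c) shared phylogenetic history requires a connected chain of
comparative analyses.  `phylorep` implements that chain as reusable,
tested components:

1. **Dollo parsimony** histories of binary characters (domain presence,
   orthogroup presence) on a rooted species tree — a character may
   originate once and be lost repeatedly, never re-originate.  This is
   the appropriate model for complex genetic loci whose independent
   re-invention is vanishingly unlikely.
2. **Clade-wise enrichment/depletion tests**: one Fisher–Pitman
   permutation test per orthogroup on per-taxon gene counts, grouped by
   clade, with Benjamini–Hochberg FDR control across orthogroups.
3. A **depletion log-ratio contrast**: per orthogroup,
   `d = ln((count in clade A + c) / (count in clade B + c))`, comparing the
   focal set's distribution of `d` against the genomic background by a
   Wilcoxon rank-sum test.  This is the control for global genome
   reduction: if the focal set is only as depleted as everything else,
   the contrast does not reject.
4. **Phylogenetic signal** (Blomberg's K, Pagel's λ) of repertoire size
   and genome size, and an uncorrected OLS of repertoire size on genome
   size.
5. **PGLS** (phylogenetic generalized least squares) of per-orthogroup
   counts on per-taxon domain counts plus genome size, under a
   Brownian-motion correlation structure — the phylogenetically corrected
   test of whether domain architecture predicts repertoire richness.
6. **CCA** (canonical correspondence analysis) of the taxa × orthogroup
   count table constrained by the four domain-count columns, with a
   permutation pseudo-F test of the global association.

# Statistical models and estimators

## Phylogenetic covariance

All tree-aware statistics use the Brownian covariance matrix `C` with
`C[i,j]` the root-to-MRCA shared path length of tips *i* and *j*
(`vcv_matrix()`).  Pagel's transform multiplies the off-diagonal of `C`
by λ, leaving tip variances unchanged (`lambda_transform()`); λ = 0 is a
star (no phylogenetic structure), λ = 1 pure Brownian motion.  All
matrix-producing operations carry an explicit tip-label index and are
reconciled by label, never by position.

## Blomberg's K

`blomberg_k()` computes the ratio of the observed MSE ratio to its
Brownian expectation,

K = [ (y−â1)ᵀ(y−â1) / (y−â1)ᵀC⁻¹(y−â1) ] ÷ [ (tr C − n/(1ᵀC⁻¹1)) / (n−1) ],

with â the GLS mean `(1ᵀC⁻¹1)⁻¹1ᵀC⁻¹y` (`phylo_mean()`).  K equals 1
exactly on a star phylogeny for any non-constant trait and is centred on
1 under Brownian motion; both properties are verified by the test suite
(the latter over 500 simulations on a 64-tip pure-birth tree).  A
tip-shuffling randomization test is available but off by default, since
the typical use reports point estimates.

## Pagel's λ

`pagel_lambda()` maximises the profile log-likelihood of
`y ~ Normal(â1, σ²·λ-transform(C))` over λ ∈ [0, 1], with â and
σ̂² = RSS/n profiled out.  The search is a 21-point grid followed by
bounded scalar optimization (`stats::optimize`, tolerance 1e-6) in the
bracketing interval; ties go to the grid argmax, and a non-converging
optimizer falls back to the grid.  The bound λ ≤ 1 is deliberate: values
above 1 are hard to interpret and can break positive-definiteness.  The
suite verifies recovery at both ends (mean λ̂ ≥ 0.9 under Brownian
simulation, ≤ 0.1 under i.i.d. simulation, 200 replicates each) and that
the optimizer matches a 1001-point grid within 0.005.

## PGLS

`pgls_fit()` solves `β̂ = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y` through the Cholesky factor
of `C` (never an explicit inverse), with
σ̂² = (y−Xβ̂)ᵀC⁻¹(y−Xβ̂)/(n−p) and Student-t inference on n−p degrees of
freedom.  With `tree = NULL` the fit reduces to OLS exactly, and the
unit tests confirm coefficient-level agreement with an independent GLS
implementation (`nlme::gls` with a Brownian correlation).  The scan over
orthogroups × domains (`pgls_scan()`) fits, for every pair, the model
`count ~ domain + genome size` under fixed Brownian correlation.  Two
choices here were genuinely open:

* **Count transform.** Counts enter as `log(count + 1)` by default
  (variance stabilisation for Poisson-like counts across taxa whose
  repertoires span an order of magnitude); `transform = "none"` fits raw
  counts.
* **Multiplicity.** p-values across the whole scan are BH-adjusted
  jointly by default (`adjust = "global-BH"`); per-domain adjustment and
  no adjustment are available, since conventions differ between studies.
* **λ in PGLS.** The correlation structure is fixed Brownian rather than
  jointly λ-estimated, matching the common "BM correlation" formulation;
  λ estimation is available separately via `pagel_lambda()`.

## Fisher–Pitman permutation test and FDR

`fisher_pitman()` uses the difference of group means as its statistic —
the canonical choice for this test family — and enumerates all
`choose(n, n_a)` group assignments exactly whenever that count is at most
20,000 (e.g. two clades of 8 taxa: 12,870 assignments), reporting the
exact proportion of assignments at least as extreme.  Larger designs use
9,999 seeded Monte-Carlo permutations with the add-one correction
`(b + 1)/(B + 1)`.  Taxa are the permutation units: the test treats taxa
as exchangeable within clade groups, which ignores within-clade
phylogenetic structure — a known limitation of this class of analysis,
stated rather than patched (the PGLS stage is the phylogenetically
corrected counterpart).  `bh_fdr()` is the Benjamini–Hochberg step-up
adjustment; the default significance level is FDR < 0.1.

## Depletion contrast

`depletion_contrast()` adds a pseudocount (default 1) to *both* clade
totals so that orthogroups completely lost in one clade — precisely the
biological signal of interest — remain finite; `drop_zeros = TRUE` with
pseudocount 0 is the alternative.  The Wilcoxon test is exact when both
groups have at most 12 tie-free values, otherwise the normal
approximation with mid-ranks and tie correction is used.  Because
software conventions differ, the reported `W` is explicitly the rank-sum
of the focal group (the Mann–Whitney `U` is also returned).

## CCA

`cca_fit()` implements the standard chi-square-metric constrained
ordination: relative frequencies, standardized residuals
`Q̄ = (p_ij − p_i·p_·j)/√(p_i·p_·j)`, row-weighted regression of `Q̄` on
the standardized constraints, and SVD of the fitted table.  Total
inertia equals the Pearson chi-square of the table divided by its grand
total; constrained + residual inertia equals total inertia to 1e-9 by
construction (projection), and eigenvalues agree with an independent
implementation (`vegan::cca`) to 1e-8 in the tests.  The pseudo-F uses
`(q, n − q − 1)` degrees of freedom, with `q` the effective (post-drop)
rank of the constraints; `cca_permutation_test()` permutes rows of the
constraint matrix jointly (no blocking), 999 permutations by default.
Degenerate inputs are handled by dropping: all-zero rows/columns of the
count table and constant or collinear constraint columns, each with a
warning.  Counts enter raw — the chi-square weighting *is* the
transform.

## Dollo reconstruction

`dollo_reconstruct()` places the single gain of each character on the
branch subtending the MRCA of all carrier tips (on the root itself when
that MRCA is the root — so an outgroup lacking the character stays in
state 0), and the losses on the branches subtending the maximal
carrier-free subtrees inside the gain clade.  Under the MRCA-gain rule
this placement is unique and achieves the minimum loss count over all
single-gain labelings; the acceptance suite proves minimality against
brute-force enumeration of every internal labeling for every binary tip
pattern on random trees of up to 8 tips.  Characters absent from all
tips yield an empty reconstruction, not an error.  Orthogroup presence is
binarized at count ≥ 1 by default (configurable threshold).  For additive
ancestral repertoire totals the default per-orthogroup weight is the
modal non-zero extant count — ancestral nodes are credited with a
"typical" copy number rather than presence alone (`weights = NULL` in
`ancestral_repertoire()` gives presence counts).

# The synthetic-data generator

The raw inputs of the motivating analyses (genome assemblies, orthology
inference, Pfam scans) are deliberately out of scope; `phylorep` consumes
their tabular products.  `simulate_dataset()` generates all of them with
known truth so every stage is testable end-to-end:

* an ultrametric pure-birth tree (default 29 taxa, birth rate 1),
  simulated forward with exponential waiting times;
* a designated **loss clade** (the internal node with tip count closest
  to 9) versus the retained remainder;
* per-taxon **domain profiles**: the DNA-binding domain is universal;
  each accessory domain (TAD, TET, SAM) is independently lost by a
  loss-clade taxon with probability 0.9, and counts for present domains
  are 1 + Poisson(1) — matching the observed contrast between
  domain-rich and single-domain p53 architectures;
* a **genome-size covariate** evolving by Brownian motion (σ² = 1) with a
  0.5 downward shift in the loss clade, emulating clade-wide genome
  reduction, and feeding back into counts with coefficient 0.3 — this
  creates the confound that the depletion contrast and PGLS stages are
  designed to control for;
* an **orthogroup count matrix** of 59 focal plus 500 background
  orthogroups with `N_gt ~ Poisson(μ_g · exp(β·D_t + γ·g_t) · m_gt)`,
  where `μ_g` is log-normal around 2 (sdlog 0.5), `D_t` the taxon's total
  domain count (β = 0.05), `g_t` the centred genome-size covariate, and
  `m_gt = δ = 0.2` for the depleted half of the focal set in loss-clade
  taxa (1 otherwise);
* a **curated gene set** of 137 genes, 56 unmapped, the remaining 81
  homologised many-to-one onto the 59 focal orthogroups — exercising the
  bookkeeping of `map_gene_set()`.

These defaults mirror the scale of a 29-genome metazoan study without
copying any real data.  Where the motivating analyses did not pin a
value (baseline Poisson mean, domain-loss probability, linkage and
genome-effect coefficients, clade shift) the defaults were chosen once
as plausible for gene-family counts of this kind and are not tuned.
What the generator does **not** emulate: ascertainment bias of orthology
assignment, between-taxon annotation-quality differences, correlated
loss of functionally linked orthogroups beyond the shared clade effect,
and non-Poisson overdispersion.  Green tests therefore demonstrate
correctness and calibration of the machinery under its stated model, not
robustness to those real-data pathologies.

Reproducibility: every generator takes a seed; `simulate_dataset()`
derives an independent sub-stream per component (tree, domains, genome
size, counts, gene set) from the run seed, so adding a component never
perturbs the others, and identical configs are bit-reproducible.

# The pipeline

`run_pipeline()` wires the stages in a fixed order (gene-set mapping →
enrichment scan → depletion contrast → signal → OLS → Dollo → CCA →
PGLS scan), derives one sub-seed per stochastic stage, and returns a
report that serialises to JSON (`write_report()`) and renders to
headline text (`render_report()`).  A config is a plain list or a YAML
file, with either a `simulate` block or a `files` block naming the five
standard inputs (Newick tree; count TSV; domain-architecture TSV; clade
TSV; gene-set TSV; optional covariate TSV).  Reruns with the same config
and seed are byte-identical apart from the timestamp.  The exported
functions are the interface; `scripts/acceptance.R` in the repository is
a worked example of driving the default profile from the command line.

```{r example, eval = FALSE}
report <- run_pipeline(list(seed = 1, simulate = list()))
cat(render_report(report), sep = "\n")
```

# Numerical choices and degenerate inputs

* All GLS-type solves go through Cholesky factors; singular covariances
  are reported as errors, not silently regularised.
* Permutation p-values are compared with a relative 1e-12 slack so exact
  enumeration is immune to floating-point ties.
* Constant traits make K undefined (error); constant constraint columns
  make CCA's constrained inertia 0 (not an error).
* Count matrices reject negative and non-integer cells; empty cells
  become 0 with a warning; a transposed table (taxon labels in the
  header) is rejected with a clear message, never silently transposed.
* Trees must be rooted; a basal polytomy is accepted only with
  `force_rooted = TRUE`.  Missing branch lengths are an error unless
  `unit_branch_lengths = TRUE`.
* Clade partitions must be disjoint; non-monophyletic clades are an
  error by default, with `monophyly = "warn"`/`"ignore"` overrides (the
  complement of a clade is legitimately paraphyletic).

# Problem sizes used by the test suite

The acceptance-style checks run at the sizes stated with each property:
Dollo oracle equivalence exhaustively over all 2^n tip patterns on 20
random trees of 4–8 tips; K and λ calibration on a 64-tip tree with
500 and 200 replicates respectively; PGLS recovery on 200 64-tip
datasets; FDR calibration on 200 null matrices of 16 taxa × 50
orthogroups with exact (12,870-assignment) permutation tests; depletion
power on 100 simulated 29-taxon datasets; CCA type-I error on 200 null
datasets at 399 permutations; and pipeline determinism plus full-null
cleanliness over 50 seeds at the default 29-taxon, 559-orthogroup
profile.  These sizes keep the whole suite to a few minutes while giving
the Monte-Carlo assertions comfortable margins.

# Known limitations

* The enrichment scan's permutation null treats taxa as exchangeable
  within clade groups; phylogenetic pseudo-replication within clades is
  addressed only by the PGLS stage.
* Dollo parsimony undercounts losses when several occur on nested
  branches (a parsimony lower bound; the generator-vs-reconstruction
  test quantifies the bias at realistic loss rates).
* PGLS assumes Brownian errors on a known tree; no
  Ornstein–Uhlenbeck or measurement-error extensions are provided.
* CCA significance is global (no per-axis tests, no partial CCA).
* The λ search is restricted to [0, 1] by design.
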