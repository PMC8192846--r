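---
title: "Prioritizing functionally active members of a large gene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing functionally active members of a large gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famrank)
```

## The problem

Large gene families — the motivating example is the Arabidopsis F-box
(*FBX*) superfamily, with roughly 700 members encoding the
substrate-recognition subunits of SCF ubiquitin E3 ligases — are typically
studied very unevenly.  A few dozen members have a characterized substrate
and a rich literature; a comparable number have mutant phenotypes; many
hundreds have nothing beyond transcriptome-wide expression reports or no
report at all.  Yet a large fraction of the silent members is probably not
functional at all: gene families of this size carry many recently
duplicated copies drifting under relaxed selection.  famrank ranks the
uncharacterized members by their likely functional activity, so that
experimental effort can be spent on the most promising candidates.

The package combines three layers:

1. **Evidence tiers.**  Every gene is placed in Group I (substrate known),
   II (mutant phenotype known), III (differential expression reported) or
   IV (never reported), with strict precedence I > II > III > IV
   (`assign_group()`).  Groups I and IV anchor the supervised analysis as
   the labeled active and inactive classes.
2. **Consensus clustering.**  Monti-style resampling consensus k-means
   over a standardized feature matrix (`consensus_cluster()`): each
   resample draws 80% of genes, clusters them with Euclidean k-means, and
   the consensus matrix records how often each pair co-clusters among the
   resamples where it was co-sampled.  Average-linkage clustering of
   `1 - consensus` gives the final assignment; CDF/delta-area curves
   (`choose_k()`) advise on the number of clusters, and PCA summarizes the
   separation.
3. **Two-tier resampling-consensus classification.**  Known-active genes
   (label 1) and a 3:1 downsample of never-studied genes (label 0) form a
   labeled pool.  Each *round* refits a classifier on 1,000 stratified
   2:1 train/validate resamples of the pool and scores every test gene
   each time; a gene is called within a round only if one class wins at
   least 950 of the 1,000 votes, and called overall only if at least 9 of
   10 rounds agree.  Genes meeting neither bar remain unclassified, which
   is the honest outcome for borderline members.

## The feature table

Each gene carries 27 characteristics (`feature_schema()`): literature and
transcript-evidence counts (publications, ESTs, cDNAs), gene-structure
counts (introns, exons), five regional T-DNA insertion counts and their
total, molecular-evolution measures (Ka/Ks, Ks, a neutral-evolution
flag), four expression summaries computed from an expression matrix
(mean, median, maximum and coefficient of variation across samples), and
nine C-terminal-domain composition indicators.  The `reduced10` subset —
publications, ESTs, cDNAs, introns, the four expression summaries, Ks and
Ka/Ks — drops the features that discriminate activity poorly and is the
default for clustering and classification.

Three conventions matter:

* **Standardization.**  Counts, ratios and expression levels live on
  incommensurable scales, so every matrix entering k-means, PCA or a
  classifier is z-scored per feature (`standardize_features()`).  The
  source analyses this package reimplements do not state their scaling;
  z-scoring is the choice that makes Euclidean distances meaningful, and
  it is exposed as an explicit step so alternatives can be substituted.
* **Missing expression.**  A gene whose expression summaries cannot be
  computed (no observed samples, or CV undefined at mean zero) is flagged
  incomplete and removed before analysis (`drop_incomplete()`), rather
  than imputed; the CV at mean zero is reported missing, never infinite.
* **Schema tolerance.**  Extra columns in a feature-table TSV pass
  through untouched, so an externally assembled 27-column table with
  additional metadata loads unchanged.

## The synthetic family generator

No real feature table ships with the package; `simulate_family()`
generates families with the statistical structure the analysis assumes,
with known ground truth, so that every stage is testable end to end.

The default configuration (`sim_config()`) is a family of 696 genes: 41
labeled active (Group I), 140 labeled inactive (Group IV) and 515
unknown (Group III), of which 12% are truly active, each gene with 50
expression samples.  Marginal distributions are the package's own
choices, since the study being emulated reports only group-level
summaries: per-sample expression is log-normal with a gene-level random
effect, counts are negative-binomial, Ka/Ks is a scaled logit-normal on
(0, 1.5), Ks log-normal, and the FBXD e-value exponent normal.

A single knob, `separation`, multiplies the active-vs-inactive location
shift of every feature family.  At `separation = 0` the two generative
distributions are identical (so any called set can only be at chance
composition); at the default `separation = 3` the group contrasts match
the published family-level summaries this work targets — mean Ka/Ks near
0.25 for active versus 0.60 for inactive genes (SDs near 0.11 and 0.16),
markedly higher and less variable expression in active genes, higher Ks,
and publication counts near 27 per Group I member versus exactly 0 in
Group IV (never-reported genes have, by definition, no publications; this
one feature is tied to the evidence tier rather than to latent activity,
and is deliberately left in the predictor set — the same circularity is
present in the real analysis, and an exclusion flag in
`standardize_features()`'s feature selection supports sensitivity runs).

Reproducibility is structural: a master seed spawns an independent
sub-stream per feature family (`substream_seed()`), so adding a feature
never perturbs the others, and the underlying noise draws do not depend
on `separation` — which makes group contrasts exactly monotone in it
rather than only on average.

What the generator does **not** emulate: correlations between feature
families beyond those induced by activity (real expression, literature
and evolutionary measures are mutually correlated for many reasons);
phylogenetic structure among genes; T-DNA insertion positions (counts
only); sequence-level anything.  Passing tests on synthetic families
therefore demonstrate that the machinery recovers a planted signal of the
stated shape — not that the feature set suffices for any particular real
family.

## Numerical and procedural choices

* **k-means** is delegated to `stats::kmeans()` (best of `n_restarts`
  seeded starts by the within-cluster sum of squares); degenerate starts
  that would leave a cluster empty are retried from a freshly derived
  seed.  On small problems the attained objective equals the exhaustive
  partition optimum (verified against a brute-force oracle in the tests).
* **Consensus settings** follow the wrapped-tool conventions of the
  analyses this package reimplements: `reps = 1000`, `p_item = 0.8`,
  features never subsampled, Euclidean distance, average linkage for the
  final consolidation.  Inner linkage is irrelevant when the per-resample
  algorithm is k-means and is not exposed.
* **Choice of k** is advisory only: the delta-area statistic flags the
  largest k whose relative gain in consensus-CDF area exceeds a floor
  (default 0.15, chosen to sit between the residual gain observed when a
  crisp cluster is split, about 0.12 in simulations, and the gain from
  resolving genuine structure).  Analyses set k explicitly in the
  configuration.
* **The reference MLP** is a 10/2 two-hidden-layer logistic network
  trained by full-batch Adam on the cross-entropy with a light L2 penalty
  (`1e-4`, which keeps the optimum finite on separable data).
  Convergence is declared when the gradient infinity-norm falls below
  0.01 — the convention of the neural-net tooling this mirrors — with an
  epoch cap of 2,000.  A fit that fails to converge is retried twice from
  fresh seeded initializations and otherwise *abstains*: that resample's
  votes count in neither tally, and abstentions are logged.  Random
  forest (`mtry = 4`) and radial C-classification SVM alternatives
  delegate to randomForest and e1071.
* **Thresholds are inclusive.**  A score of exactly 0.5 is called active;
  950 of 1,000 votes suffices; 9 of 10 rounds suffices.  With the round
  bar above half the rounds, the final active and inactive sets are
  provably disjoint (pigeonhole), and raising either threshold can only
  shrink the called set — both facts are asserted as tests.
* **Splits** are stratified by class (the emulated analysis is silent on
  this; stratification keeps the 2:1 train/validate class ratios within
  one gene of the pool ratio at every resample).  The pool itself is
  fixed once per run; which negatives enter it is a seeded draw.
* **Fisher's exact test** reports the conventional two-sided p (sum of
  hypergeometric probabilities no larger than the observed table's) and
  the conditional-MLE odds ratio, via `stats::fisher.test()`; an
  independent enumeration oracle in the test suite checks all tables with
  total at most 40.  Zero-margin tables return p = 1 with an undefined
  odds ratio.
* **Group comparisons** use the tie-corrected Kruskal–Wallis test with
  Dunn's pairwise z on pooled ranks and Benjamini–Hochberg adjustment
  across the pairs of one feature at a time; whether the emulated
  analysis pooled features is unstated, and per-feature testing is the
  conservative reading.  Verification comparisons between called sets
  first downsample the larger called set (seeded) to the size of the
  smaller, so the rank tests are balanced.
* **Normalized prediction precision** divides validation accuracy by the
  number of *test-set* genes called active or inactive.  It deliberately
  rewards parsimonious callers: for candidate prioritization, a shorter
  list at equal validation accuracy is worth more.  An empty called set
  makes it undefined (flagged, not an error).

## Scale of the shipped experiments

The package's own tests and the acceptance script run the ensemble at a
desk scale chosen to exercise every code path with comfortable margins:
the full 696-gene default family with the 10-feature set, 3 rounds of
100 resamples with thresholds rescaled proportionally (95/100 votes, 3/3
rounds), and consensus clustering at 100 resamples.  These are
configuration values, not different code; the full-scale settings
(10 rounds of 1,000 resamples, thresholds 950/1,000 and 9/10,
`reps = 1000`) are the defaults of `pipeline_config()`.

## Known limitations

* Domain-composition indicators are consumed as inputs; the package does
  not annotate domains, align sequences or compute Ka/Ks.
* The evidence tiers are only as good as the evidence table; the
  publication-count feature is circular with the tier definitions (see
  above) and should be excluded when that circularity is a concern.
* The internal-control convention treats the phenotype-known tier
  (Group II) as positive controls in the enrichment check.  The emulated
  methods text can also be read as using a second labeled-active set for
  this purpose; the Group II reading matches the results as reported and
  is the one implemented.
* Consensus calls depend on the negative downsample through a single
  seeded draw; runs with different master seeds will call slightly
  different borderline genes.  This is inherent to the design, and the
  cross-round bar is what keeps it from dominating.
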