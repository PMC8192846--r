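# famrank

Prioritization of functionally active members of large gene families by
resampling-consensus machine learning.

## The problem

Large gene families — the motivating case is the ~700-member Arabidopsis
F-box (*FBX*) superfamily, whose proteins are the substrate-recognition
subunits of SCF ubiquitin E3 ligases — mix a small, well-characterized
functional core with hundreds of members that have never been studied,
many of which are probably inactive duplicates drifting under relaxed
selection.  famrank ranks the unknown members by likely functional
activity from a per-gene table of genomic, transcriptomic and
evolutionary characteristics, so that functional-genomics effort can be
directed at the strongest candidates.

## What it does

Genes are first tiered by annotation evidence with strict precedence:
Group I (substrate known) > II (mutant phenotype known) > III
(differential expression reported) > IV (never reported).  The analysis
then runs on a standardized feature matrix (27 characteristics, or a
10-feature subset: publication/EST/cDNA counts, intron count, expression
mean/median/max/CV, K_s and K_a/K_s):

* **Consensus clustering** — Monti-style resampled k-means (reps = 1000,
  p_item = 0.8, Euclidean, average-linkage consolidation of the
  consensus matrix), with CDF/delta-area diagnostics for the number of
  clusters and PCA summaries.
* **Two-tier consensus classification** — Groups I and IV anchor the
  labels (active = 1, inactive = 0, negatives downsampled to 3:1); each
  of 10 rounds refits a classifier (a 10/2 two-hidden-layer logistic
  MLP; random forest with mtry = 4 and radial-kernel SVM as
  alternatives) on 1,000 stratified 2:1 train/validate resamples.  A
  gene is called in a round only with >= 950 of 1,000 votes for one
  class, and called overall only when >= 9 of 10 rounds agree:

  rounds_active(g) >= 9  =>  active;  rounds_inactive(g) >= 9  =>  inactive;
  otherwise unclassified.

* **Evaluation** — validation accuracy, class-conditional false
  negative/positive rates, normalized prediction precision
  (accuracy / number of test-set calls), internal-control (Group II)
  enrichment by Fisher's exact test, cross-method overlap counts, and
  verification of the called sets against expression and evolutionary
  features (Kruskal–Wallis + Dunn + Benjamini–Hochberg, Welch t).

A seeded synthetic-family generator with known ground truth
(`simulate_family()`) makes the whole pipeline testable without any
external data; its defaults reproduce the family-level contrasts the
method assumes (active genes: K_a/K_s near 0.25 vs 0.60, higher K_s,
higher and less variable expression, more literature evidence).

## Worked example

```r
library(famrank)

cfg <- pipeline_config(
  out_dir   = "run1",
  simulate  = sim_config(separation = 3),   # 696 genes, 41 I / 140 IV / 515 unknown
  feature_set = "reduced10",
  cluster_k = 3, cluster_reps = 100,
  n_rounds = 3, n_resamples = 100,          # desk-scale ensemble
  vote_threshold = 95, min_rounds = 3,
  master_seed = 1
)
run_pipeline(cfg)
write_report("run1")
cat(readLines("run1/report.txt"), sep = "\n")
```

which prints (abridged):

```
Group summary (publications per gene):
  group n_genes mean_publications sd_publications
1     I      41         26.365854        36.09415
3   III     515          5.398058        18.20096
4    IV     140          0.000000         0.00000

PCA: PC1 38.4%, PC2 15.5% of variance

Consensus calls: 66 active, 446 inactive, 3 unclassified

Evaluation metrics:
  validation_accuracy: 0.996182
  n_called_active: 66
  frac_truly_active_called_active: 1
```

Reading this: the well-studied tier averages ~26 publications per gene
while the never-studied tier has none; of the 515 unknown genes the
two-tier caller commits to 66 active and 446 inactive candidates and
leaves 3 unclassified; 99.6% of labeled validation genes are predicted
correctly across resamples, and every truly active unknown gene that
received a call was called active (the ground truth is known here
because the family is simulated).  Per-stage artifacts (group tables,
consensus matrix, cluster composition, PCA, per-gene votes, metrics)
are TSV/JSON files under `run1/`, indexed with checksums in
`run1/manifest.json`; re-running with the same seed reproduces them
bit for bit.

A thin command-line wrapper with `simulate`, `run-all` and `report`
subcommands is installed at `inst/scripts/famrank-cli.R`.

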