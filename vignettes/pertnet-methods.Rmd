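---
title: "Methods: perturbation-signature screening and network pharmacology with pertnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbation-signature screening and network pharmacology with pertnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pertnet)
```

# The data model

The substrate of every analysis is a compound × (gene, mode) score matrix
of CMap-style connectivity values: for each compound and gene, up to two
scores measuring the similarity of the compound's expression signature to
the gene's knockdown (`KD`) and overexpression (`OE`) reference
signatures. pertnet makes three normalising commitments at ingest:

* **One canonical scale.** Scores live in `[-1, 1]`. Sources that print
  0–100 scores are read with `scale = "percent"` and divided by 100.
  Mixing the two conventions silently is the classic unit bug in this
  kind of pipeline, so the scale is an explicit, mandatory declaration of
  the reader, never inferred.
* **Missing means unmeasured.** An absent (compound, gene, mode) entry is
  `NA`, never 0. Only the ML feature matrix imputes (to 0, with a
  missingness flag), because classifiers need complete rows; everywhere
  else "no measurement" propagates.
* **Exact symbol matching.** Gene symbols are uppercased and compared by
  string equality. No alias resolution is attempted: the upstream
  resources this emulates disagree on aliases, and silent alias joins are
  harder to audit than an explicit pre-mapping step done by the user.

Scores are thresholded **signed**: a large negative score never qualifies
as activity. The no-activity band `[-0.2, 0.2]` only makes sense for
signed scores, and every printed qualifying score in the source
conventions is positive. An `absolute = TRUE` flag exists for users whose
score convention is symmetric.

# Modulator calling

A compound is called a modulator of the target gene (default `PLAUR`)
when its target score strictly exceeds the calling threshold (default
0.9) in at least one mode; a score exactly at the threshold does not
qualify, matching "exceeding 0.9" wording. KD-mode calls are read as
functional *suppressors* and OE-mode calls as *stimulators*. The source
conventions are internally inconsistent about this orientation (the same
compound family appears with KD-mode scores under a stimulation heading),
so the mapping is a single configuration switch (`kd_means`) rather than
a hard-wired rule. When both modes qualify, the higher score wins and KD
wins an exact tie — an arbitrary but deterministic policy.

Sham compounds must have **every measured** target score inside the
closed band (default `[-0.2, 0.2]`; "between −0.2 and 0.2" is read
inclusively — the boundary choice only matters on a measure-zero set for
continuous scores). A compound with no target measurement at all is
neither modulator nor sham: it is unobserved, not inactive.

The calling threshold (0.9) and the band are independent knobs; the band
must sit strictly inside `(-threshold, threshold)` so that the modulator
and sham sets are provably disjoint for any matrix.

# Networks

Both network layers are bipartite compound–target graphs. The
transcriptional layer connects each modulator to every cancer driver gene
in its supra-threshold co-expression profile, computed with the *same*
strict rule as modulator calling (`any-mode score > 0.9`), so the target
gene itself appears in every profile. The translational layer connects
modulators to driver proteins through externally supplied bioactivity
pairs. Three small semantic decisions worth stating:

* Degrees are unweighted edge counts; qualifying scores are stored as
  edge weights but never enter degree computations.
* All rankings (hubs, degree tables) order by descending degree with
  lexicographic tie-break, making every "top-k" reproducible without a
  seed.
* "More than 90 compounds" (core membership) and "PPI score > 0.7" are
  strict inequalities, following the printed wording; both cutoffs are
  parameters.

Network exports (SIF, GraphML via igraph, edge TSV) carry node class and
driver role annotations so the graphs load directly into standard
viewers; SIF is lossy by design (no weights), the other two round-trip.

# Pathway repetition rate

For modulator driver-profiles $D_1,\dots,D_n$ and a pathway gene set $P$,
the numerator counts compounds with $D_i \cap P \neq \emptyset$ and the
rate divides by a **fixed** denominator — the full modulator count — even
for compounds with empty profiles. Intersection-nonempty is deliberately
the weakest membership reading: it is the only rule consistent with
near-1 published rates over 254 modulators. Display rounding is half-up
to two decimals (`0.975 -> 0.98`); JSON artifacts keep the raw ratio. The
report also counts pathways touched by at least one profile (the
"10 out of 21"-style summary statistic).

# The pair rule

The rule generalises a two-exemplar observation (uPAR + MYC, uPAR +
SMAD4) to driver roles:

* target KD-qualified **and** an oncogene marker KD-qualified ⇒
  `anti_cancer`;
* target OE-qualified **and** a tumor-suppressor marker KD-qualified ⇒
  `carcinogenic`;
* otherwise `indeterminate`. If both branches fire, or the target
  qualifies in both modes, the verdict is `indeterminate` with an
  explicit conflict flag — the source material never specifies this case,
  and guessing a direction would be invisible to the user.

Bifunctional markers match neither branch unless the user relabels them:
the rule is defined in role terms and a gene that is both roles at once
gives no direction. The pair threshold defaults to 0.85, deliberately
below the 0.9 calling threshold, because the published worked examples
treat a 0.8831 target score as active pair evidence while the calling
step used 0.9; keeping the two thresholds independent reproduces both
behaviours without special-casing any compound. Verdicts store the raw
mode+score evidence verbatim, since whether KD/OE denote signature
connectivity or the compound's own effect direction is a convention the
data source leaves open.

# The ML screening platform

Features are per-gene mode-reduced scores (`max` over measured modes, or
a single mode); the label is modulator vs sham. Feature relevance is the
absolute point-biserial correlation with the binary label — a
deterministic, documented member of the "relevance-based/CFS" family. We
do not add CFS redundancy terms: no formula or redundancy policy is
published for this step, and the downstream contract (a reproducible
ranked subset) does not need them. Ties break lexicographically;
zero-variance features score 0.

The published protocol combines a 70/30 split with tenfold
cross-validation without saying which produced the reported metrics, so
pertnet computes **both**: stratified 10-fold CV on the 70% training
portion (metrics on pooled out-of-fold predictions) and a holdout
confirmation on the 30%, reported side by side. AUC is the rank
(Mann–Whitney) statistic with mid-ranked ties, identical to the
trapezoidal ROC area; sensitivity, precision and accuracy use the 0.5
score cut with modulator as the positive class. The seven classifiers run
with fixed library defaults (nnet: size 5, decay 0.1; random forest: 200
trees; xgboost: 50 rounds, exact tree method — the exact split
enumeration places cut-points mid-gap between classes, which keeps
behaviour stable on small strata; kNN: k = 5). No hyperparameter search
is performed: the object of study is the protocol, not tuned performance.
Every random choice (split, fold assignment, learner seeds, permutations)
derives deterministically from one integer seed.

A label-permutation control (`permutation_null_auc()`) re-runs the whole
CV protocol on permuted labels; its mean AUC sitting near 0.5 is the
standard guard against information leakage through the protocol itself.

# The synthetic generator

`generate_dataset()` emulates the study conditions of a CMap-scale
screen: 2429 compounds × 3848 genes by default, a driver:non-driver
ratio of 1:12 (`driver_fraction = 1/13`), 143 + 111 planted
suppressors/stimulators with triggering scores drawn uniformly from
(0.905, 0.995), 185 planted shams inside the band, a 0.3 mean shift on 30
informative driver genes in modulators (the ML signal), 13 co-expressed
driver genes planted supra-threshold in modulator profiles (the network
core signal), 12 hub proteins in the bioactivity table, and 10 of 21
pathways seeded with planted drivers. Background scores are Gaussian with
`noise_sd = 0.15` — wide enough that sham-band membership is non-trivial,
narrow enough that a 0.9 threshold is a real outlier call — and are
clipped to stay strictly below the calling threshold, so the
supra-threshold structure of the emitted matrix is *exactly* the planted
structure and label recovery can be asserted without tolerance. The
emulated study design fixes modulator and sham counts but says nothing
about the remaining compounds, so the generator takes an explicit sham
count (`n_shams`) and labels the remainder `other`,
forcing each `other` compound outside the band in one mode but below
threshold, which keeps the three classes a clean partition.

What the generator does **not** emulate: real CMap correlation structure
between genes (beyond the planted mean shifts), compound dose/cell-line
replication, heavy-tailed score distributions, or gene-alias noise.
Passing the planted-recovery tests therefore demonstrates the
correctness of the thresholding, network, counting and CV machinery — not
that the platform's headline performance numbers transfer to real
connectivity data, which are also database-version dependent.

Determinism: one master integer seed, fixed per-component offsets
(`derive_seed()`), byte-identical bundles for identical configs.

# Packaged reference tables

`load_reference_tables()` ships small curated tables for the uPAR case
study: the per-pathway modulator counts behind the repetition rates, the
nine cell-assay-confirmed modulators with their affected driver genes,
the four-hallmark map and the five worked pair-rule rows. Two packaged
artifacts are synthetic stand-ins and say so in their file names: the
demonstration matrix (`demo_matrix_synthetic.tsv`, supra-threshold scores
invented on the curated gene lists) and the pathway membership GMT
(`pathway_memberships_synthetic.gmt`, memberships chosen to be consistent
with the reported top-10 driver counts). They exercise profile extraction
and intersection counting; they are not transcriptions of any database.

# Problem sizes and numerical choices

The test suite and acceptance script run the screening recovery at
400 × 3848 (the full gene universe, reduced compound count) and the ML
recovery at 439 × 2834 (439 labeled compounds, 218 driver features of
which 30 informative) — sizes chosen so the planted-structure claims are
tested at realistic dimensionality while a full run stays in the tens of
seconds. Oracle-equivalence tests use 100 random bipartite graphs of up
to ~26 nodes, where brute-force recounting is itself trivially
verifiable. Degenerate inputs are defined, not errors, wherever a
sensible value exists: empty networks summarise to zeros, empty profiles
give rate 0, `k` larger than the feature count returns everything with a
warning; genuinely contradictory inputs (duplicate keys, overlapping
classes, out-of-range scores, single-class folds) raise classed errors.

# Known limitations

* One target gene per screen; no polypharmacology calling.
* No enrichment p-values in the pathway module — the statistic of record
  is the repetition rate, and adding hypergeometric tests would change
  the question being asked.
* The pair rule covers only role-typed single-marker evidence; dose
  dependence (biphasic effects) is out of scope.
* Classifier hyperparameters are frozen defaults; reported metrics
  benchmark the protocol, not achievable performance.
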