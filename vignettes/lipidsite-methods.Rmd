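---
title: "Group-based prediction of lipid-modification sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-based prediction of lipid-modification sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsite)
```

## The problem

Four lipid modifications dominate the post-translational lipidation of
eukaryotic proteins: S-palmitoylation (a 16-carbon palmitate on cysteine),
N-myristoylation (a 14-carbon myristate on an N-terminal glycine, written
by N-myristoyl transferase at an MGXXXS/T signature), S-farnesylation and
S-geranylgeranylation (15- and 20-carbon prenyl groups on C-terminal
cysteines in CAAX or, for Rab-type substrates, CC/CXC contexts).  Given a
protein sequence, the package scores every candidate residue — each
cysteine for the cysteine-directed types, each glycine for myristoylation
— and reports the ones likely to be modified.  Because lipid types
co-regulate membrane targeting (myristoylation plus palmitoylation,
prenylation plus palmitoylation), the package also ships the statistics
used to quantify such dual-lipid co-regulation over an annotated sequence
library.

## The scoring model

A candidate site is represented by its peptide window `PSP(m, n)`: the
central residue with `m` upstream and `n` downstream flanking residues,
padded with `*` beyond the protein termini.  Two windows are compared
position by position; a position is a *conserved substitution* when its
residue pair scores positively in BLOSUM62.  The pairwise similarity

\[
S(A, B) = \frac{\#\{i : \mathrm{Score}(a_i, b_i) > 0\}}{m + n + 1},
\qquad D(A, B) = 1 / S(A, B)
\]

ranges over [0, 1], with `D = Inf` when `S = 0`.  A query window `q` is
scored against a *group* `G` of known modified peptides as the mean
position-weighted substitution score

\[
\mathrm{score}(q, G) = \frac{1}{|G|} \sum_{t \in G} \sum_{i} w_i \,
M(q_i, t_i),
\]

where `w` is a per-position weight vector (all ones before training) and
`M` is BLOSUM62 plus trained symmetric deltas.  Any pair involving the
padding symbol scores 0, so terminal truncation neither rewards nor
penalizes a site; unknown residues map to `X` and use BLOSUM62's X row.
Averaging over the group (rather than summing) makes scores comparable
between groups of different sizes; it rescales cutoffs but not decisions.

## Grouping

One modification can be written by enzymes with different specificities,
so positives are split before scoring:

* **Myristoylation** — `consensus` (glycine at position 2 of an M-G start
  with S/T at position 6) vs `nonconsensus` (every other annotated
  glycine, including internal ones).
* **Farnesylation** — `consensus` (cysteine fourth from the C terminus,
  the C of a CAAX box) vs `nonconsensus`.  The "A = aliphatic" constraint
  is exposed as an optional filter (`aliphatic_filter`), off by default:
  the positional rule routes borderline sites to the consensus model
  instead of silently dropping them.
* **Geranylgeranylation** — `consensus_caax`, `consensus_cc_cxc`
  (cysteine in a terminal CC or CXC), `nonconsensus`.
* **Palmitoylation** — no consensus motif is known, so positives are
  clustered by k-means (default `k = 3`) under the distance `D`.
  Centroids are always cluster members and are updated to the member with
  the highest average similarity to its cluster; assignment ties break to
  the lowest cluster id and centroid ties to the lowest peptide index, so
  clustering is deterministic given the seed.  The best of
  `kmeans_restarts` (default 10) seeded initializations by mean
  intra-cluster similarity is kept.

Groups that end up with fewer than `min_group` (default 3) positives are
merged into the non-consensus group (or the largest cluster) with a
warning — a group of one or two peptides cannot support leave-one-out
training.

## Training

`lipid_train()` runs four stages in order; all randomness derives from one
master seed, so a fit is reproducible bit for bit.

1. **Grouping**, as above, on the full (30, 30) windows.
2. **Motif length selection (MLS)** picks the effective window `(m, n)`
   from a grid (default {1, 3, 5, 7, 10, 15, 20, 25, 30} squared) by the
   pooled leave-one-out sensitivity at 90% specificity, with unit weights
   and the unmutated matrix; ties prefer the smaller total window, then
   the smaller `m`.  The pooled objective is used here because the window
   is a model-level property; weight training below is per group, because
   each group encodes a distinct positional preference.
3. **Weight training (WT)** searches per-position deltas `dw` in
   [-1, 1] (weights `pmax(1 + dw, 0)`), maximizing the group's
   leave-one-out sensitivity at 90% specificity: each group member is
   scored against its group with itself removed — an honest LOO without
   retraining — and every negative against the full group.
4. **Matrix mutation (MaM)** then searches symmetric deltas over the 210
   unordered standard-residue pairs in [-4, 4] with the same objective
   and the trained weights.  The X and padding rows are never mutated.

The search boxes keep scores in a numerically tame range; both are
config-exposed.  Because the swarm optimizer always evaluates the
zero-delta baseline first and reports the best solution ever evaluated,
each stage's objective is non-decreasing: after-WT >= baseline and
after-MaM >= after-WT hold by construction and are asserted in the tests.
The per-group objective trace is stored in the fitted model.

Finally, per-group score cutoffs are calibrated on the negatives at
specificities 0.95 / 0.90 / 0.85 (high / medium / low stringency).  The
three-tier stringency idiom is standard for this family of predictors but
does not fix the levels; the defaults here bracket the training
objective's 90% specificity and are config-exposed.  A cutoff is the minimal
observed score reaching the level, so `cutoff(high) >= cutoff(medium) >=
cutoff(low)` and prediction sets nest monotonically with stringency.  At
prediction time a candidate is scored against every group of its type and
reported when `score - cutoff(group, stringency) >= 0` for at least one
group; the best group relative to its cutoff is reported.

## The optimizer

WT and MaM use particle swarm optimization with an *aging leader and
challengers*.  A standard inertia-weight swarm (defaults: 20 particles,
inertia 0.4, c1 = c2 = 2, velocities clamped to half the box per
dimension, positions clamped to the box) follows personal bests and a
leader.  The leader ages: each generation its leading power is assessed —
+2 lifespan if the best-ever solution improved, +1 if the aggregate of
personal bests improved, unchanged if only the leader's own fitness
improved, -1 otherwise (initial lifespan 60).  When age exceeds lifespan,
a challenger is drawn by redrawing each leader coordinate with probability
1/d uniformly in the box; it leads for 2 trial generations and is accepted
only if it shows leading power, otherwise the old leader returns.  Aging
prevents a stale leader from trapping the swarm in a local optimum while
keeping plain PSO's convergence speed; plain global-best PSO is available
(`aging = FALSE`) and serves as the reference baseline in the tests, where
the aging variant's median final fitness on a rugged multimodal landscape
(Rastrigin, d = 5) is no worse over 20 seeds.

Stopping: `max_iter` generations (default 100) or 50 generations without
best-ever improvement, whichever comes first; both knobs are recorded in
the model file.  The Sn-at-90%-Sp objective is piecewise constant, which
PSO handles naturally; ties are resolved by the best-ever bookkeeping
(first particle at the optimum wins, and the zero-delta baseline is
particle 1).

## Evaluation

`loo_scores()` scores every positive with itself excluded from its own
group and every negative against the full groups; a site's score is its
maximum over groups.  `kfold_scores()` (k = 4, 6, 8, 10) splits both
classes into near-equal seeded folds; the default fast mode keeps the
trained weights and matrix and rebuilds only the group peptide sets from
the training folds, while `refit = "full"` re-runs WT/MaM per fold (the
mode is recorded on the result).  `roc_auc()` sweeps all distinct
thresholds and computes the AUC as the normalized Mann-Whitney statistic
with ties counting one half — the tests verify the equality against an
exhaustive pairwise count, and that the trapezoid under the swept curve
equals the rank formula.  `pr_curve()`, `classification_metrics()` (Sn,
Sp, Ac, MCC, Pr with the usual zero-denominator guards) and
`evaluation_report()` complete the panel.

## Co-regulation statistics

Over an annotated library (`build_library()` merges experimental sites
with high-stringency predictions, deduplicating on protein, position and
type):

* **Co-occurrence** — protein-level 2x2 table (has type A x has type B)
  over all library proteins; Pearson chi-square with df = 1 and no
  continuity correction (a flag enables Yates).  Degenerate margins
  report p = 1 with a flag rather than an error.
* **Proximity** — for every candidate residue of A's amino acid, whether
  at least one B site lies within the flanking window ((5,5), (10,10) or
  (15,15)), the residue's own position excluded; A-modified vs unmodified
  residues are compared by chi-square.
* **In-situ crosstalk** — among all cysteines of annotated proteins
  (the conditional universe: the library's own proteins, not the
  proteome), an upper-tail hypergeometric test of whether a prenylation
  type concentrates on cysteines carrying another cysteine-directed type,
  with enrichment ratio (k/n)/(K/N).

Significance is reported as `-ln(p)` — the only transform consistent with
the conventional 0.05 / 2.99 and 0.01 / 4.61 threshold pairings — capped
at `-ln(.Machine$double.xmin)` when p underflows.  Pairs where a type has
no sites are reported as not applicable rather than p = 1.

## Synthetic data

`synth_generate()` plants one positive per protein over a uniform
background of the 20 standard residues (lengths 80-160 by default):
myristoylation proteins start M-G with a 5-residue downstream signal
(position 6 = S), farnesylation proteins end in CAAX with a 5-residue
polybasic-like upstream signal, geranylgeranylation alternates CAAX and
CC/CXC termini, and palmitoylation embeds one of three mutually
non-conserved 7-residue family consensus patterns around an internal
cysteine.  At signal strength `s` each signal position carries its
consensus residue with probability `s` (default 0.8, a realistic
mid-strength motif); every protein retains at least two decoy candidate
residues.  `synth_null_library()` assigns sites of all four types
independently and uniformly over candidate residues — the exact null of
all three crosstalk tests; its defaults (60 proteins, lengths 100-150,
site rate 0.15 per candidate) were chosen so that the expected proximity
2x2 cell counts exceed the usual chi-square validity floor of about 5.

What the generator does *not* emulate: real amino-acid composition
(a uniform background is used; real sequence libraries are biased),
homology between substrates, multiple sites per protein for the planted
type, and the long-tailed class imbalance of curated site data.  Passing
the recovery tests therefore shows the machinery is correct and the
pipeline can learn planted positional signal at realistic strength — not
that the trained toy models transfer to real proteomes, which requires
the curated training data the original study collected.

## Problem sizes and numerical choices

The test suite and the acceptance script train on 60 positives and 300
negatives per type with a 20-particle, 100-generation swarm — sizes chosen
so a full four-type run completes in well under a minute per type while
leaving the leave-one-out AUC comfortably above 0.9 (observed 0.96-0.998
at seed 1).  Degenerate inputs are handled explicitly: windows at protein
termini are padded (never truncated), a positive whose removal empties its
group falls back to the remaining groups (sentinel -Inf if none), k > n
clustering and single-class ROC inputs are errors, unreachable specificity
levels place the cutoff above the maximum score with a warning, and MCC /
precision use the conventional zero guards.

## Known limitations

* The closed functional form of the similarity used by the original
  system is defined here as the conserved-position fraction normalized by
  the full window length; normalizing by non-padding positions is a
  defensible alternative that would raise terminal sites' similarities.
* WT/MaM optimize each group independently; a pooled objective across
  groups is conceivable but couples groups that recognize different
  motifs, so it was not adopted.
* The k-fold fast mode shares trained weights across folds, which leaks a
  small amount of information relative to a full per-fold refit; both
  modes are provided and flagged on the output.
* Scores are comparable across groups through their calibrated cutoffs;
  raw cross-group score maxima are used for threshold-free evaluation,
  which is innocuous for per-type models trained at one window length but
  would need calibration if groups differed grossly in size.
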