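---
title: "Evaluating virtual-screening benchmarks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating virtual-screening benchmarks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procbench)
library(dplyr)
```

## The problem

Structure-based virtual screening ranks a chemical library by a docking
score and hopes the true binders surface early. Benchmark sets such as
DEKOIS 2.0 — 40 confirmed bioactives plus 1200 property-matched decoys per
target — let us measure how well a given docking setup achieves that. But
the measurement itself is fragile: before any docking happens, the protein
and the ligands pass through a *preparation* pipeline (protonation-state
assignment, tautomer selection, force-field minimization), and different
commercial pipelines make different chemical choices for the same input.
procbench quantifies how much those choices move the screening metric,
attributes the movement to concrete molecular causes, and evaluates the
standard countermeasure against a second confounder, the size bias of
additive scoring functions.

## The enrichment metric

The package's central statistic is the pROC-AUC, the area under the ROC
curve after log-transforming the false-positive axis. Writing $f_i$ for
the fraction of decoys ranked above bioactive $i$,

$$\mathrm{pROC\text{-}AUC} \;=\; \frac{1}{N_a}\sum_{i=1}^{N_a}
  \log_{10}\!\frac{1}{f_i}, \qquad
  f_i \;\ge\; \frac{1}{N_d},$$

so a bioactive recovered before 99% of decoys contributes 2, one
recovered before 90% contributes 1, and one at the bottom contributes
about 0. The floor $1/N_d$ caps the contribution of a bioactive that
beats every decoy at $\log_{10} N_d$ (≈ 3.079 for 1200 decoys), making
the statistic finite and the perfect score attainable. Two anchors follow
analytically and are verified by the test suite:

* random scoring has expectation $\log_{10} e \approx 0.434$ — the
  package reproduces 0.433 ± 0.01 over 1000 replicates of a 40/1200 set;
* perfect separation gives exactly $\log_{10} N_d$.

Three ranking conventions needed fixing because upstream tools are silent
about them. Exact score ties between a bioactive and decoys count half of
the tied decoys into $f_i$ (average-rank convention, unbiased in
expectation); the strict global rank permutation breaks ties by molecule
id so every run is reproducible; and molecules whose docking failed are
kept, ranked strictly worst — a benchmark molecule may not vanish from
the denominator, which would silently flatter the result. Whether the
original workflow floored $f_i$ or used some other regularization is not
documented anywhere we could find; the floor is the only choice we tested
that reproduces the 0.434 random anchor exactly, and it is configurable.

## Comparing preparation schemes

For one target and program, the preparation delta is
$\Delta = \mathrm{AUC}(\text{scheme}_1) - \mathrm{AUC}(\text{scheme}_2)$.
Docking heuristics (GOLD's genetic algorithm in particular) scatter by a
few hundredths of pROC-AUC between runs, so deltas within a safety margin
of ±0.05 are classified non-significant; the boundary is inclusive, and
the comparison is floating-point-safe (a printed pair 0.75/0.80 must land
*on* the boundary, not across it). `compare_preps()` applies this per
target and emits the census of targets favoring each scheme.
`published_prep_comparison()` ships the 18-target survey table this
methodology was built around; classifying its GOLD column yields 7/7/4
(favoring MOE / favoring Maestro / non-significant) and its Glide column
9/5/4, matching the published counts. One Glide row (Thrombin, +0.07)
counts as significant under the numeric rule although the original table
leaves it unmarked; we follow the rule.

The attribution experiments all reduce to controlled perturbations of a
score table:

* **Match/mismatch grid** (`match_mismatch_grid()`): cross target,
  bioactive-set and decoy-set preparation over both schemes (8 cells) and
  report each factor's marginal mean delta. Marginals are means over the
  four toggle pairs, and a test verifies the equivalent direct-toggling
  computation gives identical numbers.
* **Protomer shuffling** (`shuffle_protomers()`): replace only the scores
  of molecules whose protonation differs between schemes with the other
  scheme's scores, re-rank, and compare the delta to the full
  between-scheme delta. Shuffling back restores the original area
  exactly.
* **Deletion** (`delete_and_rescore()`): remove the differing molecules
  entirely; $N_a$, $N_d$ and the floor update, and the result equals a
  fresh computation on the reduced table (construction-path
  independence).
* **Rank/score shifts** (`rank_shift_analysis()`): per-molecule global
  rank and score deltas, preference fractions (ties split 0.5/0.5, since
  published percentages never mention ties), quartile summaries
  (linear-interpolation quantiles, R's default type 7 — stated because
  quartile conventions differ across software), and squared Pearson
  correlations. `flag_rank_outliers()` applies the |Δrank| > 500 cutoff
  used for decoy outliers and annotates each hit with its structural
  cause, including "high flexibility" for rotor counts above 8.
* **Outlier isolation** (`isolate_outlier_subset()`): the published
  analysis picked divergent bioactives visually ("red dots"). Our
  operationalization fits the slope-1 line (intercept = mean paired
  difference), iteratively removes the largest orthogonal residual $k$
  times, and reports the core $R^2$ plus the outliers' divergence–
  property correlations. $k$ is the user's choice, exactly as the visual
  selection was; residual ties break by id order.

## Heavy-atom score normalization

Empirical scoring functions are additive over contacts, so heavier
molecules collect higher scores regardless of binding quality. The
standard correction divides the score by $N^{1/2}$ or $N^{2/3}$ ($N$ =
heavy atoms). `normalize_table()` applies either to the *whole* ranked
set — normalizing a subset is not meaningful and is not offered — and
`normalization_report()` pairs the before/after areas with
$\Delta_N = \mathrm{AUC}_\text{norm} - \mathrm{AUC}_\text{orig}$ and the
bioactive-set mean $N$. The shipped usage guideline encodes the survey
evidence: $N^{1/2}$ is worth trying at mean $N \le 30$ and risky above;
$N^{2/3}$ helps below 28, is risky from 29, and means inside the (28, 29)
gap get a neutral flag.

Two guard rails are our own. Dividing a score column that mixes signs
reorders molecules ambiguously (positive scores shrink toward zero,
negative ones grow toward zero), so `normalize_table()` refuses
mixed-sign columns unless forced — fitness functions are positive,
docking energies negative, and a mixture indicates an upstream problem.
And heavy-atom counts may come from structures or from a table column,
but a conflict between the two is an error, never a silent preference.

## The molecular audit

Attribution needs structure-level evidence, not just labels.
`read_paired_sdf()` pairs the two preparations' SD files by title (ids
present in only one file are reported, never dropped) and
`audit_prep_pairs()` runs four detectors per pair:

* **Protonation** — heavy-atom skeletons must match including bond
  orders (element-colored VF2 isomorphism via igraph); the pair differs
  when total formal charge or any mapped atom's (charge,
  attached-hydrogen count) differs. Hydrogen counts use the explicit
  polar hydrogens that preparation pipelines write.
* **Tautomer** — same formula and total charge, isomorphic skeleton, but
  *no* mapping preserves bond orders. A pure protomer pair can never be
  reported as a tautomer pair: if an order-preserving mapping exists the
  difference is protonation by definition.
* **Ring conformation** — for every non-aromatic ring of size 5–7, the
  intra-ring torsion profile is compared under the best graph mapping;
  the pair differs when some torsion deviates by more than 30° (circular
  arithmetic). The threshold is configurable because published
  ring-difference calls were qualitative; 30° cleanly separates a ring
  flip or pucker change from vibrational noise while ignoring exocyclic
  rotations, which are deliberately out of scope.
* **Symmetry-aware RMSD** — the minimum heavy-atom RMSD over all
  element-preserving graph isomorphisms, optionally with Kabsch
  superposition per mapping (both superimposed and in-place modes are
  exposed because the reference implementation's behavior is
  undocumented). Hydrogens are excluded: schemes differ in which
  hydrogens they write, and including them would dominate the deviation.
  Automorphism enumeration is capped (default 10,000); above the cap a
  greedy within-element-class assignment after identity superposition is
  used and the result is marked approximate — an upper bound, adequate
  for the highly symmetric molecules that trigger it.

Rotatable bonds are counted by a fixed, documented rule — acyclic
single-order bonds between non-terminal heavy atoms, excluding amide C–N
— because vendor definitions disagree and the flexibility analyses must
be reproducible from the definition alone.

## The synthetic benchmark generator

No public deposit contains the dockings this methodology was developed
on, and re-docking requires commercial software. The generator therefore
emulates the *statistical shape* of such a benchmark so every pipeline
stage is testable end to end. Scores follow the additive model

$$s = b_0 + b_N \cdot N + a\,[\text{bioactive}] + \varepsilon,$$

with the second preparation's score derived from the first by small
scheme noise (every molecule), an extra zero-mean shift for molecules
planted as protomer/tautomer/ring-different, and a flexibility-coupled
penalty $c \cdot n_\mathrm{rot} \cdot |\varepsilon'|$ for a small subset
of highly flexible bioactives — the mechanism that makes one scheme
systematically better, mirroring the finding that bioactive preparation,
not decoy preparation, drives the performance gap.

Defaults are study conditions, fixed once from the published anchors and
not revisited: 40 bioactives / 1200 decoys; heavy-atom counts
$\mathcal{N}(27.6, 4.5^2)$ for both roles (decoys are property-matched);
$b_0 = 35$, $b_N = 1.5$, noise sd 8, which place decoy scores near mean
77 / sd 10.5, the magnitudes reported for a real ChemPLP screen;
bioactive offset $a = 10$, giving baseline pROC-AUCs of roughly 0.65–1.2
across seeds, inside the 0.3–2.0 band real targets span; protomer
difference fractions 2/40 (bioactives) and 435/1200 (decoys); one
tautomer-different and two ring-different decoys; flexible subset of 10
with 9–13 rotors; scheme noise sd 2 (paired scores then correlate at
$R^2 \approx 0.9$); difference-shift sd 4. Every molecule's structure is
assembled from a template grammar — alkyl chain with methyl decorations
plus a flavor head: carboxylate/carboxylic acid for protomer pairs,
2-pyridinone/2-hydroxypyridine for tautomer pairs, planar/envelope
cyclopentane for ring pairs — sized so the heavy-atom count equals the
planted value exactly, and the second preparation additionally undergoes
a random rigid motion that no detector may react to. Geometries are
idealized (1.5 Å bonds, planar rings apart from the planted pucker);
they carry the planted differences faithfully but are not force-field
minima, and the scores are *simulated*, not docked — synthetic
benchmarks validate the evaluation machinery, not any docking program.

What passing tests on generator output do and do not show: they prove
the metrics, experiments and detectors implement their definitions
(flags are recovered with zero false positives *by construction*, since
differences are planted structurally); they cannot prove that real
preparation differences are detected with the same fidelity, because
real SD files contain conformational noise, exotic functional groups and
symmetry the templates lack.

One property of the real system reproduces only partially: with the size
slope present, $N^{1/2}$ normalization raises the area in 95% of seeds,
but zeroing the slope does *not* make normalization harmless — the
median change is −0.08, because dividing a score with a large constant
component ($b_0 = 35$) by $\sqrt{N}$ introduces a size bias where none
existed. That is a real mechanism (it is exactly how normalization harms
large-molecule sets in practice), and we report it rather than shrinking
the intercept or the size spread to manufacture neutrality.

## Numerical choices and degenerate inputs

* Significance boundaries compare with a `sqrt(.Machine$double.eps)`
  tolerance so printed two-decimal inputs classify as printed.
* Score TSVs are written with `%.17g` and parsed through `strtod`, making
  write/read round trips bit-identical (a fast approximate double parser
  is off by one ulp often enough to matter).
* Truth sidecars serialize the full generator configuration (doubles at
  `%.17g`) plus a version tag; `replay()` refuses a version mismatch and
  otherwise regenerates bit-identically from the seed.
* Empty score tables, single-role tables, deletions that empty a role,
  non-isomorphic molecule pairs, zero-variance correlation inputs and
  infeasible template requests (e.g. a ring flavor with too few heavy
  atoms) all raise immediate, specific errors rather than propagating
  NaN.

## Problem sizes used by the shipped checks

The test suite runs the full 40/1200 generator for the score-level
experiments (sub-second per seed), 20 seeds for the two stochastic
recovery properties, 1000 replicates for the random baseline, exhaustive
enumeration up to 8 molecules for the brute-force oracle, and a 72-pair
benchmark for the structure-level detector recovery; these sizes give
stable statistics while keeping a full run under a minute on one core.

## Known limitations

* The generator's linear-additive score model has no pose geometry, no
  protein field, and no program-specific functional form; conclusions
  about GOLD or Glide specifically cannot be drawn from it.
* The ring-conformation detector compares given conformers only; it does
  not search conformational space and will miss differences a
  re-minimization would reveal.
* The tautomer detector keys on bond-order patterns of the heavy-atom
  graph with explicit hydrogens; aromatic forms encoded as Kekulé
  alternations are handled, but delocalized representations (bond order
  4 throughout) of *different* tautomers would compare equal.
* The greedy fallback above the automorphism cap returns an upper bound
  on the symmetry-minimized RMSD, not the minimum.
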