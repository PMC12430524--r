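---
title: "Classifying kinase variant drug resistance from backbone dihedral ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying kinase variant drug resistance from backbone dihedral ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionForest)
```

## The problem

Point mutations in the BRAF kinase domain can render tumours resistant to
ATP-competitive inhibitors such as dabrafenib and vemurafenib. Whether a
given variant is drug-sensitive (S) or drug-resistant (R) is a clinical
question, but the mechanism is structural: mutations reshape the
conformational ensemble the kinase domain samples at equilibrium.
`torsionForest` implements an analysis pipeline that classifies variants
from that ensemble alone, using only the backbone torsion content of the
sampled conformations:

1. **Featurization.** Every retained conformation ("frame") of every
   variant is reduced to its backbone dihedrals: phi(i) =
   torsion(C(i−1), N(i), CA(i), C(i)) and psi(i) =
   torsion(N(i), CA(i), C(i), N(i+1)), in degrees on (−180, 180], named by
   biological residue number (`phi600`, `psi494`, ...). A chain of N
   residues yields 2N − 2 features; the 276-residue kinase-domain chain
   yields 550.
2. **Iterative tree selection.** A depth-limited Gini decision tree is fit
   on all features; the angles it splits on are harvested and removed from
   the pool; repeat. Each round contributes a small disjoint set of
   discriminative angles.
3. **Leave-one-variant-out (LOVO) random forest.** For each variant, a
   forest is trained on every *other* variant's frames over the selected
   angles and the held-out variant's frames are predicted; frame votes are
   aggregated by majority to one variant-level S/R call. Holding out whole
   variants (never individual frames) is what makes the estimate honest:
   frames within one variant are highly correlated, so frame-level
   cross-validation would leak.
4. **Interpretation.** Exact interventional Shapley values attribute the
   forest's resistant-vote fraction to the selected angles; a per-dihedral
   circular-statistics table contrasts class-average angles; convergence
   diagnostics (RMSD plateau, Ramachandran window agreement, windowed
   re-selection) support that the retained frames represent an
   equilibrated ensemble.

The pipeline consumes conformational ensembles; it does not produce them.
Molecular-dynamics ensembles arrive either as multi-model PDB files
(backbone atoms N/CA/C) or as precomputed frame × dihedral matrices.
Because no public trajectory data exist for the original study design, the
package ships a synthetic ensemble generator that reproduces the study's
statistical structure, so every downstream stage is testable end to end.

## The synthetic generator: what it emulates, and what it does not

`generate_study()` emulates the study design: per variant, 3 independent
trajectories × 10,000 frames, of which the final 1,000 per trajectory are
retained (3,000 frames/variant); a 276-residue chain numbered from 448, so
feature names carry kinase-domain numbering; 12 labeled variants for the
dabrafenib roster (36,000 × 550 matrix) and 11 for vemurafenib
(33,000 × 550).

Each dihedral of each frame is an independent draw from a von Mises
distribution — the circular analogue of a normal, appropriate for
equilibrated single-basin sampling and the weakest assumption under which
circular means are well defined. The mean structure has three layers:

* a per-study baseline mean per angle (phi drawn near the broad
  alpha/beta region, psi spread widely — loosely Ramachandran-like);
* a class-level shift on a small set of *planted* discriminative angles,
  added for resistant-labelled variants (default 60°, on the angles the
  reference analysis reported for each drug);
* a per-variant jitter drawn **once per variant** (default SD 5°), so
  frames within a variant are exchangeable but variants within a class are
  not identical. Without this layer, leave-one-variant-out would be
  trivially equivalent to frame-level cross-validation and would overstate
  generalization.

Default dispersion is concentration κ = 8 (circular SD ≈ 21°), a typical
equilibrated backbone spread. The reference study does not characterise
its empirical per-angle dispersions, so κ and the jitter SD are package
choices, exposed in the configuration and chosen once.

What the generator does **not** emulate: autocorrelation within a
trajectory (frames are i.i.d.), correlations between neighbouring
residues' angles, multimodal basins, and any coupling between sequence
change and global structure. Passing tests therefore demonstrate that the
*pipeline machinery* is correct and that the statistical design
(LOVO, vote aggregation, selection) behaves as claimed under a known
ground truth — not that real trajectories of real variants are separable.

A small torsion-space backbone builder (`build_backbone_from_torsions`,
standard peptide geometry, omega frozen trans) closes the loop between
angle space and coordinate space: it provides exact round-trip fixtures
for the torsion extractor and coordinate ensembles for the RMSD machinery.

## Tree selection: parameters and their rationale

* `max_depth = 2` per selection tree. Each reference-analysis tree
  contributed at most two distinct angles; a depth-2 tree splits on at
  most three nodes and in practice harvests about two distinct angles per
  round, reproducing that cardinality. Configurable.
* `min_leaf = 5` frames. Prevents memorising single frames; the reference
  analysis is silent on this, and with 33,000-row training sets the value
  is essentially inactive except against degenerate splits.
* Split search is exhaustive: every midpoint of consecutive distinct
  sorted values of every candidate angle, scored by sample-weighted child
  Gini impurity. Candidates are ranked by the integer-exact rational
  score (c0l² + c1l²)·nr + (c0r² + c1r²)·nl over nl·nr, so mathematically
  tied splits compare as exactly equal doubles and ties resolve
  deterministically toward the smaller threshold. Feature ties resolve by
  canonical order: ascending residue, phi before psi.
* Trees are fit on frame-level rows (the data matrix rows), with the
  selection run once on all labeled variants, matching the single global
  selection trees of the reference workflow; a fold-safe variant (run
  selection inside each LOVO fold) can be composed from the exported
  functions if leakage through selection is a concern.
* Splits act on raw signed degrees. An angle whose distribution straddles
  ±180 can defeat a single threshold; `recenter_matrix()` (rotate each
  angle so a reference ensemble's circular mean maps to 0) is provided as
  mitigation and is OFF by default, matching the reference features.

## The forest and vote aggregation

`train_forest()` fits `n_trees = 100` Gini trees on bootstrap resamples of
the training frames, restricted to the declared feature list, with
per-node feature subsampling (`mtry = floor(sqrt(p))`) and a depth cap of
5. A frame's label is the majority of tree votes; a variant's label is the
majority of its frames' votes. Both ties go to **sensitive**: a resistant
call triggers clinical action and should require a strict majority; variant
ties are additionally flagged low-confidence. Class imbalance (7 S vs 5 R
variants in the dabrafenib roster) is left unweighted. Every stochastic
step requires an explicit seed, and LOVO folds derive per-fold seeds from
it, so the pipeline is bit-reproducible.

The reported accuracy is **variant-level** (correct variants / known
variants): the reference accuracies (11/12 = 91.67%, 11/11 = 100%) are
consistent only with variant-level counting.

## Shapley attribution

`exact_shapley()` computes interventional Shapley values by exhaustive
coalition enumeration (feasible because selected feature sets have ≤ 6
angles; a hard cap of 16 features guards tractability). The value function
v(S) is the mean forest output over a background set with the features in
S taken from the frame being explained; the attributed output is the
continuous resistant-vote fraction, not the hard label, so attributions
are informative near the decision boundary. The default background is 100
frames sampled from the training matrix under a fixed seed. Exact
enumeration makes the efficiency axiom an identity: base + Σ values equals
the model output to machine precision, and the test suite verifies the
null-player and symmetry axioms plus agreement with an independently coded
permutation-enumeration implementation at 1e−12.

## Per-dihedral class differences

`group_angle_analysis()` compares, for every dihedral, the circular mean
of all sensitive frames with that of all resistant frames (frames pooled
within class by default; a per-variant-mean mode exists). Differences are
wrapped signed degrees. Significance is a Welch two-sample t-test on
values unwrapped about the pooled circular mean — the minimal adjustment
that makes a linear test meaningful for wrapped data. A dihedral is
flagged only if it is significant at α = 0.05 **and** its absolute
difference exceeds a magnitude threshold, default 15°, the scale of the
wild-type ensemble's own dispersion; `wt_threshold()` recomputes that
scale from any reference ensemble as the mean per-angle circular SD. No
multiple-testing correction is applied by default — the magnitude gate is
the effective filter — and a Bonferroni flag exists.

## Convergence diagnostics

* `rmsd_plateau()` scans rolling windows (default 500 frames) of a Kabsch
  RMSD trace and reports the earliest index from which every later window
  has |slope| ≤ 1e−4 per frame and SD ≤ 0.1 — a formalisation of the
  visual "levelled off" call.
* `ramachandran_window_agreement()` pools (phi, psi) pairs over residues,
  bins at 10° (divisor of 360 required), and returns the Jensen–Shannon
  distance (base 2): 0 identical, 1 disjoint. JSD is chosen over
  chi-squared for boundedness. The null scale depends on the number of
  pooled points: at the full design width (274 residue pairs × 1,000
  frames per window) two stationary windows sit near 0.04.
* `windowed_selection_stability()` re-runs the tree selection on frame
  windows (the design's final 200-frame windows) and reports Jaccard
  overlaps of the selected sets pairwise and against the full retention.

## Numerical choices and degenerate inputs

Angles live in degrees on (−180, 180], wrapped with the half-open
convention (−180 maps to +180); torsions use the IUPAC sign (cis 0, trans
180, right-hand rule about the central bond) via the atan2 formulation,
stable near 0/180. Collinear quadruples, empty ensembles, single-class
training sets, constant feature columns, zero-frame variants, resultant
lengths near 0 (undefined circular mean) and rank-deficient
superpositions are all rejected with specific errors rather than silently
propagated; a class represented by a single variant makes LOVO impossible
and says so. The von Mises sampler is the Best–Fisher rejection method,
vectorised; paper-scale generation (36,000 × 550) takes seconds.

## Problem sizes used in the shipped checks

The test suite exercises scaled-down studies (12 variants, 12–30 residue
chains, tens of frames) for unit behaviour, and the full design scale
(276 residues, 3 × 1,000 retained frames, 550 angles, 36,000/33,000-row
matrices) for the layout, recovery, and convergence checks; the
permutation null uses 20 label shuffles on 250-frame-per-variant
subsamples with 15-tree forests, sizes at which the null distribution is
already stable. These sizes are the package's own verification choices.

## Known limitations

* The generator's independence assumptions (see above) make the synthetic
  task easier than real trajectory data; results on it validate the
  machinery, not the biology.
* Feature selection run on all labeled variants (the reference workflow's
  design) can leak selection information into the LOVO estimate when
  signal is weak; with the strong planted signal this is immaterial, but
  on real data the fold-safe composition should be preferred.
* Only single-chain, protein-backbone PDB models are supported; side-chain
  chi angles and omega are out of scope.
* Exact Shapley enumeration is capped at 16 features; no sampling
  approximation is provided.
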