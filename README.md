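# torsionForest

Classify protein kinase variants as drug-**R**esistant or drug-**S**ensitive
from the backbone dihedral content of their conformational ensembles.

Mutations in the BRAF kinase domain decide whether ATP-competitive
inhibitors (dabrafenib, vemurafenib) still work. The structural signal sits
in the equilibrium conformational ensemble each variant samples, and a
remarkably small number of backbone torsions carries it. `torsionForest`
implements the full analysis as a tested, reusable R pipeline:

* **Featurization** — every conformation of every variant is reduced to its
  backbone torsions phi(i) = torsion(C(i−1), N(i), CA(i), C(i)) and
  psi(i) = torsion(N(i), CA(i), C(i), N(i+1)), degrees in (−180, 180],
  named by residue (`phi600`, `psi494`, ...). A 276-residue chain gives 550
  features; the frame-level matrix for a 12-variant study is
  36,000 rows × 550 angles (+ status and variant columns).
* **Iterative decision-tree feature selection** — fit a depth-2 Gini tree by
  exhaustive split search, harvest the angles it splits on, remove them,
  repeat; disjoint per-round feature sets.
* **Leave-one-variant-out random forest** — train on all other variants'
  frames, predict every held-out frame, aggregate frame votes to one
  variant-level call by majority (ties go to sensitive). Accuracy is
  counted over variants, never frames, so correlated frames cannot leak.
* **Exact Shapley attribution** — interventional value function, exhaustive
  coalition enumeration over the (small) selected feature set; efficiency,
  null-player and symmetry axioms hold to machine precision.
* **Circular angle statistics** — per-dihedral class-mean differences with
  proper wrapping, Welch tests on unwrapped values, and a wild-type
  dispersion-derived 15° magnitude gate.
* **Convergence diagnostics** — Kabsch RMSD plateau detection, Ramachandran
  window Jensen–Shannon agreement, and stability of the selected feature
  sets across frame windows.
* **Synthetic ensemble generator** — von Mises per-angle distributions with
  class-level planted signal and per-variant jitter, reproducing the study
  design (3 trajectories × 10,000 frames/variant, final 1,000 retained), so
  the whole pipeline is testable without any MD run.

I/O covers multi-model PDB ensembles (backbone N/CA/C), angle-matrix TSV,
and variant label tables; a bundled roster maps the study's 16 BRAF variants
to S/R/Unknown status per drug.

## Worked example

A scaled-down synthetic study (60-residue chain, 3 × 100 retained frames
per variant, signal planted on `psi494` and `phi500`):

```r
library(torsionForest)
cfg <- pipeline_config(list(
  seed = 20, n_residues = 60, residue_offset = 448,
  frames_per_trajectory = 300, retain_last = 100,
  planted = c("psi494", "phi500"), selection_rounds = 2,
  n_trees = 50, shap_frames = 30))
res <- run_pipeline(cfg)
print(res$selection)
print(res$lovo)
```

```
SelectionResult: 2 round(s)
  round 1: psi494, phi500  (gini 0.4861 -> 0.0539, training accuracy 0.971)
  round 2: phi501, psi501, phi502  (gini 0.4861 -> 0.4687, training accuracy 0.606)
LovoResult on {psi494, phi500, phi501, psi501, phi502}: variant-level accuracy 1.0000
 variant truth predicted vote_fraction
   V600E     S         S     0.9766667
   V600M     S         S     0.9766667
   ...
   S467L     R         R     0.9533333
```

Round 1 recovers exactly the two planted angles with a large impurity drop
(0.486 → 0.054); round 2, with those removed, only finds weak residual
structure. Leave-one-variant-out classification on the selected angles
calls all 12 variants correctly, and the Shapley ranking puts the planted
angles on top:

```r
round(res$shap$ranking, 4)
#> psi494 phi500 phi502 psi501 phi501
#> 0.2566 0.2394 0.0099 0.0040 0.0036
subset(as.data.frame(res$angle_table), flag,
       select = c(feature, difference, p))
#>        feature difference p
#> psi494  psi494   61.91242 0
#> phi500  phi500   57.52395 0
```

The angle-difference table flags exactly the planted dihedrals: their
class-mean differences (≈ 62° and 58°) exceed the 15° wild-type dispersion
gate at vanishing p. The unknown-significance variants each receive one
S/R call (`res$vus`), and `res$rama_distance` (here 0.064) reports the
Ramachandran agreement between early and late retained frames.

On the published performance surface: feeding the bundled reference
variant-call tables through the evaluation module reproduces the reference
metrics —

```r
calls <- reference_variant_calls("dabrafenib")
confusion_and_metrics(calls$status, calls$predicted)
#> MetricsReport (R = positive class)
#>   confusion: TP=4 FP=0 TN=7 FN=1
#>   accuracy 0.9167 | specificity 1.0000 | MCC 0.8367
#>   class S: precision 0.8750 recall 1.0000 F1 0.9333
#>   class R: precision 1.0000 recall 0.8000 F1 0.8889
```

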