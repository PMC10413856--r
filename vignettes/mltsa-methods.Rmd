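---
title: "Models and methods behind mltsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mltsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mltsa)
```

# The problem

When a drug-like ligand leaves a deep receptor pocket — the motivating case
is an antimuscarinic bronchodilator leaving the orthosteric site of a
muscarinic G-protein-coupled receptor — the residence time is controlled by
a transition state (TS) somewhere along the dissociation path. Finding that
TS, and the interactions that define it, from molecular-dynamics (MD) data
is the job this package automates. The chain has four stages:

1. **Adaptive unbinding CV.** Ligand–protein heavy-atom pairs closer than
   3.5 Å for more than half of a simulation segment are declared
   *interacting*; the collective variable (CV) is the plain sum of those
   distances. The CV is restrained harmonically
   ($U = \tfrac12 k\,(\mathrm{CV}-c)^2$, $k = 10$ kcal mol⁻¹ Å⁻²) and the
   center $c$ is only ever increased, dragging the ligand outward over 25
   iterations. New contacts formed along the way join the CV; contacts
   stretched beyond 11 Å are discarded.
2. **Downhill trajectories and committor bisection.** Short unbiased
   simulations launched from candidate structures relax into the bound (IN)
   or unbound (OUT) basin. A candidate whose shots split ~1:1 has committor
   ≈ 0.5 and is taken as the TS.
3. **Featurization.** Early-time frames of the downhill ensemble are turned
   into feature matrices: all ligand–protein atom distances inside a 3 Å or
   6 Å shell of the TS pose (optionally augmented with a loop/helix residue
   range), per-residue minimum distances, the eight closest water–ligand
   distances, or the top-100 principal components of the protein heavy-atom
   coordinates.
4. **MLTSA.** One hundred replica classifiers (an MLP and a
   gradient-boosted tree ensemble) are trained to predict IN/OUT from a
   short early window (0.05–0.1 ns). Feature relevance is scored two ways:
   *relative accuracy drop* (RAD) — flatten one feature's variance and
   measure the relative loss of validation accuracy — and *relative feature
   importance* (RFI), the Gini/gain importance of the trees. Per-residue
   profiles are obtained by averaging features that belong to the same
   residue.

The MD engine itself is out of scope: the package supplies seeded synthetic
generators with exact ground truth instead, so every stage is testable.

# The synthetic systems

## Pseudo-atom receptor (`receptor_spec()`)

Pair-detection and featurization need trajectories whose pair-distance
statistics are known exactly. Each protein atom is tethered to a ligand
atom along a fixed random direction, with the distance following a
stationary Ornstein–Uhlenbeck process (mean, stationary SD and relaxation
time are spec fields), so occupancies at any cutoff can be recounted by
brute force. Waters are single-oxygen pseudo-molecules on an outer shell —
every water feature in the pipeline reduces to one distance per molecule,
so one site suffices.

## Binding funnel (`make_funnel_system()`)

The end-to-end protocol needs a system the ligand can actually leave. The
funnel has a rigid three-atom ligand in a six-atom pocket ring, a line of
"vestibule" atoms along the exit axis spaced so the ligand keeps forming
new interacting pairs on its way out (as a real exit channel does), a
Gaussian binding well (3 kT deep, 1.5 Å wide), and harmonic walls (2 kT/Å²)
confining lateral motion. The propagator is overdamped Brownian dynamics of
the rigid ligand (D = 10 Ų/ns, dt = 2·10⁻⁶ ns, 50 steps per frame);
restraint forces use kT at 310 K to convert the kcal-based force constant.
The geometry was designed so that contacts sit near the detection cutoff at
rest and the discard rule genuinely fires during a run.

## Double-well committor system (`toy_system_spec()`)

Downhill ensembles are overdamped-Langevin paths on
$U(x) = B\,((x/a)^2-1)^2$ with barrier $B$ = 6 kT at the saddle $x=0$ and
basins at $x=\pm a$ ($a$ = 1 Å). Overdamped (Brownian) rather than full
Langevin dynamics keeps the committor exactly computable by quadrature
($q(x_0) \propto \int_{-a}^{x_0} e^{U/kT}\,dx$, `committor_exact()`), which
the Monte-Carlo shot generator is tested against. A trajectory's label is
the basin it *first* reaches, checked at every integration step — the
standard committor convention, immune to later recrossings (rare at 6 kT:
the Kramers rate is ≈ 0.04/ns, about 2 % over a 0.5 ns shot).

Features are planted: informative features equal a constant plus
`informative_gain` times the reaction coordinate plus Gaussian noise
(SD 0.5 Å); the rest are pure noise on the same scale. With gain 1 the
single-frame Bayes accuracy of one informative feature is Φ(2) ≈ 0.98,
so a competent classifier should exceed 0.9 while the label-shuffled
control stays at 0.5 — that contrast, not any particular accuracy value,
is what the tests assert.

**Problem sizes.** The default ensemble is 150 trajectories of 1250 frames
over 5 ns (frame spacing 0.004 ns), so the default 0.05–0.1 ns analysis
window holds 13 frames per simulation — the window is the same ~1 % early
slice of the trajectory that the protocol prescribes, at a desk-scale frame
density. Windows are half-open `(t_start, t_end]`, which makes "a 0.05 ns
window at spacing Δ" contain exactly `0.05/Δ` frames.

# Design choices the protocol leaves open

* **Restraint-center schedule.** The candidate center is
  `cv(current) + δ · n_pairs`, clamped so the history never decreases. The
  per-pair increment δ is not prescribed anywhere, but it is constrained by
  arithmetic: a harmonically tracked CV advances the ligand by ≈ δ per
  iteration (the CV is a sum over n pairs whose distances all grow roughly
  with the displacement), and the protocol is expected to move the ligand
  ~10–12 Å in 25 iterations. That back-of-envelope gives δ ≈ 0.4–0.5 Å per
  pair; the default is **0.5 Å**. A value as small as 0.1 Å would cap the
  total displacement near 2.5 Å and the protocol could never terminate by
  displacement.
* **Discard rule timing.** Pairs are discarded on the *segment-mean*
  distance exceeding 11 Å, not on instantaneous excursions — robust to
  single-frame spikes. Both the rule and the threshold are config fields.
* **Re-admission.** A discarded pair that re-qualifies (occupancy above ½
  again) re-enters the CV; detection is symmetric with the initial scan,
  and the ledger keeps the full event history.
* **Empty CV mid-run.** If every pair has been discarded the segment is
  propagated unrestrained: the ligand has lost all tracked contacts and
  either drifts past the stop displacement (10 Å, matching the ~10–12 Å
  ligand displacements the protocol aims for) or is recaptured.
* **Stop criterion.** Ligand-centroid displacement from the starting pose,
  default 10 Å, checked after each iteration.

# Labeling and bisection choices

* The downhill score is the equal-weight sum of the CV's pair distances
  (weights are configurable; nothing in the protocol fixes them), averaged
  over the final 10 % of frames. Terminal-window averaging was preferred
  over first-crossing for *scored trajectories* because short paths
  recross; the synthetic generator labels by first crossing because there
  the full path is available at every integration step.
* Thresholds should bracket the undecided region: the bundled toy windows
  use score = 10 + x with thresholds 10 ± a/2, i.e. half-way into each
  basin.
* `select_ts_candidate()` minimises |IN fraction − ½|; ties go to the
  earlier window along the path. Wilson 95 % intervals accompany every
  window fraction.

# Featurization conventions

* **Shell semantics.** "Within X Å of the ligand" selects protein heavy
  atoms whose minimum distance to *any* ligand heavy atom at the TS
  reference is below X, then takes **all** ligand × selected-atom pairs.
  This is the default because it reproduces the ~5000-feature scale a 6 Å
  shell is expected to produce, which a strict pair-under-X reading does
  not; the strict reading is available as `semantics = "strict"`.
* **Water identity.** The eight closest waters are ranked at the reference
  frame and then tracked *by molecule identity* — a tracked water that
  drifts away produces a growing distance, which is physically continuous.
  Per-frame re-ranking (`track = "per_frame"`) is available.
* **PCA.** Frames are superposed on the protein heavy atoms of the
  reference, coordinates flattened, and the PCA fitted on the pooled
  in-window frames (the same data the classifiers see). Per-residue
  contributions are sums of squared loadings, which sum to one per
  component by construction.
* **H-bond site occupancy** uses a pure distance criterion (3.5 Å to the
  site heavy atom); no angular term is defined anywhere in the chain.

# ML design

* **Splits are by simulation, never by frame** — frames of one trajectory
  are strongly autocorrelated, and frame-level splitting would leak the
  outcome. Validation accuracy is counted over frames.
* **Replica seeds.** Replica r uses `base_seed + r` for both the 70/30
  split and the model initialisation, so ensembles are bitwise
  reproducible.
* **MLP.** One hidden layer of 8 rectangular units (nnet's logistic
  sigmoid), weight decay 10⁻³, 100 BFGS iterations, inputs standardised
  with training-split statistics. The planted committor signal — and the
  distance features the pipeline produces generally — are low-dimensional
  and close to linearly separable, so a small network reaches the ceiling
  accuracy; widening it multiplies training cost ~linearly in the weight
  count without measurable benefit at these feature-set sizes (tens to a
  few thousand features, ~10³ training frames).
* **GBDT.** xgboost with 100 trees, depth 3, learning rate 0.1,
  single-threaded for determinism. Gain importance is the Gini-style
  impurity reduction; per replica it is normalised to sum to one before
  averaging.
* **RAD.** "Removing the variance" of feature f replaces its column with
  the feature's global mean over the full data set, then re-evaluates the
  replica's validation accuracy A_f; RAD = (A₀ − A_f)/A₀. The relative
  form makes profiles comparable across ensembles with different
  baselines. A permutation variant (`method = "permute"`) shuffles the
  column instead. A constant feature yields RAD = 0 exactly.

# What the synthetic tests do and do not show

Passing the suite demonstrates that the bookkeeping (detection, ledger,
scheduling, splits, importance algebra) is exact, that the stochastic
stages behave correctly on systems with known committors and planted
signals, and that the chain recovers planted ground truth with the
prescribed ensemble sizes (150 trajectories, 50 shots per window, 100
replicas). It does **not** show that the defaults are right for a real
membrane-embedded receptor: the toys have no conformational heterogeneity,
no correlated features beyond the planted ones, no force-field physics,
and far fewer atoms. Accuracies near 0.95 on the planted system are a property
of the generator's signal-to-noise choice, not a prediction for real data,
where ~0.77–0.8 is more typical for distance feature sets.

# Numerical notes and limitations

* Integration steps are chosen for stability of the stiffest harmonic
  term (D·dt·k_eff ≲ 0.15); halve `dt` before stiffening the restraint.
* DCD I/O is single precision (≈10⁻³ Å round-trip); XTC is not read — use
  DCD or multi-model PDB.
* `committor_exact()` integrates e^{U/kT}; for barriers ≫ 20 kT the
  integrand overflows and the committor saturates numerically.
* Superposition uses the Kabsch SVD solution with a determinant guard
  against reflections; collinear fitting selections are rejected.
* Feature matrices hold S × T × D doubles in memory; 150 × 1250 × 50 is
  ~75 MB. Persist with `write_feature_matrix()` (CSV + JSON sidecar).
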