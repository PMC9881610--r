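---
title: "Grid free-energy docking, FragMap reweighting and consensus scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid free-energy docking, FragMap reweighting and consensus scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfedock)
```

## The model

gfedock predicts the relative blockade of the hERG potassium channel — the
canonical off-target behind drug-induced QT prolongation — by combining a
structure-based score computed in precomputed *FragMap* fields with a
ligand-based physicochemical regression.

FragMaps are 3D grids of *grid free energy* (GFE, kcal/mol), one per
functional-group class: apolar (`GENN`), hydrogen-bond donor (`GEND`),
acceptor (`GENA`), positively charged (`MAMN`) and negatively charged
(`ACEO`). They derive from cosolvent simulations of the target in which
probe-molecule occupancy is accumulated on a grid; the normalized occupancy
probability $p$ of each voxel maps to a free energy by the Boltzmann
transformation

$$\mathrm{GFE} = -k_B T \ln p, \qquad k_B = 0.0019872\ \mathrm{kcal/mol/K},$$

capped above at `gfe_cap` (default +3 kcal/mol, about $5\,k_BT$ at 300 K) so
that unvisited voxels carry a finite, unfavorable penalty. Generating the
maps themselves (grand-canonical MC/MD of the membrane-embedded channel) is
out of scope here: the package consumes maps in OpenDX format and ships a
synthetic Gaussian-well generator for testing and method development.

A ligand pose is scored by the *ligand grid free energy* (LGFE): every heavy
atom is assigned one FragMap class from its element, formal charge and
bonded hydrogens (charged > donor > acceptor > apolar precedence; hydrogens
are never scored because the maps are built from heavy-atom densities), and

$$\mathrm{LGFE}(\mathbf{x}, w) = \sum_{a} w_{t(a)}\,
\mathrm{GFE}_{t(a)}(\mathbf{x}_a),$$

where $t(a)$ is atom $a$'s class and $w$ a per-class weight vector (unit by
default). The lookup is nearest-voxel rather than trilinear: it matches the
occupancy (overlap) interpretation of the maps and keeps the score exactly
linear in $w$, which the reweighting machinery exploits. Per-atom terms sum
exactly to the total, so any atom partition yields an exact moiety
decomposition — the tool used to attribute affinity changes to individual
substituents.

## Docking protocol

Docking is Monte-Carlo simulated annealing in the FragMap field. One run is

1. random placement: ligand centroid uniform in a sphere (default radius
   10 Å) around the pocket center, orientation uniform over rotations;
2. greedy minimization (default 10,000 steps, downhill moves only) — the
   grid-field stand-in for force-field pre-minimization. An optional
   intramolecular-energy callback can be added to the MC energy for users
   who want strain terms;
3. Metropolis MC at 300 K (default 10,000 steps);
4. simulated annealing, temperature linear from 300 K to 0 K (default
   40,000 steps).

Moves are chosen uniformly among rigid translation (±1 Å per axis), rigid
rotation (±0.25 rad about a random axis through the centroid) and, when
rotatable bonds exist, torsion rotation (±0.5 rad). Rotatable bonds are
single acyclic bonds between non-terminal heavy atoms. Moves whose centroid
leaves the placement sphere are rejected outright: the maps extend over far
more of the target than the pocket being docked, and an unconfined walk on
the flat capped region would diffuse away from the site. Uphill moves pass
the Metropolis test $\exp(-\Delta E / k_B T)$; at 0 K only downhill moves
survive, so the anneal terminates in a local minimum.

A `dock()` call repeats runs in independent blocks (default 5 blocks of up
to 50 runs, hard cap 250) and stops early once the two lowest run scores
agree within 0.5 kcal/mol, reporting the best pose over all runs. The
convergence rule is stated in the field only as a tolerance; "two lowest
run scores within tolerance" is this package's interpretation, and both
limits are configurable. Every run seeds its own RNG substream from the protocol
seed, so results are bit-reproducible and blocks are independently
replayable.

## Ionization states

Compounds ionizable near physiological pH are scored in both states and
mixed with Henderson–Hasselbalch fractions at pH 7.4: for a base the
charged fraction is $1/(1+10^{\mathrm{pH}-\mathrm{p}K_a})$ and

$$\mathrm{LGFE}_{HH} = f_c\,\mathrm{LGFE}_{charged} +
(1-f_c)\,\mathrm{LGFE}_{neutral}.$$

Mixing is linear in the energy scores, matching the ionization-state
weighted LGFE formulation; the result always lies between the two state
scores. States are supplied explicitly (the package does not enumerate
protonation), with pKa as user input.

## LGFE to pIC50

The conversion between LGFE and predicted pIC50 is not uniquely fixed by
the method description, so both plausible modes are provided. The default
treats LGFE as a binding free energy at 300 K,

$$\mathrm{pIC50} = \frac{-\mathrm{LGFE}}{\ln(10)\,k_B T} =
\frac{-\mathrm{LGFE}}{1.3727\ \mathrm{kcal/mol}},$$

which is consistent with training-set mean unsigned errors near one log
unit; an affine mode $a\,(-\mathrm{LGFE})+b$ with user-fitted $a, b$ is
available for regression-calibrated workflows. Note that Pearson R, the
predictive index and percent correct are invariant between the two modes;
only MUE depends on the choice.

## FragMap reweighting (MCSA)

The per-class weights are trained against experimental affinities by
Markov-chain MC simulated annealing. Because LGFE is linear in $w$, each
ligand's docked pose is first decomposed into unweighted per-class sums
$G_{it}$, and the chain re-scores the whole training set as $G w$ — no
redocking inside the loop. The objective is the negated target metric
(Pearson R by default, percent correct optionally) plus a flat-bottom
penalty $k\,[\max(0, w-u)^2 + \max(0, l-w)^2]$ with $k = 5000$ kcal/mol
and bounds $l = 0.05$, $u = 2.0$. The penalty permits excursions of at most
$\sqrt{1/k} \approx 0.014$ beyond a bound per unit of metric gained, which
is the tolerance the tests use when asserting the bound-respecting
property.

The chain itself — 50,000 steps, single-weight uniform proposals of
half-width 0.05 from a start at $w = 1$, geometric effective-temperature
decay from 1.0 to 0.01 — is this package's own default; the published
workflow cites prior work for its schedule without reproducing it, so
every element is configurable. Training is train-once, apply-everywhere:
one weight set fitted on the training split is applied unchanged to all
evaluation sets. The finalization step redocks every compound under the
trained weights; a per-ligand pose-shift diagnostic (centroid displacement
vs the original poses) is attached as an overfitting sentinel, since
weights that only look good by distorting poses show large shifts.

Note the scale degeneracy: doubling all $G$ entries while halving $w$
leaves every prediction unchanged, and correlation metrics are invariant
to positive rescaling of $w$. Weight recovery is therefore assessed on
predictions, not on the raw weight values.

## Property and consensus models

The ligand-based channel is ordinary least squares over five descriptors —
logP, logS, TPSA (Å²), molecular weight and van der Waals volume —
consumed from an input table (descriptor computation is deliberately not
normative; any provider can fill the CSV). The consensus model refits the
same regression with the structure-based predicted pIC50 appended as a
sixth regressor; joint refitting, rather than averaging two models, is the
package's stated interpretation of combining the two sources (averaging
can be had by predicting separately and mixing). Rank-deficient designs
are rejected with the collinear columns named, and fits require more
observations than parameters.

## Evaluation metrics

* **MUE** — mean unsigned error in pIC50 log units.
* **Pearson R** — with a zero-variance guard that returns 0 with a warning
  instead of NaN, so optimization objectives stay finite.
* **Predictive index (PI)** — pairwise rank concordance weighted by the
  experimental difference $|y_j - y_i|$; +1 for perfect ordering, −1 for
  full inversion, 0 at random. Prediction ties contribute 0; experimental
  ties carry zero weight; all-equal experimental values are an error.
* **Percent correct (PC)** — for each compound as reference, the fraction
  of remaining compounds ranked on the correct side, averaged over
  references; random baseline 0.5. Ties count as incorrect by default
  (`strict`), or half-correct under the `half-credit` option.

Tie conventions are not fixed by the method description; the defaults
above are documented choices and PC's is configurable.

## Synthetic study conditions

The generator builds everything the pipeline consumes with known ground
truth:

* **Maps**: baseline at the cap plus negative Gaussian wells. The default
  places one well per class, co-located at the grid center (depths −6 to
  −4 kcal/mol, width 3 Å) on a 21³ grid at 1 Å spacing — co-location lets
  a compact ligand realize every atom's class signal in one pose, so
  affinities derived from class composition are achievable docked scores.
* **Ligands**: self-avoiding heavy-atom chains (bond length 1.5 Å) whose
  atoms realize a prescribed class composition exactly; donors get an
  explicit hydrogen. Chemistry is deliberately minimal — scoring and
  docking only see class labels and coordinates — so passing tests
  demonstrate the machinery, not chemical realism.
* **Affinity tables**: per-class sums $G_{it}$ uniform in [−5, 0] with a
  0.7 occupancy pattern, true weights drawn inside the optimization
  bounds (default spread 0.3–1.8 so unit weights are clearly
  mis-specified), Gaussian pIC50 noise of 0.3 log units — the scale of
  inter-laboratory scatter in curated hERG data.
* **Two-signal consensus data**: affinity = descriptor signal + structure
  signal + noise, so by construction the consensus regression must beat
  either single-source model.

What the synthetic conditions do *not* emulate: real FragMap topography
(many anisotropic basins), ring-containing flexible chemotypes, tautomers,
experimental heteroscedasticity, and any membrane or protein context.
Results on synthetic fixtures validate the algorithms, not hERG
pharmacology.

## Numerical choices and degenerate inputs

* Voxel index is `floor((x − origin)/spacing + 0.5)` per axis; half-way
  points round up. Out-of-grid lookups return the cap.
* OpenDX values are written with 17 significant digits so read-back is
  exact; z varies fastest, row-major, axis-aligned grids only.
* Formal charges survive SDF round trips via `M CHG` lines (which take
  precedence over the legacy atom-block charge column, per the format
  specification); corrupt records are skipped with a warning rather than
  failing the file.
* At 0 K the Metropolis test accepts only non-positive energy changes —
  no division is evaluated on the rejected branch.
* Zero-variance inputs: Pearson returns 0 with a warning; PI on all-equal
  experimental values is an error (its weights vanish identically).
* Docking with zero steps returns the placement pose; an empty torsion
  list simply removes torsion moves from the proposal mix.

## Problem sizes used in the shipped tests

The test-suite and acceptance-script runs use scaled protocols chosen as
this package's standard quick-validation conditions: 100/1,000/4,000
minimization/MC/annealing steps for single-well recovery studies (100
independent seeds), 30/200/800 steps with 2×2 runs for pipeline-level
checks on 10–15 ligands, and the default 50,000-step MCSA chain on
50-ligand tables. The full production protocol (10,000/10,000/40,000
steps, 5×50 runs) is the package default for real use.

## Known limitations

* Nearest-voxel lookup makes the score piecewise constant; gradients are
  unavailable and minimization is stochastic search, not line search.
* No sterics beyond the GFE field: poses may overlap receptor atoms if
  the maps do not penalize the region.
* The greedy in-field minimization is not a force-field minimization;
  strained internal geometry is neither detected nor corrected unless an
  intramolecular callback is supplied.
* Weight training on small series (fewer than ~10 compounds) is prone to
  the documented scale and sparsity degeneracies; the redock step and
  pose-shift diagnostic are the intended guard, not a substitute for a
  held-out validation set.

## A minimal session

```{r example, eval = FALSE}
spec <- synthetic_spec(n_ligands = 12, rng_seed = 1)
dir <- tempfile("fixtures")
write_synthetic_fixtures(spec, dir)

cfg <- run_config(
  maps_dir = file.path(dir, "maps"),
  sdf = file.path(dir, "ligands.sdf"),
  affinity_csv = file.path(dir, "affinities.csv"),
  descriptor_csv = file.path(dir, "descriptors.csv"),
  pka_csv = file.path(dir, "pka.csv"),
  sites = list(S1 = c(0, 0, 0)),
  protocol = dock_protocol(n_min_steps = 100, n_mc_steps = 1000,
                           n_anneal_steps = 4000, n_independent = 2,
                           runs_per_block = 2),
  bml = bml_config(n_steps = 10000),
  seed = 1)
res <- run_pipeline(cfg)
res$metrics
```
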