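---
title: "Methods: a subcellular-element model of wing-disc cross-section mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a subcellular-element model of wing-disc cross-section mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`wingsce` simulates the cross-section of the *Drosophila* wing imaginal disc
along its anterior-posterior axis as a two-dimensional subcellular-element
(SCE) system. Three node classes carry the mechanics:

* **nucleus nodes** — each cell holds a cluster (default 10) of Morse-coupled
  nodes forming a soft, elongated nucleus;
* **membrane nodes** — an ordered ring per cell, bonded by springs
  (`E_memb`), partitioned into apical, basal and two lateral arcs;
* **ECM nodes** — an open spring chain (`E_ecm`) wrapping the basal
  perimeter, partitioned into ECMs (over the squamous layer), ECMbc (margins)
  and ECMc (under the columnar pouch).

Node positions evolve by overdamped (inertia-free) dynamics

$$C_\mathrm{class}\,\dot{x} = -\nabla E,$$

integrated with the explicit Euler method at a default step of 0.002 AU.
The energy is a sum of nine terms: two Morse interactions (volume exclusion
`E_v`, nucleus cohesion `E_nuc`), six spring families (membrane `E_memb`,
lateral E-cadherin adhesion `E_adhL`, basal integrin adhesion `E_adhB`,
apical interlayer adhesion `E_adhA`, basal actomyosin contractility
`E_cont`, ECM stiffness `E_ecm`) and a quadratic penalty on each cell's
polygon area (`E_vol`), the two-dimensional realisation of cytoplasmic
volume conservation. The Morse form is the two-exponential SCE potential
$U(r) = U_0 e^{-r/\xi_0} - W_0 e^{-r/\gamma_0}$ with a hard cutoff;
separations within 1 nm of the cutoff are treated as beyond it, so rest
configurations placed exactly at the cutoff are robust to rounding.

Units are micrometres for length, nanonewtons for force, and an arbitrary
simulation time unit (AU) absorbed by the damping coefficients.

### Interaction scope and pair lists

Volume exclusion acts between nucleus and membrane nodes of the same cell,
between membrane nodes of different cells, between non-adjacent membrane
nodes of the same ring (ring neighbours are covered by `E_memb`), and
between membrane and ECM nodes. Exclusion candidates are rebuilt on a
uniform spatial grid every `pair_refresh_interval` steps (default 50).

Adhesion is pairwise and matched: a lateral, basal or apical adhesion bond
persists while shorter than its break distance; only unpaired nodes are
offered new partners by mutual-nearest-neighbour matching within that
distance, one partner per node. Persistence matters: adhesion that re-hops
every refresh transmits no tangential force, and cells then slide freely
along the basement membrane. Two further structural choices:

* **Adherens belt.** The lateral-wall bonds adjacent to each cell's apical
  arc are unbreakable, making the apical surface a mechanically connected
  band, as the adherens-junction belt does in epithelia.
* **Interlayer coupling.** The two cell layers are built in apposition
  (0.2 µm) and the apical adhesion `E_adhA` spans the whole pouch by
  default (`adhesion_span_fraction = 1`). This distributed coupling stands
  in for force transmission through the enclosed, incompressible lumen,
  which is outside the model's scope as an explicit fluid; without it the
  pouch peels off the squamous layer and collapses into an inverted sack
  under any contractility. The central 20 % of columnar cells remain the
  *tight adhesion zone* used by the interlayer-gap detector.

### Contractility

Basal actomyosin contractility connects laterally opposed membrane nodes of
each columnar cell lying below its basal-most nucleus node (minus one node
spacing), measured along the cell's own apicobasal axis. The coefficient
`k_cont` (nN/µm) is the **total** contractile stiffness of a cell, divided
evenly across its pairs; this keeps the contraction force independent of
the node resolution (and is what makes halving the time step or refining
the discretisation leave the outcome essentially unchanged). The study
levels are 3, 6 and 9 nN/µm.

## Built tissue and calibration

`build_tissue()` constructs the calibrated flat cross-section: 65 columnar
cells of 2.5 × 25 µm, 10 squamous cells (stretched to span the tissue,
≈17 µm each, within the measured 15–18 µm), 2 marginal boundary cells per
side, nuclei centred at fractional height 0.65, and the three-region ECM
chain one adhesion gap outside the membranes. Two desk-scale presets exist:
`"reduced"` (17 columnar cells, 1.25 µm node spacing — used throughout the
package's tests) and `"mini"` (9 columnar cells — used by the sensitivity
screen).

The builder places every spring at rest and every non-bonded gap at or
beyond its interaction range, then relaxes the whole tissue to mechanical
equilibrium (overdamped descent plus an L-BFGS polish, tolerance 0.02 nN —
six to seven orders below the nanonewton-scale forces of a simulation).
Relaxation rather than analytic placement is required because the nucleus
clusters must settle against their membranes: the nucleus is deliberately
sized to nearly fill the cell width, which props the cell open and holds
the cell-row pitch; without it, zero-rest-length contractility collapses
cells into strings.

The squamous layer carries an intrinsic lateral tension
(`squamous_prestress`, default 10 % rest-length shortening of its membrane
bonds), encoding the lateral actomyosin activity that keeps peripodial
cells flat and taut and lets the squamous layer pull on the columnar layer
through the marginal cells. Consequently squamous membrane springs are the
one bonded family *not* at rest in the built tissue; the built state is an
equilibrium under that tension.

ECM prestrain is applied by rest-length reduction: a spring in region $R$
gets $r_0 \to r_0 - F_R / k_\mathrm{ecm}$ and therefore carries exactly
$F_R$ of tension at the built geometry. The patterned-tension scenario uses
`F_ECMs = 2` nN by default with `F_ECMc` set by the 4–7× ratio; the
absolute scale is a package calibration (only the ratios are prescribed),
chosen so the ratio-7 case bends visibly but far less than high
contractility.

## Shape quantification

* **Global curvature** — signed circumcircle curvature through a surface
  polyline's endpoints and arc-length midpoint. The sign convention is
  dome-positive: positive when the pouch bows toward the squamous side
  (margins deflected basally). The tissue-level readout
  `tissue_global_curvature()` measures the **pouch apical surface** — the
  surface quantified alongside the basal peripodial surface in the original
  analysis — because the pouch basal surface convolves bending with
  columnar height growth (the pouch deepens relative to the margins, which
  reads as spurious inversion).
* **Menger profile** — at each interior point, the circumcircle curvature
  of the points one arc-length half-window behind and ahead (linear
  interpolation along the polyline; default window 5 µm, configurable — the
  experimental pipeline's window is not published).
* **Nuclear position** — per columnar cell, $L_A$ and $L_B$ are the
  distances from the nucleus-cluster centroid to the cell's apical and
  basal surfaces; the fractional position $L_B/(L_A+L_B)$ is 0 at the basal
  and 1 at the apical surface, and the height is $L_A + L_B$.
* **Convergence** — a run is converged when the global curvature varies by
  less than `convergence_tol` (relative to `max(|curvature|, 0.005)`, so a
  flat tissue can also converge) over the trailing window;
  `asymptotic_fit()` additionally fits $c(t) = c_\infty - a e^{-t/\tau}$
  by Levenberg–Marquardt least squares and reports the plateau and the
  RMS residual normalised by it.

## Scenarios

Five declarative scenarios reproduce the study's in-silico experiments:
baseline (nothing active), patterned ECM tension (ratios 4–7), basal
contractility (3/6/9 nN/µm, no prestrain), maintenance (high-contractility
dome, then contractility off with ECMc damping ×10³; the control omits the
multiplier), collagenase (acute deletion of all ECM nodes, bonds and basal
adhesion, plus contractility off), and the dual perturbation (collagenase
plus deletion of the interlayer adhesion). Perturbation events fire once
the generation phase converges; "equal" post-phases run exactly as many
steps as the generation phase took.

At the reduced resolution the package reproduces: a flat baseline
(|curvature| < 0.005 µm⁻¹), strictly dose-ordered dome curvature under
contractility with apically retained nuclei and dome radii of 50–100 µm,
ECM-tension bending far below the contractility dome, and maintenance of
the generated shape after contractility switch-off.

Two behaviours of the original study are **not** reproduced, and their
acceptance checks are expected to fail: the no-multiplier maintenance
control does not relax by >30 %, and acute ECM removal does not invert the
bend (hence no interlayer gap opens after the dual perturbation). The cause
is structural: matched, breakable adhesion gives the tissue an adhesion-
turnover plasticity, so the contractility-generated dome is a genuine
equilibrium of the perturbed systems — shape memory here is a material
property rather than an ECM-damping effect. Break distances, interlayer
coupling variants, nucleus size, squamous tension up to the flat-baseline
limit, repulsion-only exclusion and prestrain release were all explored
without recovering an inversion drive; a restoring mechanism beyond the
nine published energy terms (for example membrane bending stiffness or
field-like elastic adhesion) would be needed.

## Sensitivity screen

`run_sensitivity()` draws a Latin hypercube (via the `lhs` package) over
seven mechanical parameters — `k_cont`, both prestrain levels, membrane,
lateral-adhesion and ECM stiffness, and the area-penalty stiffness — runs
the mini tissue for a fixed 6000–8000-step horizon per sample, and computes
partial rank correlation coefficients (PRCC) of the final global curvature
against each parameter: rank-transform everything, regress the parameter
and the output ranks on the remaining parameters' ranks, and correlate the
residuals, with bootstrap confidence intervals. PRCC is invariant under
monotone transforms of any column; the screen's headline result is that
`k_cont` carries the largest-magnitude, positive coefficient. Defaults are
60 samples (30 in the acceptance check) and 500 bootstrap replicates;
failed runs are excluded, tolerated up to 10 %.

## Numerical choices

* **Stability.** Explicit Euler requires $k\,\Delta t / C < 2$ for every
  stiffness; the engine refuses a violating step and names the offending
  term. The area penalty's stiffest mode is uniform ring dilation with
  effective stiffness $k_\mathrm{vol} \cdot P \cdot \ell$ (perimeter ×
  edge length), which is why the default $k_\mathrm{vol} = 5$ nN/µm³ looks
  small but is near the ceiling for the default step; it still holds areas
  within 1 % in all scenario runs.
* **Determinism.** The dynamics contain no noise; identical configurations
  give bit-identical trajectories. Seeds only affect fixture noise and the
  Latin hypercube.
* **Degenerate input handling.** Coincident interacting nodes raise a
  degenerate-pair error naming the nodes; a non-finite position aborts the
  run naming the substep and worst node; zero-area polygons are an error
  and negative signed areas a warning.
* **Problem sizes.** The package's tests and acceptance checks run the
  reduced preset (≈1400 nodes) with horizons of 150 000 steps (generation)
  and mini-preset sensitivity sweeps at 6000 steps per sample; the full
  calibrated geometry (≈10 000 nodes) builds and runs with the same code.

## Limitations

The model is a 2D cross-section: no out-of-plane mechanics, no growth or
division, no lumen fluid, no dissipative shear friction. The synthetic
tissue generator emulates the calibrated geometry with rectangular cells
and a single nucleus cluster per cell; it does not emulate image-derived
irregularities (surface roughness, cell-size variability, segmentation
noise) beyond the optional noisy-arc fixtures, so passing tests demonstrate
mechanical consistency of the model, not performance on segmented
microscopy data. The supplementary calibration table of the original study
is not public; all coefficients here are package calibrations with the
geometry, contractility levels, tension ratios and time step taken from the
published values.
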