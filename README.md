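# wingsce

A subcellular-element (SCE) model of the *Drosophila* wing imaginal disc
cross-section, for studying how the organ's bent "dome" profile along the
anterior–posterior axis is generated and maintained. The intended users are
tissue-mechanics modellers and quantitative developmental biologists who
want a desk-scale, scriptable version of the disc's force balance: basal
actomyosin contractility, patterned basement-membrane (ECM) prestrain,
cell–cell and cell–ECM adhesion, and nuclear positioning.

## The model

Each cell is a ring of membrane nodes enclosing a cluster of nucleus nodes;
the ECM is an open spring chain wrapping the basal perimeter in three
regions (ECMs over the squamous layer, ECMbc at the margins, ECMc under the
columnar pouch). Node positions follow overdamped dynamics

    C_class * dx/dt = -∇E,     E = E_v + E_nuc + E_memb + E_adhL + E_adhB
                                   + E_adhA + E_cont + E_ecm + E_vol

integrated by explicit Euler (default dt = 0.002 AU). `E_v` and `E_nuc` are
two-exponential Morse potentials (volume exclusion, nucleus cohesion); the
six spring families cover membrane cortex, lateral E-cadherin adhesion,
basal integrin adhesion, apical interlayer adhesion, basal actomyosin
contractility (`k_cont`, the stiffness of zero-rest springs spanning each
columnar cell beneath its nucleus) and ECM stiffness; `E_vol` is a
quadratic penalty on each cell's polygon area, the 2D version of
cytoplasmic volume conservation. Shape readouts are the circumcircle
("Menger") global and local curvature of surface polylines and the
fractional apicobasal nuclear position `L_B / (L_A + L_B)` (0 = basal,
1 = apical) with cell height `L_A + L_B`.

The calibrated tissue is 65 columnar cells (2.5 × 25 µm), 10 squamous
cells, 2 marginal boundary cells per side, nuclei initially at fractional
height 0.65; a `"reduced"` preset (17 columnar cells, 1.25 µm node spacing)
runs all of the package's analyses in seconds to minutes on one CPU.

## Worked example

Run the high-contractility scenario (k_cont = 9 nN/µm, no ECM prestrain)
on the reduced tissue and quantify the outcome:

```r
library(wingsce)

cfg <- tissue_config(preset = "reduced")
sim <- sim_config(max_steps = 150000L, convergence_window = 20000L,
                  convergence_tol = 0.005)
res <- run_scenario(scenario_contractility("high"), cfg, sim = sim)

res$final_curvature
#> [1] 0.01967     # dome curvature of the pouch apical surface, 1/um (R ~ 51 um)

np <- tissue_nuclear_positions(res$state)
round(100 * c(mean = mean(np$fraction), sd = sd(np$fraction)), 1)
#> mean   sd
#> 64.2  1.9       # nuclei stay apically biased (0 = basal, 100 = apical)
```

The flat baseline stays flat (|curvature| < 0.005 µm⁻¹), curvature is
strictly ordered in the contractility level (3 < 6 < 9 nN/µm gave 0.0120,
0.0165, 0.0199 µm⁻¹ in the same configuration), and ECM-tension-only
scenarios at ratios 4–7 bend an order of magnitude less — the mechanism
ranking the model is built to exercise. A Latin-hypercube/PRCC screen over
seven mechanical parameters (`run_sensitivity()`) ranks `k_cont` as the
dominant, positive driver of curvature (PRCC 0.98 at n = 30).

Command-line wrappers live in `inst/scripts/`:

```sh
Rscript inst/scripts/simulate.R --scenario contractility --level high --out out/
Rscript inst/scripts/quantify.R --surfaces surfaces.csv --nuclei nuclei.csv --out metrics.csv
```

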