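---
title: "An immersed-boundary model of epithelial acinar morphogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An immersed-boundary model of epithelial acinar morphogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ibcell)
```

## The model

`ibcell` simulates how a single mammary epithelial cell seeded in a
laminin-rich gel develops into an acinus: a growth-arrested monolayer of
polarized cells enclosing a hollow lumen. Cells are fully deformable: each
is a closed counterclockwise polygon of boundary points joined by linear
springs (the plasma membrane), immersed in a viscous incompressible fluid
that represents both cytoplasm and the extracellular medium. The simulation
is a two-dimensional central cross-section of the three-dimensional
culture.

Mechanics follow the immersed boundary method. On a periodic Cartesian
grid the fluid obeys the Navier-Stokes momentum equation in the
quasi-static (Stokes) regime together with a mass balance `div(u) = s`,
where `s` is a field of point sources and sinks. Boundary forces - membrane
elasticity, cell-cell adhesion springs, and the contractile ring of a
dividing cell - are spread onto the grid with the classical 4-point cosine
regularized delta; the solved velocity is interpolated back with the same
kernel, and the boundary points are carried along with the fluid (forward
Euler with adaptive halving so no point moves more than a quarter mesh
width per step).

Cell behaviour is gated by the configuration of labelled membrane
receptors. Every point carries exactly one label:

* **growth sensors** - the default; they detect free space,
* **adhesion receptors** - points joined by a short spring to a receptor
  on a neighbouring cell,
* **ECM receptors** - free sensors whose local matrix concentration
  exceeds the threshold `E`,
* **apical markers** - the lumen-facing domain of a polarized cell,
* **death receptors** - created on an inner cell when it loses contact
  with the polarized shell or with a dying neighbour.

The threshold triple `V = (G, D, E)` indexes the whole behaviour space: a
matured cell grows only if its free-sensor fraction reaches `G` percent
(otherwise it is contact-inhibited); apoptosis starts once the
death-receptor fraction reaches `D` percent; free sensors convert to ECM
receptors at matrix density `E`. Growth is implemented as fluid transport
through the membrane: balanced point sources just inside and sinks just
outside, with total strength `source_strength x free fraction`, so a
crowded cell grows more slowly. When a cell's area doubles, a contractile
ring spring pinches it and it splits into two daughters; while the tissue
is smaller than `division_mode_switch` (default 8) cells the cleavage
plane is orthogonal to the basal domain (two basal daughters), afterwards
parallel to it (one basal, one luminal daughter). ECM is secreted at a
constant rate along basal membrane domains and decays first-order
everywhere, so the basal steady state is `secretion / decay` and arrest
propagates on the matrix clock. The model contains no random numbers:
identical configurations replay bit-identically.

## Domain classifications

A boundary point is *basal* when it is a free (growth or ECM) sensor whose
outward probe, cast two contact distances along the normal, lands in the
exterior region of the box; the exterior is found by rasterizing all cell
polygons onto the grid and flood-filling from the border. A cell is
*outer* if it owns a basal point; everything else is *inner*. The same
probes classify points as *lumen-facing* (probe in an enclosed cell-free
region) and *open* (probe not inside another cell).

Polarization requires all three epithelial domains to be possible: an
outer cell with a matrix-engaged basal domain (at least one ECM receptor),
lateral bonds to at least two other outer cells, and inner-cell contact
(or lumen-facing free membrane) commits, and after `apical_delay_h` its
inner-facing points become apical markers while the bonds to inner cells
are disassembled. Detached inner-cell endpoints become death receptors; so
does the whole free membrane of an inner cell with no bonds to the shell
that touches the lumen - this covers daughters deposited into the cleared
cavity, which the polarized shell refuses to re-bind and which would
otherwise repopulate the lumen indefinitely. A two-hour hysteresis on the
outer status protects rim cells from raster flicker. Apical membrane never
rebinds, which is what makes the cleared lumen permanent.

## Parameters

Units are micrometres and hours throughout. The calibration constants the
outcome actually depends on:

| key | default | meaning |
|---|---|---|
| `G`, `D`, `E` | 25, 10, 14.5 | receptor thresholds (`%`, `%`, density) |
| `cell_diameter_um` | 20 (presets 17) | daughter/resting cell diameter; a cell divides at twice the resting area |
| `source_strength` | 10 (presets 29 / 48) | area gain rate of a fully free cell, um^2/h |
| `apoptosis_rate` | = source | drain rate of a dying cell, um^2/h (presets 15) |
| `maturation_h` | 4 (presets 6) | post-division rest |
| `apical_delay_h` | 4 (presets 48) | polarization commitment delay |
| `death_delay_h`, `detach_delay_h` | 4 (presets 20 / 4) | apoptosis onset / bond shedding delays |
| `ecm_secretion`, `ecm_decay` | 0.1355, 0.00542 | basal secretion and first-order decay; steady state 25, threshold 14.5 is reached after ~160 h of basal exposure |
| `k_membrane`, `k_adhesion`, `k_ring` | 4, 4, 12 | spring constants |
| `d_contact_um`, `d_break_um` | 1.0, 2.5 | bond assembly / disassembly distances |
| `spacing_um` | 0.6 | boundary point spacing, about half the mesh width so the membrane is watertight to the fluid |
| `grid_n`, `domain_um` | 128, 80 | fluid grid; the tuned presets use a 160 um box because a day-8 cluster is ~100 um across and must stay clear of the periodic wrap seam |

The `config_mcf10a()` and `config_yvma()` presets were produced with the
package's own stagewise search procedure against the packaged experimental
tables: proliferation knobs (source strength, maturation) against the
day-4 cell count, then death/polarization/ECM knobs against the day-8
count and the final morphology. The non-tumorigenic baseline uses
`V = (25, 10, 14.5)`; the HER2-YVMA-like variant uses `V = (0, 65, 15)`
with luminal-space sensing enabled, contact inhibition released, and a
larger fluid source strength.

Two flag semantics were genuinely open and are resolved as follows.
`lumen_sensing` lets apical markers count as free space both for the
growth decision and for fluid transport (luminal space promotes growth).
`contact_inhibition_released` affects the growth *decision* only: adhered
membrane cannot transport fluid, so sources are still scaled by the
membrane that truly faces open space. This keeps a crowding brake on
released mutants, which is what limits their day-8 counts to the observed
~40 cells rather than exponential blow-up. Source/sink pairs are delivered
only at membrane stretches facing exterior medium or lumen; a sink lowered
into an abutting neighbour would drain it.

## Numerical choices

* Fluid solve: spectral, with centred-difference first-derivative symbols
  and the five-point Laplacian symbol, so the centred discrete divergence
  of the returned velocity equals the source field at every node to
  round-off. The 4-point cosine delta has equal even/odd translate sums,
  which removes the checkerboard null space of centred differences. The
  inertial term is dropped by default (`rho = 0`); boundaries move far
  less than a mesh width per step.
* Time stepping: mechanics at `dt_h = 0.1`, receptor/phenotype rules every
  `rule_dt_h = 0.2` (splits, resampling, classification, adhesion, ECM
  receptors, polarization, death, growth decisions, division triggers),
  adaptive halving of the mechanics step whenever the fastest boundary
  point would move more than `h/4`.
* Resampling keeps edge lengths within `[0.5, 1.5] x spacing`; insertions
  are chord midpoints (area-neutral), deletions only from over-dense runs
  and never at bonded or ring points.
* Degenerate geometry: membranes that self-intersect after advection are
  untangled by removing the smaller folded loop (deterministic); an
  apoptotic cell that cannot be untangled is treated as fully drained; any
  cell crushed below 10% of its resting area is removed. Dividing cells
  whose neck cannot yet be split cleanly keep contracting and retry.
* Stabilization: a run is growth-arrested when no positive source has
  been placed and no division has occurred over a trailing 2-day window;
  arrested runs stop after a 1-day grace period and freeze their remaining
  scheduled snapshots (nothing can change afterwards by construction).
* Classification: `non_stabilized` if still active at the final day; else
  `normal` (monolayer, lumen, roundness >= 0.75), `filled` (no lumen or
  multilayer), `degenerate` (distorted outline). Roundness is the
  isoperimetric circularity of the convex hull of all boundary points
  multiplied by the solidity (cluster over hull area); the 0.75 split is a
  tunable because the distinction is only pictorial in the experimental
  literature. Lumen areas below 5% of the mean cell area are treated as
  rasterization slivers.
* Receptor fractions are measured over point counts; with near-uniform
  spacing this equals the arc-length measure to first order.
* ECM-arrested cells may re-enter growth if the matrix decays below `E`
  (the rule is memoryless); with basal secretion active this effectively
  never happens in a stabilized acinus.

## Interpreting the printed anchors

The experimental tables packaged under `load_fixture()` give per-day
cross-section areas and counts (MCF10A: 3490 +- 810 um^2 and 11.5 +- 2
cells at day 4; 7640 +- 1550 and 25.8 +- 6.3 at day 8; HER2-YVMA: 6180 +-
1280 / 20.2 +- 4.2 and 11450 +- 2770 / 40.7 +- 10.7) plus effective
doubling times of 47.7 +- 9.4 h and 33.3 +- 6.8 h. Because the per-cell
cross-section averages about 300 um^2 at both days and the measured mean
equivalent diameter is 19.5 um, the resting (daughter) cell is taken to be
~19.5-20 um across; the presets use 17 um so that the mid-growth average
matches the measured 19.5 um equivalent diameter. "Effective doubling
time" is computed as the population-level estimator - the doubling time of
the log-linear fit to the total-count curve over the day 0-8 window in
which counts are reported - which is the quantity population doubling
times in the experimental literature refer to. The mean age of cells at
division (`division_cycle_stats()`) is also reported; in a deterministic
2D run it is dominated by the fast early cycles (~21 h for the baseline)
and is a different statistic.

## Scaled study conditions

Full-length runs at the published durations are supported
(`config_mcf10a()` runs to day 20 in about a minute on one core), and the
test-suite and acceptance-script runs use these problem sizes:

* MCF10A baseline: 128x128 grid on a 160 um box, day-20 horizon.
* HER2-YVMA: same grid, day-8 horizon (of the 24-day condition); at that
  point the class is already decided (no lumen, not growth-arrested,
  more than twice the parental day-4 count).
* Death-threshold robustness: day-16 horizons with the stabilization
  short-circuit.
* The ten threshold-vector classification suites run a miniature geometry
  (`config_mini()`: 12 um cells, 80 um box, 64x64 grid, day-16/12
  horizons) in which classes and size orderings are decided but absolute
  areas are not comparable to the full geometry.
* Tuner demonstrations use `config_toy()` (10 um cells, 60 um box,
  day-3 horizon).

## What the model does and does not capture

A 2D cross-section of a deterministic model reproduces the architecture
(hollow monolayer vs filled vs non-stabilized), the count timelines within
the experimental bands, the threshold-space structure, and the robustness
of lumen formation to the death threshold. It does not capture
sample-to-sample variability (one configuration gives one trajectory, so
early counts move in division waves), true 3D packing (union
cross-section areas run ~25-35% below the printed day-8 values, and
membrane overlap under adhesion contributes), out-of-plane divisions, cell
motility, nutrient limitation, or the alternative luminal death modes
(autophagy, entosis) discussed for these cultures. Lumen clearing
completes around day 12 here versus day 20 experimentally: with
deterministic synchronous polarization the first detachment wave carries
most of the interior.
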