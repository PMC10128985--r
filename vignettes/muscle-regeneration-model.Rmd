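---
title: "An agent-based model of skeletal muscle damage and regeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of skeletal muscle damage and regeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`myoregen` simulates a cross-section of skeletal muscle as a 2-D lattice and
follows its repair over a 28-day cycle (672 one-hour ticks) after an initial
bout of damage. The question the model is built to ask is comparative: does
mechanically **localised** damage, of the kind produced by eccentric
exercise where strain concentrates in a contiguous zone, repair differently
from **widespread** damage of the same magnitude scattered across the
tissue, as seen in chronic inflammatory myopathies?

The tissue is a label grid: fibril pixels (each 3.61 µm² of a 50 µm-thick
slice) grouped into 30 contiguous fibres, separated by an extracellular
matrix (ECM) band carrying a collagen density, inside an empty margin. On
this grid live four mobile agent populations — neutrophils, macrophages
with an M1/M2 phenotype, satellite cells (SCs) with a quiescent →
activating → active → myoblast → fusing lifecycle, and fibroblasts — and
seven secreted-factor value layers (IL-10, IL-15, TNF-α, HGF, IL-6, IGF-1,
TGF-β) that carry the chemical signals coupling them.

A tick proceeds as: (1) the four agent phases execute in an order shuffled
from the run RNG, with synchronous vectorised updates within each type
(agents may co-occupy pixels, so within-type conflicts do not arise);
(2) cytokine production for the tick is computed and deposited spatially;
(3) one diffusion/evaporation step updates all seven layers; (4) the state
is recorded. Every run is fully determined by its configuration and seed.

## Synthetic cross-section generator

The reference histology-derived geometry is emulated by a generator that
tessellates a tissue disc into fibre territories (Lloyd iterations around
farthest-point-seeded centres), labels territory boundaries as ECM, and
then thickens or erodes the ECM band pixel-by-pixel until the requested
counts are hit *exactly*: by default 30 fibres, 25 840 fibril pixels and
4 318 ECM pixels. Erosion only converts an ECM pixel back to a fibre when
no other fibre would become Moore-adjacent and the pixel attaches through
an edge, so fibres stay 4-connected and always separated by at least one
ECM pixel (fibroblasts, which move only through the ECM network, can
therefore reach every inter-fibre site). The generator validates all of
this before returning and fails loudly on infeasible targets rather than
silently adjusting them.

What the synthetic geometry does *not* reproduce is the specific fibre
shape distribution of any real section: real fibres have more irregular,
angular outlines, and emergent quantities that depend on boundary shape
(e.g. exactly where strain concentrates) will differ from any particular
histological slice. Passing tests on this geometry show that the *rules*
behave as specified, not that any specific tissue's numbers are recovered.

## Damage

Widespread damage marks `round(fraction × 25840)` fibril pixels drawn
uniformly without replacement. Localised damage marks the same number of
pixels but chooses those with the highest strain, ties at the cutoff broken
by (row, col) order. Strain comes either from an imported per-pixel CSV
(e.g. registered finite-element output) or from the synthetic generator,
which low-pass filters white noise to a correlation length of roughly a
fibre diameter and mildly boosts fibre-border pixels with high local
boundary curvature and fibrils at thin (< 2 px) ECM bands — the two
geometric features known to concentrate strain mechanically. Its top
percentiles therefore form one or a few contiguous hot zones (at 1%
prescribed damage, typically under a dozen compact clusters), which is the
single property that separates the two damage modes: a mechanical strain
concentration injures a zone, not a scatter of isolated pixels.

At seeding time a one-shot necrosis step spreads damage to every fibril and
ECM pixel in the 3×3 block around each seeded pixel (damaged ECM loses its
collagen). This is applied once, not per tick, and is idempotent by
construction. Necrosis is what makes the two modes differ in *total*
damage: scattered seeds each drag in up to 8 neighbours (~7–9× expansion),
while clustered seeds overlap heavily (~1.2× expansion). Equal prescribed
fractions thus produce substantially more total injury in the widespread
mode — which the results machinery shows is the main driver of delayed
clearance, higher macrophage recruitment and impaired recovery, consistent
with the biology the model encodes.

## Secreted factors

The seven layers obey signed linear production equations in cell counts and
current levels (all 31 coefficients non-negative, signs structural):

```
dIL10/dt = 0.899·AM + 0.827·IL6 + 0.670·HGF
dIL15/dt = 0.004·F + 0.558·Mb + 0.377·TNF − 0.825·TGFβ
dTNF/dt  = 0.273·IM + 0.456·N + 0.493·Fb − 0.346·TGFβ − 0.106·IL6 − 0.044·IL10 − 0.485·IGF1
dHGF/dt  = 0.755·F + 0.156·IL6
dIL6/dt  = 0.043·N + 0.395·IM + 0.077·F − 0.077·HGF − 0.132·TGFβ + 0.482·TNF
dIGF1/dt = 0.258·AM + 0.009·F − 0.788·TNF − 0.019·TGFβ − 0.477·IL6 + 0.826·IL10
dTGFb/dt = 0.007·F + 0.211·AM + 0.798·IL6
```

`AM`/`IM` are anti-/pro-inflammatory macrophage counts, `N` neutrophils,
`Fb` fibroblasts, `Mb` myoblasts and `F` the fibre count (30, constant
within a run). Diffusion follows
`new = evap·(own + diffConst·(nghAvg − own))` with `evap = 0.9`,
`diffConst = 0.1`, an equal-weight 8-neighbour average (a 4-neighbour
toggle and a closed reflective boundary are exposed for testing; the
default grid edge is a value sink — out-of-grid neighbours read as zero and
the corresponding outflow is lost).

Three design decisions here were genuinely open and deserve their
rationale:

* **Starting condition.** The coefficient set determines not only the
  dynamics but the baseline: layers are initialised at the steady state of
  the undisturbed tissue, found by iterating the production/diffusion
  update to a fixed point (`steady_state_field()`). Because several
  production terms are negative and layers clamp at zero, the
  pro-inflammatory layers settle at exactly zero while IL-10, HGF, IGF-1
  and TGF-β settle at positive levels. A zero-damage run started there is
  stationary, which is what makes the no-damage control keep every
  population count constant. Recorded cytokine series are absolute totals;
  subtracting `baseline_totals` gives the deviation-from-baseline view.

* **Spatial placement.** Each *population's* production term is deposited
  at that population's pixels: TNF-α/IL-6 terms of neutrophils and M1
  macrophages at agents currently in contact with damage, fibroblast terms
  at fibroblast positions, M2 terms at M2 positions, fibre terms along the
  fibre borders, and myoblast terms at myoblasts. Cytokine-cross terms act
  on the layer as a whole (negative totals are applied uniformly and
  clamped at zero per pixel). The per-layer sums equal the equations
  exactly; only placement is refined. This matters because with
  `evap = 0.9` the diffusion length is about one pixel: a signal is only
  ever *locally* strong where it is released. Contact-driven release is
  what lets a cluster of engaged neutrophils push local TNF-α + IL-6 above
  the proliferation threshold even though the tissue-wide TNF-α balance is
  negative.

* **HGF.** HGF is released from the ECM as a whole (fibre term plus the
  IL-6-stimulated term over all ECM pixels), not only at damaged ECM.
  Concentrating it at damage sites starves the distributed satellite-cell
  niche of its activation signal, again because of the short diffusion
  length. With ECM-wide release, inflammation (via IL-6) raises HGF
  everywhere above its baseline for a window whose duration scales with
  damage, and SC gates sense HGF *relative to its local baseline*
  (`hgf_activation_rel`, default 1.25×). This reproduces
  elevated-HGF windows that lengthen with damage fraction.

## Agent rules and parameters

**Neutrophils and macrophages** (30 + 30, seeded on random ECM pixels) are
inert without damage. Damage seeding leaves each damaged element at the
clearance-gate integrity (0.5); engaged agents chew integrity further and
run a phagocytosis timer of 2 ticks per fibril and 4 per ECM element, after
which the element is removed from the grid. Neutrophils step to the
lowest-collagen Moore neighbour (damage and debris read as collagen 0);
macrophages descend a Chebyshev distance map to the nearest damage.
Neutrophils that have encountered damage proliferate where local
TNF-α + IL-6 exceeds `neut_prolif_threshold` (0.75 AU) with probability
0.5 per tick; macrophages in contact with damage proliferate once damage
has persisted `mac_prolif_window` (24) ticks, with probability 0.25,
daughters entering pro-inflammatory. Both are limited by a per-pixel
crowding cap (3) and by
resolution: an agent with no damage within 5 px for 24 consecutive ticks is
removed, never dropping below the seeded 30. An M1 macrophage switches
permanently to M2 after its first completed phagocytosis, moving its
secretion from TNF-α/IL-6 to IL-10/IGF-1/TGF-β.

**Satellite cells** (0.08 per fibre per 10 µm, ×5 for the 50 µm slice → 12)
sit quiescent on fibre-border niches. Supra-baseline HGF (> 1.25× the
pixel's own baseline level) activates them at a dose-dependent per-tick
rate (`sc_activation_gain`, default 2, per unit of relative excess);
72 ticks later they are active, move 11 pixel-steps per tick up the
HGF + IL-6 gradient through fibre and ECM (speed 40 µm/h over 3.61 µm²
pixels → `floor(40/3.61) = 11`), and divide while HGF has stayed elevated
for ≥ 6 ticks with IGF-1 present, 50% symmetric (two active) / 50%
asymmetric (one active, one returning quiescent to the nearest niche), with
an 8-tick cooldown. Division is niche-limited: the per-division probability
falls linearly to zero as the total SC pool approaches
`sc_pool_factor` (8) times the seeded count, which is what lets very large
diffuse injuries exhaust the pool instead of expanding it without bound.
After a proliferative phase of at least 24 active
ticks, supra-baseline or rising IGF-1 differentiates them into myoblasts
(and once the HGF window has closed with repair work still outstanding,
maturation itself commits them, so late-activating cells do not idle),
which descend the distance map to the nearest unclaimed *cleared* site
(debris must have been phagocytosed before fusion can begin; while clearance
is still in progress myoblasts gather at the damage), claim it, and draw a
fusion timer uniform on {3,…,24}. Gating fusion on clearance couples the
repair phase to the inflammatory phase: where clearance is efficient —
the dense swarm at a localised zone — rebuilding starts sooner. A completed fusion heals
the damaged/removed fibril patch within Chebyshev radius 3 of the site —
the regenerative mirror of the necrosis spread; each fusion incorporates
the agent (consumes it) with probability 0.02, otherwise it continues to
the next nearest site. When no repair site remains, myoblasts move to the
nearest *expandable* stretch of fibre border (one with a convertible
ECM/EMPTY neighbour touching exactly one fibre — narrow inter-fibre bands
never qualify) and fuse there, converting up to 5 adjacent pixels into new
fibril tissue (hypertrophy), only ever where no other fibre would become
Moore-adjacent. Hypertrophy is bounded: once the fibril count exceeds the
initial count by `hypertrophy_limit` (1%, the magnitude of the hypertrophic
gain expected from a single repair cycle), leftover myoblasts return to
the niche as quiescent cells. Actives with no remaining repair work and
24 ticks of low HGF return to quiescence. There is no cap on SC number.

The patch-healing/serial-repair reading deserves its justification: with
necrosis expanding scattered seeds ~7–9×, a 5–10% bout injures thousands of
elements while the SC pool stays in the tens. One-shot single-pixel fusions
cannot restore such counts within 672 ticks at any plausible SC count; a
fusing myoblast contributing nuclei that regenerate the local fibre segment,
then seeking the next nearest damaged neighbour, both closes the arithmetic
and matches how fusion repairs a fibre segment rather than a point.

**Fibroblasts** (21 seeded, hard cap 67) live strictly on the ECM network
(ECM pixels plus removed-fibril gaps), moving 14 steps per tick
(`floor(52/3.61)`) down a geodesic distance map over that network to the
nearest site needing remodelling. Collagen deposition takes 4 ticks per ECM
element (reset to density 1). A removed *fibril* pixel becomes a
remodelling target too — fibrosis — but only when three conditions hold:
it has stayed unrepaired for `fibrosis_delay` (240) ticks, it sits in a
dense chronic gap field (at least `fibrosis_density` = 10 gap pixels in its
5×5 neighbourhood; isolated lesions awaiting repair are spared), and it
touches the current ECM network, so fibrosis creeps inward from the matrix.
Eight ticks of fibroblast work then convert it to intact ECM. The density
and adjacency requirements make a diffuse injury (dense scattered gap
fields, all bordering ECM) far more exposed than the interior of one
contiguous damage zone.
This race between myoblast repair and fibroblast remodelling is what
produces fibre gaps, shape change and net ECM gain at high widespread
damage while leaving lower damage levels to recover fully. Fibroblasts
divide on simultaneously rising IL-15 and TGF-β (cap 67) and decay back
toward 21 once nothing needs remodelling.

## Numerical choices

* Coordinates are 1-based `(row, col)` in memory (R matrix convention);
  every on-disk CSV interface is 0-based. Conversion happens only at the
  file boundary.
* Damage counts use round-half-up; the Moore neighbourhood is the 3×3
  block minus the centre, enumerated in (row, col) order so lexicographic
  tie-breaking is positional; movement tie-breaks are uniform draws from
  the run RNG.
* Temporal-gradient gates use a small epsilon (1e-9 AU) so that float
  drift around the steady state never triggers divisions.
* The steady-state burn-in iterates to a 1e-10 max-per-pixel change
  (a few hundred iterations); ensembles share one baseline field.
* Distance maps (damage, repair, fibroblast-target, border) are multi-source
  breadth-first Chebyshev/geodesic maps refreshed every 4 ticks when their
  source sets change; agents re-validate targets on arrival so staleness
  only costs a few wasted steps.
* Per-run seeds derive deterministically from the master seed (48271/16807
  multiplicative scheme, kept below 2³¹).

## Behavioural parameters the source biology leaves open

The phagocytosis gate, proliferation thresholds and probabilities, crowding
cap, resolution window, SC division cooldown and incorporation probability,
repair/hypertrophy patch sizes, and the fibrosis delay are not quantities
the underlying experimental literature pins down. Each is a `sim_config()`
parameter with the default stated above. The defaults were chosen once so
that the model's qualitative structure matches the documented repair
biology — neutrophils peaking within days and resolving, macrophages
peaking later and higher under diffuse injury, SC recruitment scaling with
damage, full recovery at low-to-moderate damage with hypertrophic overshoot,
and impaired recovery with fibrosis at 10% widespread damage — and they are
deliberately not tuned per condition: every comparison in the package runs
both damage modes through identical rules and parameters, so differences
between conditions are attributable to damage placement alone.

## Problem sizes used by the test-suite

The packaged tests exercise the full rule set at reduced problem sizes
chosen as the package's own trade-off between statistical resolution and a
desk-scale run time: unit and property tests use 4–6-fibre tissues
(400–1200 fibrils), and the ensemble-ordering tests use a 12-fibre tissue
(10 336 fibrils, 1 727 ECM — 40% of the reference scale) with 10 runs per
condition over the full 672-tick cycle. The acceptance script runs the
full 30-fibre reference geometry. Cell-count *orderings* between conditions
are stable at the reduced scale; absolute peak values are not directly
comparable to full-scale runs (inflammatory peaks scale roughly with the
damaged area).

## Calibration

`ga_optimise()` calibrates the 31 production coefficients against a
fibroblast time course at 0, 48, 168 and 672 h by minimising the RMSE of
simulated fibroblast counts, using a compact real-coded genetic algorithm
(tournament selection, blend crossover, Gaussian mutation, elitism — so the
best RMSE is non-increasing by construction) over the box with lower bounds
0 and upper bounds 1 for the first 25 coefficients and 0.5 for the last six
in the equation-order flattening. Two caveats are documented rather than
hidden: the published reference values behind the original calibration are
not available (only the initial count 21 and maximum 67), so the package
ships a clearly-labelled synthetic stand-in reference anchored at those two
values and accepts any user CSV; and several printed coefficients exceed
0.5, so the "last six" bound assignment cannot be recovered uniquely — the
equation-order flattening is the documented default. Calibration quality
claims are therefore property-based (the optimiser improves its objective
and respects bounds), not value-matching.

## Known limitations

* 2-D only; no out-of-plane migration or repair.
* No finite-element mechanics: localised damage needs an imported strain
  field or the synthetic generator.
* A single damage bout; chronic repeated injury is out of scope.
* The inflammatory resolution rule (idle-agent removal floored at the
  seeded 30) is the model's largest inferential gap; it is config-exposed.
* Cytokine levels are arbitrary units on the model's own scale; only
  relative comparisons (between conditions, against baseline) are
  meaningful.
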