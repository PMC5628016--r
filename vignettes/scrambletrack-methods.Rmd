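---
title: "Methods: membrane, aqueduct, event detection and selectivity analysis"
author: "scrambletrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane, aqueduct, event detection and selectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrambletrack)
```

# Scope and model

TMEM16-family scramblases translocate phospholipids between leaflets and
conduct ions along the same membrane-exposed hydrophilic groove, the
*aqueduct*, one per subunit of the homodimer.  This package analyses
coordinate trajectories of such systems: it does not run dynamics, compute
energies, or build simulation systems.  All coordinates are in Ångström,
times in nanoseconds, angles in degrees.

The analyses share three geometric conventions:

1. **Membrane frame.**  The membrane midplane defines z = 0:
   `centerMembrane()` shifts each frame so that the midpoint between the
   mean z of the upper-leaflet and lower-leaflet phosphorus atoms is zero.
   Because membranes drift under pressure coupling, the midplane is
   recomputed per frame by default (`per_frame = FALSE` pins the first
   frame's shift).  The operation is idempotent and the leaflet split is
   recomputed from the current phosphorus distribution, so pre-centered
   input passes through unchanged.
2. **Leaflet labels.**  A lipid is *outer* if its phosphorus has z > 0 at
   the designated reference frame, *inner* if z < 0; a phosphorus exactly
   at z = 0 inherits the previous frame's label.  Labels are assigned once
   at the analysis start frame and only event detection reinterprets them,
   which avoids label flicker for lipids dwelling near the midplane.
3. **Periodic boxes.**  Only orthorhombic boxes are supported; distance
   computations use the minimum-image convention and z-traces are
   unwrapped (`unwrapZ()`) before any event detection, so a box wrap is
   never mistaken for a crossing.  Triclinic cells are rejected with an
   error rather than silently mis-measured.

# The aqueduct cylinder

`defineAqueduct()` builds one cylinder per subunit: radius 13 Å, axis
perpendicular to the membrane through the geometric centre (x, y) of the
atoms of the helices lining the groove, z range tiled by half-open 2 Å
slabs.  The axis is recomputed per frame by default because the protein
diffuses laterally; a fixed-axis mode exists for rigid fixtures.  Water
counting (`hydrationProfile()`) bins water oxygens radially inside the
cylinder into slabs; phosphate occupancy (`aqueductPhosphateSeries()`)
counts lipid phosphorus atoms jointly inside the cylinder and inside the
central core slab |z| ≤ 10 Å, and reports a 20-sample moving average
(trailing, with partial windows, so constant series map to themselves) and
a normalised count histogram.

# Event detection

**Lipid flip-flop.**  `traceLipids()` emits an unwrapped z-trace for every
lipid whose phosphorus ever enters a cylinder.  `detectFlipEvents()` runs
a per-lipid state machine over three z-regions: leaflet zones |z| ≥ 15 Å,
the midplane band |z| ≤ 5 Å, and the space between.  A *full* event leaves
one leaflet zone and completes at the first frame inside the opposite
zone; *flop* means inner→outer, *flip* outer→inner.  Returning to the
entry zone cancels the attempt, so thermal recrossings near a zone
boundary are never double counted (hysteresis).  A trace that has reached
the midplane band when the trajectory ends, without completing or
cancelling, is a *half* event.  A transit must additionally visit the
cylinder interior within the core (|z| ≤ 10 Å) at least once, so a lipid
crossing far from the aqueduct is not attributed to it.  The 15/5 Å
thresholds are a package choice, not a literature constant: leaflet
phosphates sit near ±18 Å and the mid-membrane dwell site near −3 Å, so
the zones sit 3 Å and 2 Å inside those landmarks, well beyond the ~0.5–1 Å
positional noise of phosphate z-positions; both are arguments.

**Ion permeation.**  `detectIonPermeations()` applies the same hysteresis
logic to ion traces with boundary planes at ±15 Å, mirroring the lipid
detector.  Radial confinement to the cylinder is enforced only while the
ion crosses the core (|z| ≤ 10 Å): ions approach through wide vestibules
outside any cylinder.  The event completes at the first frame beyond the
far plane; *inward* means extracellular (z > 0) to intracellular.  Whether
radial confinement should cover the whole crossing or only the core is not
settled by the source material; core-only is adopted because the funnel
vestibules extend far beyond the 13 Å cylinder.

# Contacts and coordination

Electrostatic contacts are (protein N/O, head-group N/O/P) pairs within
4 Å, restricted to head groups inside the aqueduct; hydrophobic contacts
are carbon–carbon pairs within 4 Å with no cylinder restriction.  All
cutoffs are inclusive (≤) and configurable.  A residue's *contact
fraction* counts frames with at least one contact; its *coordination
ratio* counts donor atoms (a residue donating two oxygens in a frame
contributes two), sums them weighted by frame duration, and divides by the
window duration, giving coordinations/ns — the two conventions differ
deliberately, because the fraction is a residence probability while the
ratio is a rate.  Frame durations are the time to the next frame, the
last frame reusing the previous spacing.  Coordination counts around an
entity (3 Å cutoff) are split into water-O, protein-O/N and lipid-O/N
donor classes; for a lipid centre the donors are counted once per frame
against the whole head group (P/O/N atoms) and the lipid's own atoms are
excluded.

# Gating metrics

`superpose()` implements the Kabsch least-squares fit via SVD with a
determinant correction (proper rotations only) and rejects collinear
subsets.  `perResidueRMSD()` aligns once on a common subset and then
computes each residue's heavy-atom RMSD *without* re-fitting, so the
profile reports displacement in the shared frame.  The *pinch* criterion
declares a frame closed when any configured TM4–TM6 residue pair has a
minimum sidechain heavy-atom distance strictly below 3.0 Å; the strict
inequality and the minimum-heavy-atom reading are the only interpretation
compatible with reported contact distances as small as 2.6–2.7 Å.
Sidechain atoms are all non-hydrogen atoms outside the N/CA/C/O backbone
set; glycine in a pair set is an error rather than a silent zero.

# GHK dilution-potential analysis

For a single cation X with chloride, the zero-current reversal-potential
shift under a concentration switch is

$$\Delta E_{rev} = 25.7\,\mathrm{mV}\cdot
  \ln\frac{X_o + Cl_i\,r}{X_i + Cl_o\,r},\qquad r = P_{Cl}/P_X .$$

`ghkShift()` evaluates this; `ghkRatio()` inverts it in closed form and
errors when the shift lies outside the limits attainable for any positive
ratio (the r → 0 and r → ∞ single-ion potentials).  With fully symmetric
solutions and zero shift every ratio fits; unity is returned by
convention.  RT/F is fixed at the conventional 25.7 mV rather than
recomputed from temperature, and chloride is assumed to follow the cation
(mannitol-compensated dilution), which exactly reproduces the CsCl worked
examples (+45.8 mV for r = 9.7; −17.7 mV for r = 0.45; a 21.6-fold
selectivity change).  The corresponding published NaCl example is
internally inconsistent as printed (a 5-fold switch with a −7 mV shift
does not give the quoted ratio under this equation), so it is not used as
a reference value here.

`appliedVoltage()` converts an applied uniform field along −z to the
potential it imposes, V = −E·L_z: fields of 1.12, 1.87 and 3.74 mV/Å over
a 133.64 Å box give −149.7, −249.9 and −499.8 mV.

# The synthetic world

`syntheticScenario()` describes a labelled stand-in for a simulated
scramblase system; its defaults are the stated conditions of the system
the analyses target:

| parameter | default | why |
|---|---|---|
| box | 204 × 162 × 130 Å | the simulated system's box |
| leaflet phosphates | ±18 Å | reported leaflet positions |
| outer leaflet | pure POPC | reported composition |
| inner leaflet | 2:1 POPC:POPS | reported composition |
| lipids/leaflet | 128 | sized for < 1 min generation |
| frames × dt | 2000 × 0.5 ns | a 1000 ns observation window |
| event schedule | 5 full flops (2 POPS + 3 POPC), 3 half-flops (2 POPC + 1 POPS), 1 half-flip (POPC), 24 inward Na⁺ | the reported event mix |
| noise σ | 0.5 Å | sub-Å thermal jitter of heavy-atom anchors, below the detector hysteresis margin |
| waters/slab | 15 | a partially hydrated open groove (≈40% of bulk for a 13 Å × 2 Å slab) |
| pinch duty | 6.3% | the Ca²⁺-activated gate |

The generator builds a two-subunit pseudo-protein (four vertical lining
"helices" per subunit with N/CA/O backbone pseudo-atoms, gate sidechain
atoms on the TM4/TM6 contact pair, bound Ca²⁺ sites), places lipids with a
P/N head group and two 8-carbon tails on a grid excluding the cylinders,
fills each cylinder slab with water, and scripts events as
piecewise-linear paths: scripted lipids enter the cylinder radially, dwell
at the z ≈ −3 Å mid-membrane site, and either complete to the far leaflet
(full) or remain at the dwell site to the end of the trajectory (half).
Scripted ions run along the cylinder axis between the bulk reservoirs.
The gate toggles between 8 Å (open) and 2 Å (pinched) sidechain
separation on an evenly spread duty cycle, so a requested fraction is met
to within 1/n_frames exactly.  Every scripted event is recorded in a
truth log; the seed fully determines the output.

What the generator does *not* emulate: realistic lipid conformational
dynamics, water structure, electrostatics, protein flexibility beyond the
scripted gate, or any free-energy landscape.  A green detector test
therefore establishes that the detector implements its stated definition
exactly (classes, species, directions, counts, fractions), not that the
definition would capture every event in a real trajectory.  Conversely,
the published trajectory-derived statistics (per-aqueduct phosphate
counts, coordination numbers, pinch fractions of the real gate) depend on
unreleased multi-microsecond trajectories and are used here only to
parameterise the default scenario, never asserted as recomputed results.

# Numerical choices

- Half-open bins `[lo, hi)` everywhere (voxels, slabs, histograms): a
  sample exactly on a boundary belongs to the upper bin.
- Voxel occupancy conserves counts: summed voxel values times the frame
  count equal the brute-force number of occupied voxel–frame pairs.
- Bulk density for `relative_to_bulk` maps is the mean voxel density at
  least 20 Å from any protein atom at the reference frame; an error is
  raised when no such region exists rather than normalising by noise.
- The DCD writer stores a single uniform time step (the format has no
  per-frame time); non-uniform spacing falls back to the mean with a
  warning.  Coordinates are float32, good to ~10⁻⁵ Å relative at membrane
  box scales; PDB roundtrips are exact to the format's 10⁻³ Å.
- `movingAverage()` is trailing with partial start windows, so constant
  series are fixed points and the output length equals the input length.
- Event completion times are the first frame past the far boundary,
  making durations strictly positive.

# Known limitations

- No triclinic boxes, no XTC input, no coarse-grained mapping.
- The flip detector assumes traces sampled finely enough that a transit
  spends at least one frame in the core region; extremely sparse sampling
  could miss the cylinder-interior requirement.
- `relative_to_bulk` normalisation needs a genuine bulk region; small
  fixtures should use `fraction_of_frames` mode.
- The GHK module covers one cation plus chloride only; no activity
  coefficients or liquid-junction corrections.
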