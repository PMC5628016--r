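Package: scrambletrack
Title: Trajectory Analysis of Lipid Scrambling and Ion Permeation in
    TMEM16-Family Scramblases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing molecular-dynamics trajectories of
    membrane-embedded lipid scramblases of the TMEM16 family.  Provides
    membrane-frame conventions (midplane centering, leaflet assignment,
    periodic-boundary unwrapping), occupancy-grid densities with OpenDX
    export, membrane-deformation metrics near the protein, a per-subunit
    aqueduct cylinder with hydration profiles, lipid head-group tracing
    and flip-flop event detection, lipid-protein contact and
    ion/head-group coordination statistics, ion-permeation event counting
    with applied-field voltage conversion, conformational gating metrics
    (superposition, per-residue RMSD, helix center-of-mass distances,
    pinch fractions), Goldman-Hodgkin-Katz dilution-potential analysis,
    and a ground-truth-labelled synthetic trajectory generator for
    validating every analysis stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'geometry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'atoms.R'
    'io-pdb.R'
    'io-dcd.R'
    'io-dx.R'
    'core.R'
    'grid.R'
    'synthetic.R'
    'membrane.R'
    'aqueduct.R'
    'angles.R'
    'contacts.R'
    'coordination.R'
    'ions.R'
    'gating.R'
    'ghk.R'
    'scrambletrack-package.R'
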