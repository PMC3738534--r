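Package: g4geom
Title: Geometric Analysis of G-Quadruplex Conformational Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-frame based conformational analysis of G-quadruplex
    nucleic-acid trajectories. Fits observed bases to standard planar reference
    geometries to obtain per-base triads (origin plus orthonormal axes), combines
    them into quartet and base-pair group frames by half-angle axis association,
    and derives the trajectory observables used to characterise loop dynamics:
    inter-group stacking distance and angle with occupancy classification,
    quartet planarity (RMSD along the quartet Z-axis), hydrogen-bond occupancy
    and lifetime, pairwise and reference RMSD, and backbone torsion rotamers.
    Includes a deterministic synthetic quadruplex-trajectory generator with
    known ground truth (rigid-body noise and two-state Markov conformational
    switching) for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
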