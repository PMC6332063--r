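Package: calixchpi
Title: Quantification of CH-pi Interactions in Calix[4]pyrrole Host-Guest Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify weak CH-pi interactions in 1:1 inclusion
    complexes of aryl-extended calix[4]pyrrole receptors with small N-oxide
    and P-oxide guests. Predicts single hydrogen-bond free energies in a
    competing solvent from empirical alpha/beta donor/acceptor descriptors,
    fits association constants to fast-exchange 1H-NMR titrations (global
    shared-K fit across signals) and to isothermal titration calorimetry
    thermograms (Wiseman-type 1:1 perfusion model), isolates the CH-pi
    contribution by reference-state subtraction (double-difference free
    energies), divides it per contact, and tests its electrostatic dependence
    by linear regression against aromatic-ring electrostatic surface
    potentials. Includes seeded generators for synthetic titrations,
    thermograms and 3D contact geometries, and geometric characterization
    (centroid distance and angular parameters) of CH-pi contacts from XYZ or
    PDB coordinates.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
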