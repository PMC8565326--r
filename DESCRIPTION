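Package: nickscope
Title: Geometry and Catalytic-Mechanism Analysis of Nicking Endonuclease-DNA Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structural analysis of protein-DNA complexes formed by
    single-metal nicking endonucleases such as the LINE-1 retrotransposon
    endonuclease. Reads and writes macromolecular structures (PDB/mmCIF) with
    alternate-location handling and scissile-bond-relative residue numbering;
    computes base-pair and base-pair-step helicoidal parameters, backbone
    torsions and groove-width profiles against a canonical B-form reference;
    enumerates and classifies protein-DNA contacts; performs least-squares
    rigid superposition with selection- and shell-based RMSD; models the
    alpha/gamma torsion-driven rotation path of a scissile phosphate, builds
    pentacoordinate (trigonal-bipyramidal) phosphorane transition-state
    models, and analyzes divalent-metal coordination shells and water
    displacement. Includes a synthetic-structure generator for ideal and
    locally perturbed B-DNA duplexes, hydrated ions and protein-DNA probe
    poses used as test fixtures and as the B-form reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
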