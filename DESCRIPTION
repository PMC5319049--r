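Package: lipacc
Title: Lipid-Accessible Residue Classification for Membrane Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies residues of alpha-helical and beta-barrel membrane
    proteins as lipid-exposed or buried, directly from a structure that has
    been transformed into the membrane coordinate frame (bilayer center at
    the origin, membrane normal along z). The membrane region is cut into
    horizontal slices; in each slice the C-alpha atoms are projected onto
    the membrane plane and a convex hull (QuickHull), a concave hull
    (distance-cutoff digging) and a concave shell are computed. Shell
    membership, transmembrane span-count exceptions and a sidechain
    C-beta/C-alpha/center-of-mass angle rule yield per-residue calls, which
    are written back into the B-factor column of the PDB file (50 exposed,
    0 buried). Includes a relative solvent-accessible surface area baseline
    classifier, confusion-matrix metrics, deterministic synthetic bundle and
    barrel generators with geometric ground truth, and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite
Config/testthat/edition: 3
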