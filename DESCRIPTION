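Package: mitobell
Title: Quantitative Modelling of Prohibitin Ring Complexes in Mitochondrial Cristae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of prohibitin (PHB1/PHB2)
    complexes in the mitochondrial inner membrane. Implements a stereological
    abundance pipeline from cell-level measurements (molecule counts,
    mitochondrial network length, crista spacing) to complexes-per-crista and
    crista-membrane coverage estimates with Monte-Carlo uncertainty
    propagation; a parametric builder for n-fold cyclic assemblies of
    alternating subunits matching the bell-shaped complex geometry;
    symmetry-aware mapping of crosslinking mass-spectrometry residue pairs
    onto such assemblies under a C-alpha distance constraint, including
    self-link based tests of subunit arrangement; and a desk-scale
    subtomogram-averaging simulator with synthetic bell densities, missing
    wedge, in-plane alignment, rotational symmetry detection and Fourier
    shell correlation. Synthetic-data generators with planted ground truth
    make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
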