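Package: dimergen
Title: Random Rigid-Body Dimer Configuration Generation and Curation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates and curates randomized rigid-body dimer configurations
    between small-molecule monomers annotated with interaction sites, for
    building noncovalent interaction-energy datasets. Enumerates interaction-site
    dimers under donor/acceptor and Lewis acid/base pairing rules, places dimers
    from six intermolecular internal coordinates, samples van der Waals
    separations from a biased radial density with energy-threshold rejection,
    selects diverse low-energy starting points for geometry optimization by
    greedy maximin RMSD, filters optimized structures (redundancy, separation,
    molecular-graph change, proton-transfer recapture), and reads and writes the
    Splinter .xyz dialect with its 25-field energy metadata line. A classical
    Coulomb plus Lennard-Jones surrogate stands behind the pluggable energy
    backend so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
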