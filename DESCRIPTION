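Package: hthatlas
Title: Structural Atlas of Helix-Turn-Helix Protein-DNA Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a unified structural coordinate system for helix-turn-helix
    (HTH) protein-DNA complexes. Provides curation utilities for protein-DNA
    crystal structures (pathology screening, duplex standardization, domain
    splitting), heuristic HTH-domain and recognition-helix detection,
    recognition-sequence redundancy elimination, a DNA-anchored constrained
    rigid-body alignment of complex pairs, affinity-propagation clustering with
    exemplar-based construction of a universal residue/basepair index, position
    weight matrix construction from curated binding sites with Laplace
    smoothing, and atomic contact-frequency statistics in universal
    coordinates. A synthetic-complex generator with known ground truth makes
    every pipeline stage testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
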