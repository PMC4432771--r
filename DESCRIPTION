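Package: protdescr
Title: General-Purpose Descriptor Generation for Protein Sequences and
    Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-residue numerical indices from protein
    three-dimensional structures (PDB) and sequences (FASTA) -- contact-based
    topographic indices such as the residue-level weighted contact order,
    amino-acid property scales, and energy-like thermodynamic terms --
    transforms them with sequence-neighbourhood weighting operators
    (autocorrelation, Kier-Hall, electrotopological state, Ivanciuc-Balaban,
    gravitational-like), pools them over residue groups (amino-acid types,
    physicochemical classes, structural contexts) with a panel of aggregation
    statistics, and writes tab-delimited residue-level and protein-level
    descriptor tables for downstream machine learning.  Includes a
    Shannon-entropy variability filter for descriptor relevance ranking,
    inter-protein distance matrices, a batch project-file runner, and seeded
    synthetic-structure generators for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
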