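Package: foldscan
Title: Two-Phase Protein Structure Similarity Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Filter-and-refine similarity searching of protein 3D structures.
    Structures are reduced to chains of secondary-structure elements for a
    fast low-resolution local alignment that prunes a database, survivors are
    re-aligned at residue level using molecular residue descriptors (inter-CA
    vector length, inter-vector angle, secondary structure, amino-acid type)
    with a BLOSUM62-weighted Gaussian reward, and top hits are superposed by
    the Kabsch algorithm to report RMSD over aligned CA pairs. Includes a
    PDB reader, a binary database cache, deterministic synthetic-structure
    generators for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
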