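Package: xnageom
Title: Conformational Analysis of DNA and Xeno-Nucleic-Acid Duplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemistry-aware conformational analysis of nucleic-acid structures,
    including synthetic genetic polymers (threose nucleic acid and its
    phosphonomethyl variant) alongside DNA. Reads PDB/mmCIF models into tidy
    atom tables, resolves alternate conformations, and annotates residues
    against a user-extensible chemistry registry. Computes endocyclic sugar
    torsions and Altona-Sundaralingam pseudorotation (phase, amplitude,
    conformer), chemistry-specific exocyclic backbone torsions and glycosidic
    chi, phosphorus-phosphorus backbone spacings, Watson-Crick pair detection
    with heavy-atom hydrogen-bond distances, base-pair and base-pair-step
    parameters from fitted reference frames, and rigid-body superposition
    (Kabsch) with iterative outlier rejection. A synthetic-structure generator
    builds furanose rings at prescribed pucker and idealized multi-chemistry
    duplexes at prescribed step parameters so every stage is verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
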