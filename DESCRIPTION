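Package: pgnn
Title: Graph Neural Networks for Protein Property Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph neural networks for predicting physicochemical and geometric
    properties of proteins from all-atom structures. Implements a global
    residue-graph network (GSnet) predicting solvation free energy, radius of
    gyration, hydrodynamic radius, diffusion constants and molecular volume, and
    a local charge-aware atom-graph network (aLCnet) for residue pKa shifts.
    Includes PDB/PQR parsing, Gaussian-smeared edge featurization, transformer
    message passing with masked multi-target training and transfer learning
    (frozen or fine-tuned encoders), a leakage-aware sequence-similarity
    splitter for pKa data sets, reference calculators for radius of gyration
    and Shrake-Rupley solvent-accessible surface area, and a synthetic
    all-atom structure generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
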