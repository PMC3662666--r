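Package: ringcsp
Title: Ring-Current Chemical Shift Simulation and RDC Analysis for
    Protein Conformational Change Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects subtle protein conformational change upon small-molecule
    (fragment) binding from backbone amide NMR observables. Simulates
    ring-current induced amide-proton chemical shift perturbations (CSPs) for
    ensembles of docked ligand poses with the Haigh-Mallion semi-classical
    model, scores pose agreement with experimental HSQC CSPs (P factor), and
    flags residues whose experimental CSP cannot be explained by any pose.
    Corroborates CSP evidence with residual dipolar couplings: SVD fit of the
    molecular alignment tensor, RDC back-calculation, Pearson correlation and
    quality factors, outlier detection, and multi-structure comparison.
    Includes synthetic fixture generators (ideal helices, aromatic ligand
    poses, forward-modelled peak lists, tensor-generated RDCs) and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
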