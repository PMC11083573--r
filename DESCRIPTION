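Package: aggtraj
Title: Trajectory Analysis of Early-Stage Peptide Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    self-assembling peptides, built around the early aggregation of the
    N-terminal beta-lactoglobulin peptides 1-33 and 1-52 at pH 2.
    Identifies peptide clusters per frame by single-linkage contact
    clustering under periodic boundary conditions (the head-and-list
    algorithm), builds cluster-size transition networks, assigns
    helix/strand/coil secondary structure from Kabsch-Sander backbone
    hydrogen bonds, detects geometric hydrogen bonds, decomposes
    Shrake-Rupley solvent-accessible surface area by residue
    hydrophobicity, and characterizes aggregate orderliness by the
    nematic order parameter. A synthetic-trajectory generator with known
    ground truth (scripted aggregation events, ideal helices and sheets,
    oriented rod bundles) makes every stage testable without MD output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
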