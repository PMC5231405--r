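Package: tcsgeom
Title: Reaction-Center Geometry and Interface Analysis of Two-Component
    Signaling Complexes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Geometric analysis of histidine kinase:response regulator
    (HK:RR) phosphotransfer complexes. Reads and writes PDB/mmCIF
    coordinates, expands crystallographic symmetry, measures reactive
    His(Ne2)-Asp(Od1) distances, reaction-coordinate distances and Mg2+
    asymmetry ratios, and classifies phosphotransfer reaction centers as
    associative-compatible (Group I) or dissociative (Group II).
    Implements least-squares (Kabsch) superposition with separate fit and
    evaluation selections, the two-regime "slippage" superposition matrix
    quantifying interface gliding, superposition-based transplanting of
    phosphoryl-group surrogates and cations from donor structures,
    Shrake-Rupley solvent-accessible surface area, buried surface area,
    interface footprints, and Lawrence-Colman shape complementarity.
    Ships a synthetic-fixture generator with analytic ground truth so the
    whole pipeline is testable without downloading deposited structures.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
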