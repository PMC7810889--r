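Package: residomics
Title: Presence-Absence Metabolomics for Ancient Organic Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for untargeted LC-MS metabolomics of
    archaeological organic residues. Aligns chromatographic features across
    sample extracts by m/z and retention-time tolerance, removes solvent-blank
    contaminants, merges multi-solvent extracts into a binary presence matrix,
    and explores the result with Jaccard distances, Ward minimum-variance
    clustering and principal components analysis. Identifies compounds unique
    to individual reference plants and scores their ubiquity across vessels,
    annotates accurate masses with candidate elemental formulas, and ships a
    synthetic-study generator with planted ground truth so every stage of the
    pipeline can be validated without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
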