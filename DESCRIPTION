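Package: thermadapt
Title: Comparative Structural and Flexibility Analysis of Thermally
    Adapted Enzyme Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing homologous enzymes adapted to different
    habitat temperatures: geometric interaction censuses (hydrophobic,
    aromatic, hydrogen-bond and ionic contacts), salt-bridge conservation
    mapping across homologs, Kabsch-Sander secondary-structure assignment
    with loop segmentation, least-squares (Kabsch) superposition with
    per-secondary-structure-class RMSD, Shrake-Rupley solvent-accessible
    surface area, trailing-window RMSF profiles from conformer ensembles,
    and classification of surface loops into stability- and
    activity-associated regions from temperature-ladder RMSF differences.
    Includes seeded generators for synthetic structures, homolog families
    and conformer ensembles with planted ground truth.
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
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
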