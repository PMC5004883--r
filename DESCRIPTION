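Package: chromprox
Title: Chromatin Proximity Analysis by 3D FISH Quantification and 5C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for deciding whether a gene and a distal
    enhancer colocalise in nuclei. One arm quantifies two-colour 3D FISH
    images: sub-voxel spot detection and localisation, mutual-nearest-
    neighbour probe pairing, inter-probe distances in nanometres, 200-nm
    distance-class statistics (colocalised / adjacent / separate), per-cell
    allele categories, and Fisher / Mann-Whitney group comparisons with
    s.e.m. across tissue sections. The other arm processes chromosome
    conformation capture carbon copy (5C) contact counts: restriction
    digestion and alternating forward/reverse primer assignment, total-read
    normalisation, fixed-window binning, virtual 4C viewpoint extraction and
    insulation-score domain-boundary detection. Both arms are driven by
    synthetic-data generators with known ground truth: an imaging simulator
    with anisotropic Gaussian point-spread functions for conventional
    widefield and structured-illumination modalities, and a multinomial
    contact-count simulator with power-law distance decay, interaction
    domains and enriched viewpoint pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
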