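Package: hippoplast
Title: Synthetic Benchmarking of Dendritic Spine Morphometry, Object
    Recognition Scoring and Total Protein Approach Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to generate and analyze the three data modalities of a
    hippocampal aging and neuroplasticity study design: PSF-blurred
    fluorescence images of DiI-labeled dendrite segments with spines of
    known geometry, novel-object-recognition behavioral trajectories with
    planned exploration bouts, and label-free proteomic intensity tables
    with planted group effects. Analysis stages cover dendrite-core
    tracing, spine skeleton fitting by fluorescence maximization,
    length-to-width shape ratios and linear spine density, rule-based
    exploration scoring with a 20-second criterion and climbing
    exclusion, Total Protein Approach quantification with unique-peptide
    and group-presence filters and fold-change/FDR differential
    abundance, and the study's two-sample statistics (scaled
    Kolmogorov-Smirnov convention with exact permutation p-values,
    pooled t-test, coefficient of variation). An end-to-end pipeline
    runs a seeded four-group synthetic study and writes a reproducible
    report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    EBImage,
    igraph,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
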