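Package: uroquant
Title: Quantitative Analysis of Urothelial Senescence and Mouse Bladder Function Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the quantitative assays used to study
    cellular senescence in the mouse bladder urothelium and its functional
    consequences. Provides seeded synthetic-data generators with machine-
    readable ground truth for every input (3D confocal stacks with telomere
    and gamma-H2AX foci plus lipofuscin confounders, RNAscope p16 fields,
    SA beta-galactosidase sections, cystometry pressure/volume traces,
    voiding-spot-assay images, RNA-seq count matrices and qPCR Ct tables);
    imaging quantifiers (telomere-associated-focus calling with overlap-ratio
    colocalization and autofluorescence exclusion, puncta-per-nucleus
    counting, positive-cell scoring); cystometric landmark extraction and
    per-mouse summaries; voiding-spot metrics; multi-reference-gene Pfaffl
    relative expression, TPM normalization, a log-CPM Welch differential-
    expression engine and fold-change filter cascades; and a group-comparison
    engine (Welch and pooled t from summary statistics, exact Mann-Whitney,
    Dunnett and Tukey multiple comparisons) that works from printed
    (mean, SD, n) tables as well as raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mvtnorm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
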