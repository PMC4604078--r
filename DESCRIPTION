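Package: dystromorph
Title: Quantitative Morphometry and Decision Statistics for Dystrophic
    Muscle, Bone and Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested re-implementation of the quantitative measurement
    pipeline used in preclinical studies of dystrophin-deficient (mdx)
    mice: muscle-fiber morphometry from immunofluorescence sections
    (border-mask segmentation, rotating-calipers minimum Feret diameter,
    central-nucleation classification), thresholded cell counting and
    area-fraction quantification (IgG influx, Masson trichrome fibrosis,
    revertant fibers), micro-CT trabecular bone morphometry (seeded region
    growing, BV/TV, Tb.Th, Tb.Sp, Tb.N), qPCR relative quantification with
    geNorm reference-gene stability and 2^-ddCt, RNA-Seq heatmap
    preparation (log z-scoring, Ward clustering), scalar assay metrics,
    and the accompanying statistical decision procedure (t/ANOVA + Tukey,
    Anderson-Darling gate, permutation ANOVA, Mann-Whitney and
    Kruskal-Wallis routing). A synthetic-data generator produces every
    input with exact ground truth so each stage is verifiable without the
    original animals or images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    nortest,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
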