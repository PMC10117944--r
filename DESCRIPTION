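Package: radmut
Title: Radiation Mutagenesis Catalogs, Spectra, and Target-Theory Survival Curves
Version: 0.1.0
Authors@R: person("radmut", "maintainers", email = "radmut@example.org", role = c("aut", "cre"))
Description: Tools for comparative radiation-mutagenesis studies in plants:
    harmonization of multi-caller variant catalogs (SNV/indel, symbolic SV and
    breakend records), cross-sample recurrence and allele-fraction filtering
    with M2 zygosity calling, an eight-category mutation classification scheme
    with complex-event clustering and net indel lengths, mutation-spectrum and
    rearrangement statistics (Ti/Tv, G:C/A:T versus genome composition,
    Fisher/ANOVA group comparisons with compact letter displays), per-plant
    gene-impact counts, single-hit multitarget survival-curve fitting with
    shoulder-dose derivation, and a synthetic-data generator that exercises
    the full pipeline against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    optparse,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment
Config/testthat/edition: 3
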