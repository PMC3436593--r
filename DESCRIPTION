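Package: BarcodeDelim
Title: DNA Barcode Evaluation and Species Delimitation by the General
    Mixed Yule-Coalescent Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating DNA-barcoding practice in protists and
    other taxa: model-based pairwise genetic distances (p, K2P/K80 and
    maximum-likelihood distances under JC69, K80, F81, HKY85, TIM2 and
    GTR, each optionally with invariable sites and discrete-gamma rate
    variation), an entropy-based substitution-saturation test with
    critical-value lookup and OTU resampling, barcode-gap
    frequency-distribution analysis including a taxon-sampling
    duplication experiment, and automatic species delimitation on
    ultrametric trees by the general mixed Yule-coalescent (GMYC) model
    with single and multiple thresholds.  A synthetic-data generator
    (Yule species trees, within-species Kingman coalescents, sequence
    evolution under the implemented models) makes every stage testable
    without external sequence downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, ape, phangorn, Biostrings
Suggests: testthat (>= 3.0.0), jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
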