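Package: bovipreg
Title: Combined Embryo and Recipient Metabolite Biomarkers for Bovine
    Pregnancy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for discovering and validating metabolite
    biomarkers of pregnancy after bovine embryo transfer, combining
    gas-chromatography metabolomics of single-embryo spent culture medium
    with recipient plasma. Implements univariate candidate screening with a
    normality-gated ANOVA/Kruskal-Wallis choice and multiplicity control,
    single-biomarker ROC evaluation with closest-to-corner optimal cutoffs
    and bootstrap confidence intervals, and a rule-based combined-biomarker
    procedure: Boolean pregnant-range calls OR-combined across one embryo
    metabolite and one recipient metabolite, scored by F1 with
    Mantel-Haenszel chi-square significance, optionally stratified by Day-6
    embryonic stage. Includes a synthetic cohort generator emulating the
    study design (36 embryo transfers, three nested pregnancy endpoints,
    breed blocks, a 19-transfer Holstein validation cohort) and an
    independent-cohort validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
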