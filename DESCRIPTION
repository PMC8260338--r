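Package: plgfbind
Title: Total Placental Growth Factor from Free PlGF and sFlt-1 via
    Mass-Action Equilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes total placental growth factor (PlGF, free plus
    sFlt-1-bound) from routine immunoassay measurements of free PlGF and
    sFlt-1 using the 1:1 ligand-receptor mass-action equilibrium model,
    estimates the sFlt-1/PlGF dissociation constant from paired
    free/total measurements, and provides the surrounding toolkit: exact
    mass/molar unit conversion, in-silico spike-equilibration and
    recovery arithmetic, method-comparison statistics (Spearman
    correlation with exact permutation p-values, identity-line fits),
    normality-gated group comparisons with exact Mann-Whitney
    enumeration, sFlt-1/PlGF ratio cutoff classification, ISSHP
    preeclampsia and HELLP classification, and a seeded synthetic-cohort
    generator with log-normal marker marginals parameterized from
    published group medians and interquartile ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
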