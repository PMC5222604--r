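Package: stabnorm
Title: Stable Marker-Gene Selection and Geometric-Mean Normalisation for
    Ageing Circadian Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selection of stable reference (normalisation) genes for the
    mouse liver transcriptome under circadian and ageing perturbations, and
    downstream detection of age-related expression changes. Implements
    centered log-ratio (clr) stability screening of candidate genes against
    genome-wide and targeted-panel backgrounds, a meta-analytic fold-change
    criterion over many public studies, combination of assessments into core
    and extended marker sets, positive-control and marker-gene
    geometric-mean normalisation, and repeated-measures mixed-model
    detection of age effects with Bonferroni control. Ships a synthetic-data
    generator reproducing the statistical structure of pooled RNA-seq age
    screens, multiplexed count panels over zeitgeber time, and multi-study
    fold-change tables, with ground-truth accessors for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
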