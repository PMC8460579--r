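Package: binocsync
Title: Binocular Fixation Asynchrony Analysis for Reading Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing small temporal asynchronies between the two
    eyes' fixations in binocular reading. Pairs temporally overlapping
    monocular fixation events into binocular fixations with an optimal
    non-crossing matching, classifies each pair into a nine-type start/end
    asynchrony typology ('Syn', 'T1'-'T8'), summarises the spatial
    distribution of types across the text display (screen regions and
    hexagonal binning), and fits Poisson regression and mixed models with
    random intercepts for participant, article and page to fixation-pair
    counts by screen region, compared by likelihood-ratio tests. Includes a
    synthetic binocular reading-session generator with planted asynchrony
    biases for validation studies, plus readers for a canonical fixation CSV
    and the EyeLink ASC fixation-report dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
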