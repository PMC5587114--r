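Package: hcasim
Title: Digital Twin of an RFID Baseplate Home-Cage Monitoring System for
    Group-Housed Rats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates group-housed rat movement, posture and subcutaneous
    temperature in a standard individually ventilated cage, together with
    the 12-antenna RFID baseplate reader that observes the animals through
    implanted glass transponders.  Raw tag-read streams are converted into
    per-animal tracks via flicker filtering and gap interpolation, activity
    is summarised as antenna transitions in circadian bins, and a synthetic
    side-view camera provides frame-differencing detection of vertical
    (rearing) activity with per-individual assignment.  Agreement between
    measurement routes is quantified with intraclass correlation (ICC(1,k)),
    Bland-Altman limits of agreement, fixed and random-intercept regressions,
    a negative binomial count model, and an implant-site scoring rubric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    MASS,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
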