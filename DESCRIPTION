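Package: crcscreen
Title: Microsimulation and Cost-Effectiveness Analysis of Colorectal Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort microsimulation of the colorectal adenoma-carcinoma
    sequence with competing other-cause mortality, a screening-strategy engine
    covering stool, blood and colonoscopy based regimens (follow-up
    colonoscopy, polypectomy, surveillance and resumption rules), and a
    cost-effectiveness layer computing discounted life-years, quality-adjusted
    life-years, costs, incremental cost-effectiveness ratios with strict and
    extended dominance, and net monetary benefit. Includes a full-factorial
    threshold analysis over blood-test characteristics (sensitivity, interval,
    unit cost) and a scenario-discovery step based on random-forest variable
    importance and a locally weighted regression surface of net monetary
    benefit with iso-benefit contours.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
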