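Package: meioswitch
Title: Bistable APC/C-Cdh1 / Cyclin B:Cdk1 Switch Model of Meiotic Resumption in Mouse Oocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation model of meiotic
    entry (germinal vesicle breakdown) in mouse oocytes, built around the
    antagonism between APC/C-Cdh1-dependent cyclin B degradation and the
    Wee1B/Cdc25B phosphorylation switch on cyclin B:Cdk1. Provides stiff
    time-course simulation of wild-type, triggered and knockout scenarios,
    enumeration and stability classification of all steady states of the
    six-variable system, the two-dimensional pseudo-steady-state reduction
    with Cdh1 and Cdk1 nullclines and their intersections, and a synthetic
    kinase-assay data generator with least-squares parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
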