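Package: camtrapnets
Title: Social Networks and Observer-Agreement Statistics from Camera-Trap
    Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning individual-identification records from
    camera-trap video, annotated by two observer channels (e.g. experts and
    consensus-based citizen scientists), into agreement statistics and
    weighted social networks. Videos are grouped into events by a 15-minute
    same-camera rule, parties are formed under the gambit of the group, and
    dyadic association is measured with the simple ratio index. Networks are
    compared via leading-eigenvector community detection, MRQAP with double
    semi-partialling (Dekker et al. 2007), node strength and eigenvector
    centrality with Spearman rank correlations, and subsample-based
    robustness curves with bootstrap confidence intervals. A synthetic
    fission-fusion community simulator with configurable identification and
    count-error rates makes the full pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
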