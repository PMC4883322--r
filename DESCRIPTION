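Package: aggropig
Title: Aggression Recognition in Group-Housed Pigs from Top-View Depth Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and classifies aggressive interactions (head/body
    knocking and chasing) among group-housed pigs from top-view depth-image
    sequences. Standing pigs are segmented from the pen floor by a height
    threshold, tracked across frames by greedy Euclidean matching of region
    barycenters, and maximal runs of close physical contact lasting at least
    one second become interaction episodes. Each episode is summarised by a
    five-dimensional activity descriptor (minimum, maximum, mean and standard
    deviation of velocity, plus inter-pig distance) and classified by a
    hierarchical pair of binary support vector machines: aggressive versus
    normal, then knocking versus chasing. A synthetic top-view depth-video
    simulator with ground-truth tracks and episode labels supports testing
    and benchmarking without farm recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
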