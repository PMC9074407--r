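Package: tipsaver
Title: Pipette Tip Minimization for Parallel One-Pot DNA Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans contamination-free pipetting for liquid-handling robots that
    prepare many one-pot DNA assembly mixes (BASIC, MoClo, Start-Stop) in
    parallel on a multi-well plate. The distribution of each DNA part across
    the construct wells that need it is cast as a capacitated vehicle routing
    problem in which cross-contamination edges carry unit cost, the total
    travelled cost is fixed at zero and the fleet size (number of tips) is
    minimized. Because the zero-cost relation between wells is a set-inclusion
    preorder, the routing problem is a minimum capacitated chain cover; it is
    solved exactly. The package reads construct and source tables, emits a
    validated pipetting command sequence, reports tip savings against the
    fresh-tip-per-addition baseline, and includes a random Start-Stop scenario
    generator and a savings-versus-scale benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    utils,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
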