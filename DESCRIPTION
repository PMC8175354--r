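Package: signedcircles
Title: Dunbar Circles, Signed Communities, and Structural Balance in
    Friendship Nomination Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of two-wave, signed, directed, weighted friendship
    nomination networks from sociometric surveys. Provides per-student
    Dunbar-circle layer statistics (the mu parameter log(l2/l1) and its
    in-degree analogue rho) with group summaries and cross-wave increment
    tests; signed modularity for directed weighted networks with a
    multi-heuristic optimizer agnostic to the number of communities and an
    exhaustive brute-force oracle; reciprocity with degree-preserving
    rewiring null models; structural-balance testing via triangle censuses
    and embedding-preserving sign permutations; and a synthetic two-wave
    nomination-network generator so every stage is testable without survey
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
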