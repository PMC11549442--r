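Package: hetcon
Title: Uncertainty-Driven Opinion Dynamics on Heterogeneous Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Agent-based simulation of consensus opinion dynamics on
    degree-heterogeneous connected networks. Provides random-graph
    generators spanning the centralization spectrum from a star to an
    all-to-all network at (approximately) constant mean degree,
    Gaussian belief initialization with heterogeneous or deliberately
    mismatched uncertainties, synchronous opinion-update rules (DeGroot
    naive averaging with locally-equal or universal self-weights,
    inverse-variance Bayesian fusion, and a conservative covariance
    intersection style fusion), an accuracy/precision/trueness error
    decomposition, dynamic in-degree centrality observables, and a
    reproducible Monte-Carlo sweep runner.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
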