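Package: cprsim
Title: Agent-Based Simulation of Cooperative Common-Pool Resource Harvesting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates groups of heterogeneous agents that repeatedly harvest
    a renewable common-pool resource governed by a stepwise discrete logistic
    growth rule. Agents hold individual perceptions of the optimal stock size,
    share them with confidence-weighted influence to form group agreements,
    update their knowledge through social learning, and adjust confidence and
    trust in response to ecological feedback. The package provides the
    resource model with an optimal-policy oracle, the agent decision
    operators, a deterministic batch runner for scenario experiments and
    factorial sweeps, outcome classification (cooperation; over-, under- and
    optimal exploitation), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
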