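Package: pulmoperf
Title: Multi-Scale Pulmonary Perfusion Modelling on Anatomic Vascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady-state blood flow in the pulmonary circulation across
    spatial scales. Generates anatomically based arterial and venous trees by a
    volume-filling branching algorithm inside synthetic lung shapes, attaches
    nine-generation ladder acini whose capillary beds follow the Fung sheet-flow
    model with West-zone recruitment, and solves the compliant Poiseuille network
    with gravitational (hydrostatic and tissue-recoil) effects. A calibrated lumped
    pressure-flow surrogate of the main, left and right pulmonary arteries can be
    coupled iteratively to the network with under-relaxation, reproducing
    posture-dependent redistribution of flow between the lungs and gravitational
    gradients in acinar perfusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
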