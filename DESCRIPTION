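Package: oxikin
Title: Antioxidant Thermochemistry and Lipid Oxidation Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing phenolic antioxidants acting on unsaturated
    lipids. Computes homolytic bond-dissociation enthalpies and
    frontier-orbital gaps from tabulated quantum-chemical species energies
    with strict unit handling; estimates Arrhenius (Ea, ln A) and
    Eyring/activated-complex (dH, dS) parameters from Rancimat induction
    periods; performs Flynn-Wall-Ozawa and Kissinger-Akahira-Sunose
    isoconversional analysis of DSC peak temperatures; and estimates IC50
    values from DPPH/ABTS radical-scavenging dose-response curves. A
    synthetic-data module generates Arrhenius-structured induction periods,
    isoconversional peak tables and sigmoidal scavenging curves so every
    fitting stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
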