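Package: aacascade
Title: Adaptable Ensemble Kinetic Modelling of the Arachidonic Acid Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble kinetic modelling of the arachidonic acid (eicosanoid)
    cascade. Represents the reaction network (cyclooxygenase, lipoxygenase,
    non-enzymatic conversion, transport and degradation reactions across an
    intracellular and an extracellular compartment) as an editable tabular
    catalogue, draws kinetic parameters and enzyme concentrations from
    weighted log-normal priors under Haldane thermodynamic-consistency
    constraints, integrates each model variant as a stiff ODE system through
    an equilibration-then-stimulus protocol, scores predictions against
    sparse eicosanoid time courses with a Gaussian log-density quality score
    and ensemble-level Psi scores, and adapts priors to new cell types by
    Kolmogorov-Smirnov testing of the parameter distributions of the
    best-fitting variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
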