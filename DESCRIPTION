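Package: thymostate
Title: Executable State-Transition Models of Thymocyte Differentiation
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A small executable formalism for parallel state-transition
    (statechart) models of lymphocyte dynamics, with two interchangeable
    backends. A population backend compiles a statechart into a linear
    compartmental ODE system implementing the conveyor-belt flux law for
    generation-structured thymocyte differentiation, exports human-readable
    equations, and integrates trajectories exactly via matrix exponentials.
    An agent backend interprets the same statechart per cell in discrete
    time with competing-risks transition sampling, division and death, and
    a mean-field comparison harness. Ships two concrete thymus models: the
    conveyor-belt differentiation model (DN to SP stages, G0/S-M cell
    cycle, generation-indexed differentiation, ganciclovir depletion of
    dividing cells) and a 2-D lattice model of thymocyte migration guided
    by chemokine gradients with TCR/MHC binding, positive/negative
    selection, death by neglect, signal-duration CD4/CD8 lineage choice,
    and thymic egress.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
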