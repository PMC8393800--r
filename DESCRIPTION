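Package: pmaxsel
Title: Cell-Age-Aware Product Formation Models and Entropic Information
    Criteria for Fed-Batch Protein Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling recombinant protein expression in fed-batch
    Escherichia coli cultivations. Derives physiological state variables
    (specific growth rate and average cell age) from biomass trajectories,
    evaluates a library of candidate maximal product formation rate (Pmax)
    models built from growth-, age- and induction-linked terms including
    Monod-type saturation, predicts offline protein trajectories through a
    discrete left-Riemann scheme for the Luedeking-Piret-type balance
    dPX/dt = Pmax - kt*PX, calibrates model coefficients simultaneously
    across multi-site experiment collections (pseudo-global multi-start
    optimisation of a relative-entropy objective), and ranks candidate
    models by AIC, BIC and two entropic extensions of AIC with a tunable
    maximum-parameter-count coefficient kmax. A seedable two-site synthetic
    fed-batch study generator supports parameter-recovery and
    selection-power simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
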