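Package: lymphosim
Title: Continuum Mixture Simulation of Lymphoma Growth in the Lymph Node
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multiphase continuum simulator of non-Hodgkin lymphoma growth in a
    murine inguinal lymph node. Evolves viable, dead and host tissue volume
    fractions under mass conservation with proliferation, apoptosis, necrosis
    and dead-cell clearance; solves quasi-steady reaction-diffusion for
    oxygen/nutrient and VEGF; closes tissue mechanics with a generalized
    Darcy law driven by oncotic pressure; and grows a discrete sprouting
    vessel network on the simulation lattice. Includes the
    immunohistochemistry-based calibration pipeline (Ki-67, Caspase-3, CD31,
    HIF-1alpha, H&E stain-count conversion to model rates), a necrosis-rate
    calibration sweep, virtual histology sectioning of simulated tumors, and
    a radially symmetric reduced model for terminal-size analysis in terms of
    the apoptosis-to-proliferation ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
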