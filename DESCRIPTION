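Package: vesiwrap
Title: Membrane Wrapping of Dumbbell Colloids by Lipid Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse the engulfment of anisotropic
    dumbbell-shaped colloids by giant unilamellar vesicles (GUVs). Provides a
    coarse-grained Langevin simulator of a one-particle-thick fluid membrane
    vesicle with solute-controlled tension and an adhesive rigid dumbbell;
    trajectory observables (tilt angle, insertion depth, per-lobe wrapped
    fractions) and a wrapping-state classifier with transition-time
    measurement; flicker-spectroscopy estimation of membrane tension and
    bending rigidity from equatorial contour fluctuations; an analytical
    overdamped contact-line theory of the dumbbell wrap time with parameter
    fitting and a fluctuation-barrier estimate; and seeded synthetic-data
    generators so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
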