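Package: pemrelease
Title: Diffusion Modelling of Drug Release from Polyelectrolyte-Multilayer
    Coated Particles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the retardation of drug release caused by
    polyelectrolyte-multilayer (PEM) coatings on polymer particles. Provides
    the steady-state series-resistance model for a coated (composite) sphere
    and its coated/uncoated mass-transfer-rate ratio, a conservative
    transient solver for radial diffusion in a two-layer sphere, bookkeeping
    for in-vitro release assays (aliquot-and-replenish cumulative release,
    drug loading, encapsulation efficiency, per-layer coating drug-loss
    accounting), a seeded generator of study-shaped synthetic data (release
    curves with burst, coating-loss runs, zeta-potential sequences), and
    least-squares estimation of transport parameters from release curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
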