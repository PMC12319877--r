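Package: rtefield
Title: Real-Time TMS-Induced Electric Field Computation by Mode Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage solver for the electric field induced in the brain by
    transcranial magnetic stimulation (TMS). An offline stage builds an
    orthonormal basis of brain E-field modes by probing a labeled tetrahedral
    head mesh with Gaussian white-noise magnetic surface currents, solving the
    quasi-static scalar-potential finite-element problem for each realization,
    and compressing the solutions with a volume-weighted QR+SVD. Equivalent
    electric and magnetic surface currents for every mode are extracted on a
    Huygens surface just outside the scalp. The online stage evaluates, for
    any rigid coil placement, reciprocity integrals of the coil primary fields
    (interpolated from a precomputed Cartesian grid) against the equivalent
    currents and reconstructs the brain E-field as a mode expansion. Includes
    a layered-sphere head phantom generator, a figure-8 coil builder, a direct
    FEM reference solver, and the global/local error metrics used to validate
    the expansion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
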