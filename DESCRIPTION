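Package: pentarho
Title: Photocycle Kinetics, Titration, Electrometry and Pore Geometry of a
    Pentameric Viral Rhodopsin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the quantitative characterization of the
    pentameric viral rhodopsin OLPVRII: global multiexponential fitting of
    flash-photolysis transient-absorption matrices by variable projection,
    reconstruction of absolute intermediate spectra under a sequential
    irreversible photocycle (Bateman kinetics), Boltzmann-sigmoid pKa
    titration fits, decomposition of black-lipid-membrane photocurrents into
    electrogenic exponential components, rigid-body (Kabsch) protomer
    superposition and HOLE-style pore-radius profiling of pentamer
    structures, and potential-of-mean-force profiles from particle densities
    with block-bootstrap uncertainties. Includes a synthetic-data generator
    emulating every measurement the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
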