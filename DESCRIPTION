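Package: vibtun
Title: Vibrational Tunneling Spectra from Instanton Couplings and VCI Local States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes vibrational tunneling spectra of multi-well systems by
    combining single-well anharmonic states (VSCF/VCISD on an n-mode
    representation of the potential) with semiclassical inter-well couplings
    obtained from Jacobi-field instanton wavefunctions and a generalized
    Herring surface integral. Minimum action paths between wells are optimized
    with a string method on the Jacobi action; Gaussian width matrices,
    excitation amplitudes and nodal vectors are transported along the path and
    assembled into a tunneling matrix whose eigenvalues give level positions,
    splittings and mixing angles. Includes a two-dimensional benchmark double
    well with independently tunable well frequencies and depth, and an exact
    sinc-DVR reference eigensolver for two-dimensional potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
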