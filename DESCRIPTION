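Package: cdosc
Title: Far-UV Circular Dichroism Spectra of Proteins from Coupled
    Atomic Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts far-UV circular dichroism (CD) spectra of proteins
    from their three-dimensional structures using the second-order term
    of the DeVoe coupled-oscillator theory of optical activity. Atoms
    are treated as point dipoles carrying effective complex
    polarizabilities selected from a library by secondary-structure
    content; the chirality-sensitive coupling coefficients and the
    dipole-dipole interaction matrix yield the molar ellipticity over
    the 188-244 nm band. Includes a hydrogen-bond/torsion secondary
    structure assigner with STRIDE/DSSP file ingestion, D-amino-acid
    handling via sign-flipped polarizabilities, normalized absolute and
    root-mean-square deviation metrics for spectral comparison, a
    discrete Kramers-Kronig transform, Monte Carlo deconvolution of
    atomic polarizabilities from (structure, spectrum) corpora, and
    generators for synthetic structures, Lorentzian polarizability
    libraries and noisy spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
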