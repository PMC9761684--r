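Package: gvpt2
Title: Generalized Second-Order Vibrational Perturbation Theory with
    Automated Resonance Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anharmonic vibrational energies, transition moments and simulated
    IR/VCD spectra from cubic-quartic force fields in dimensionless normal
    coordinates. Implements the VPT2 chi matrix with Coriolis contributions,
    deperturbed (DVPT2) and hybrid degeneracy-corrected (HDCPT2) variants,
    automated identification of Fermi and Darling-Dennison resonances with
    both energy-based (Martin, CVPT) and intensity-aware (wave-function
    coefficient) criteria, polyad construction and per-block variational
    correction (GVPT2), resonance-aware transition moments with projection
    onto the variational states, pseudoeigenvectors, band-shape convolution,
    a Duschinsky consistency check for hybrid force fields, a synthetic
    bundle generator with planted resonances, and a dense variational oracle
    for small systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'chi.R'
    'duschinsky.R'
    'forcefield.R'
    'io.R'
    'ladder.R'
    'methods.R'
    'moments.R'
    'oracle.R'
    'pipeline.R'
    'resonance.R'
    'spectra.R'
    'synthetic.R'
    'variational.R'
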