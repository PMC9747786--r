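Package: focusISM
Title: STED Image Scanning Microscopy Simulation, Pixel Reassignment and
    Focus-ISM Background Removal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for image scanning microscopy (ISM) with a 5x5
    detector array and tunable stimulated emission depletion (STED).
    Simulates per-element scanned point spread functions from scalar
    Debye focal fields, generates synthetic Poisson ISM acquisitions from
    bead or filament phantoms, reconstructs super-resolved images by
    adaptive pixel reassignment (phase-correlation registration),
    classifies and removes out-of-focus background from micro-images
    (outer-frame subtraction and constrained two-Gaussian fitting), and
    sharpens results with background-aware multi-image Richardson-Lucy
    deconvolution sized by Fourier ring correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
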