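Package: kymoMT
Title: Centrosome and Microtubule Dynamics Quantification for Embryo
    Fluorescence Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region-based quantification of centrosomal, centriolar and
    cytoplasmic fluorescence with focal-plane selection and background
    subtraction; circular-arc kymograph construction around centrosomes;
    counting of EB-family plus-end comets at proximal, midpoint and
    cortex-offset regions; microtubule polymerization velocity estimation
    from kymograph slopes; and thresholded pixel-overlap colocalization.
    Includes a synthetic one-cell embryo movie generator (Poisson comet
    nucleation, radial plus-end motion, per-frame catastrophe, Gaussian
    spot rendering with mixed Poisson/Gaussian noise) that provides ground
    truth for every measurement stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
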