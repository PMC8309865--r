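Package: flipim
Title: Fuzzy Logarithmic Image Processing on Bounded Graylevel Ranges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-parameter family of bounded graylevel arithmetics (FLIP)
    generated by the Hamacher T-conorm. Graylevels are fuzzified to tones
    v = g/D in [0,1) and added, subtracted and amplified inside the physical
    range without clipping; the classical LIP, the homomorphic LIP and the
    pseudo-LIP models are recovered as the special cases p = 1, 2 and 0 of the
    model order. On top of the algebra the package implements dynamic-range
    maximizing enhancement (closed-form and joint numerical optimization over
    amplification factor and model order), FLIP neighborhood averaging for
    noise reduction, FLIP Sobel and Laplacian edge detectors with Otsu
    binarization and Pratt figure-of-merit evaluation, weighted image
    blending, and seeded synthetic-image generators for all experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
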