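Package: simi
Title: Similarity Unmixing of Spectrally Multiplexed Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-pixel similarity unmixing (SIMI) for multichannel fluorescence
    microscopy. Each pixel's normalized cross-channel signal is matched against
    a library of fluorophore fingerprints (normalized emission signatures) by
    minimizing the squared difference, assigning one fluorophore per pixel.
    Unlike linear spectral unmixing, the classifier remains functional in the
    underdetermined regime where fluorophores outnumber detection channels.
    Includes fingerprint estimation from single-color reference images, a
    linear-unmixing baseline (ordinary and non-negative least squares), a
    synthetic one-fluorophore-per-cell scene simulator with Poisson/Gaussian
    noise, evaluation tooling (confusion matrices, per-object accuracy), and
    multichannel TIFF input/output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tiff,
    jsonlite,
    pracma,
    EBImage,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
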