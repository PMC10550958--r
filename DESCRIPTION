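Package: pfsfuse
Title: Multimodal Medical Image Fusion with Pythagorean Fuzzy Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-level fusion of pre-registered multimodal medical image
    pairs (MR-T1/MR-T2, MRI/CT, MR/MRA, and MRI with PET or SPECT). Each
    source image is split into a Gaussian base layer and a residual detail
    layer; base layers are fuzzified, lifted to Pythagorean fuzzy images
    with a fuzzification parameter selected by maximizing Pythagorean fuzzy
    entropy, optionally contrast-enhanced with a fuzzy hedge and the INT
    intensification operator, and fused block-wise by a blackness/whiteness
    count rule; detail layers are fused block-wise by spatial frequency.
    Color (PET/SPECT) inputs are fused through the luminance channel in YUV
    space with chrominance preserved. Includes the seven objective fusion
    quality metrics (mean, standard deviation, average gradient, spatial
    frequency, modified spatial frequency, mutual information, fusion
    symmetry), a deterministic phantom generator for fully offline testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    optparse,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
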