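Package: woundkinetics
Title: Scratch Wound-Healing Kinetics via the Fisher-Kolmogoroff Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantifies in vitro scratch wound-healing assays from
    phase-contrast time-lapse imaging. Segments the cell-free wound
    region by local texture, fits the wound closure velocity (the slope
    of the normalized wound area after an initial lag), and inverts the
    Fisher-Kolmogoroff reaction-diffusion model to separate the
    contribution of cell random motility (D) from proliferation
    (doubling time tau), including the Thiele modulus regime diagnostic.
    Ships a synthetic-data generator (1D Fisher-KPP solver plus a
    phase-contrast-like renderer with ground-truth masks) so the whole
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
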