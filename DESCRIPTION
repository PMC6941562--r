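Package: cardiomorph
Title: Automated Histomorphometry of Trichrome-Stained Cardiac Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-level colour segmentation of trichrome-stained heart
    sections by a configurable RGB threshold scheme, with per-section and
    volumetric infarct size, scar collagen content and remote interstitial
    fibrosis morphometry, serial-section voxel-stack assembly for 3D
    inspection, a synthetic phantom generator with exact ground truth, and
    CSV/spreadsheet reporting. Designed for serial sections of infarcted
    mouse hearts where collagen stains blue to blue-gray, viable muscle
    red, and background near-white.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
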