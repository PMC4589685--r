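Package: fibralign
Title: Quantification of Collagen Matrix Microstructure and 3D Cell Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for reflection-confocal images of fibrillar
    collagen matrices and for trajectories of cells migrating through them.
    Implements radial background normalization and an oriented fiber
    enhancement filter bank for fiber segmentation, pore-size spectra by
    sequential morphological opening (granulometry), a Fourier-transform
    fiber alignment index from the eigenvalues of the angular power
    second-moment matrix, cell speed, net invasion distance, eight-partition
    protrusion orientation statistics with a polarization index, and min-max
    normalized cross-metric correlation reports. Includes a synthetic-data
    generator for fiber-network images, persistent random-walk trajectories
    and protrusion event streams with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
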