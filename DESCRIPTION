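Package: flowshape
Title: Cell Shape and Flow-Alignment Analysis of Endothelial Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Morphometry of confluent endothelial monolayers from
    instance-segmentation label masks. Computes per-cell equivalent-ellipse
    properties (area, orientation, axis lengths, elongation factor) from
    pixel moments, applies segmentation quality-control filters (relative
    area, aspect ratio, border contact), and quantifies collective flow
    alignment with axial (180-degree periodic) orientation statistics:
    per-image median orientation, signed deviations, radial histograms and
    a coefficient of variation of the centred deviations. Nonparametric
    group comparisons (Mann-Whitney U, Kruskal-Wallis with Dunn's post
    hoc) are included, together with a synthetic anisotropic-Voronoi
    monolayer generator with known per-cell orientation and anisotropy for
    end-to-end validation without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    ggplot2,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
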