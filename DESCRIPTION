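Package: vinecanopy
Title: Canopy Volume Estimation and Missing-Plant Detection in Vineyards
        from UAV Photogrammetric Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Unsupervised estimation of grapevine canopy volume and
        detection of missing plants from products of UAV photogrammetry.
        Implements two complementary pipelines: a 2.5D surface-model
        method operating on a digital elevation model (terrain
        normalisation by morphological opening, Otsu binarisation of
        vine versus soil, per-cell thickness profiles, quartile-based
        canopy height, cuboid volumes, and thickness-gap missing-plant
        counts), and a 3D method operating on the dense point cloud
        (robust ground-plane segmentation, per-cell alpha-shape volume
        via Delaunay tetrahedralisation with a circumradius cutoff, and
        volume-deficit missing-plant counts). A synthetic-vineyard
        generator produces terrain, canopies, point clouds, rasters and
        ground-truth tables with known geometry so both pipelines can be
        validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, EBImage, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
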