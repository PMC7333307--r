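# shared synthetic-site builders for the tests

specWith <- function(base, ...) {
    do.call(syntheticSiteSpec, utils::modifyList(base, list(...)))
}

# a clean, noise-free, flat, axis-aligned slab vineyard: the exact-recovery
# reference world (rows run along world x, continuous hedgerow)
cleanSiteSpec <- function(...) {
    specWith(list(nRows = 2, rowLength = 8.1, interRow = 2.5,
        intraRow = 0.9, rowAzimuth = 90, canopyHeight = 1.2,
        canopyThickness = 0.4, canopyLengthFrac = 1, missingFraction = 0,
        perVineSizeCV = 0, terrainSlope = 0, terrainNoiseSd = 0,
        demDp = 0.01, pointDensity = 150, seed = 3L), ...)
}

# realistic benchmark site at the 2.5 x 0.9 m geometry
benchSiteSpec <- function(...) {
    specWith(list(nRows = 5, rowLength = 21.6, interRow = 2.5,
        intraRow = 0.9, rowAzimuth = 90, missingFraction = 0.15,
        perVineSizeCV = 0.08, terrainSlope = 0.05, terrainNoiseSd = 0.01,
        demDp = 0.01, pointDensity = 120, seed = 1L), ...)
}

# hidden-gap (palissage overhang) scenario at the 3.0 x 1.0 m geometry:
# continuous hedgerow, neighbors overhang empty slots near the top wire
overhangSiteSpec <- function(...) {
    specWith(list(nRows = 4, rowLength = 15, interRow = 3.0,
        intraRow = 1.0, rowAzimuth = 90, missingFraction = 0.15,
        perVineSizeCV = 0.05, canopyLengthFrac = 1, terrainSlope = 0.02,
        terrainNoiseSd = 0.01, demDp = 0.01, pointDensity = 150,
        overhangFrac = 0.3, seed = 1L), ...)
}

gridFor <- function(truth, azimuth = truth@spec$rowAzimuth) {
    cfg <- siteConfig(interRow = truth@spec$interRow,
                      intraRow = truth@spec$intraRow, rowAzimuth = azimuth)
    buildGrid(rowAxes(truth), cfg)
}
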