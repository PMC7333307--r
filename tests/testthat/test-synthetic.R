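test_that("site generation is deterministic in the seed", {
    spec <- benchSiteSpec(seed = 7L)
    a <- generateSite(spec)
    b <- generateSite(spec)
    expect_identical(vineRecords(a), vineRecords(b))
    expect_identical(elevation(renderDem(a)), elevation(renderDem(b)))
    expect_identical(coords(renderCloud(a)), coords(renderCloud(b)))
    c <- generateSite(benchSiteSpec(seed = 8L))
    expect_false(identical(vineRecords(a)$present, vineRecords(c)$present))
})

test_that("missing-plant bookkeeping matches the Bernoulli model", {
    spec0 <- cleanSiteSpec(seed = 1L)
    expect_equal(nrow(missingPoints(generateSite(spec0))), 0L)

    # high missing probability, many seeds: total within 3 binomial SDs
    p <- 0.9
    tot <- 0L; trials <- 0L
    for (s in 1:100) {
        tr <- generateSite(cleanSiteSpec(missingFraction = p, seed = s))
        tot <- tot + sum(!vineRecords(tr)$present)
        trials <- trials + nrow(vineRecords(tr))
    }
    expect_lt(abs(tot - trials * p), 3 * sqrt(trials * p * (1 - p)))

    # the truth invariant: one missing point per absent vine
    tr <- generateSite(benchSiteSpec(seed = 5L))
    expect_equal(nrow(missingPoints(tr)), sum(!vineRecords(tr)$present))
    expect_true(all(vineRecords(tr)$trueVolume[vineRecords(tr)$present] > 0))
})

test_that("rendered cloud has the advertised geometry and density", {
    spec <- syntheticSiteSpec(nRows = 1, rowLength = 0.9, interRow = 2.5,
        intraRow = 0.9, rowAzimuth = 90, canopyHeight = 1.2,
        canopyThickness = 0.4, canopyLengthFrac = 1, missingFraction = 0,
        perVineSizeCV = 0, terrainSlope = 0, terrainNoiseSd = 0.01,
        pointDensity = 400, demDp = 0.01, seed = 2L)
    tr <- generateSite(spec)
    cl <- renderCloud(tr)
    z <- coords(cl)[, 3]
    ground <- tr@groundPlane[3]
    canopyZ <- z[z > ground + 0.5]
    expect_true(all(canopyZ >= ground + spec$cordonHeight - 3 * 0.01))
    expect_true(all(canopyZ <= ground + spec$cordonHeight +
                        spec$canopyHeight + 3 * 0.01))
    # vertical extent of the canopy ~ CH
    expect_lt(abs(diff(range(canopyZ)) - spec$canopyHeight), 3 * 0.01 * 2)

    # area bookkeeping: ground bbox + slab faces sampled at pointDensity
    frame <- vinecanopy:::siteFrame(spec)
    areaGround <- prod(frame$bbox[2, ] - frame$bbox[1, ])
    CL <- 0.9; CT <- 0.4; CH <- 1.2
    areaCanopy <- CL * CT + 2 * CL * CH + 2 * CT * CH
    expected <- spec$pointDensity * (areaGround + areaCanopy)
    expect_lt(abs(nPoints(cl) - expected) / expected, 0.1)
})

test_that("rendered DEM has surface-model semantics", {
    spec <- cleanSiteSpec(missingFraction = 0.3, seed = 13L,
                          terrainSlope = 0.04)
    tr <- generateSite(spec)
    dem <- renderDem(tr)
    rec <- vineRecords(tr)
    lookup <- function(x, y) {
        o <- rasterOrigin(dem)
        elevation(dem)[ceiling((o[2] - y) / pixelSize(dem)),
                       ceiling((x - o[1]) / pixelSize(dem))]
    }
    gz <- function(x, y) unname(tr@groundPlane[3] + tr@groundPlane[1] * x +
        tr@groundPlane[2] * y)
    # pixel-center vs vine-position offset contributes <= slope * dp
    tolM <- 0.04 * pixelSize(dem) + 1e-9
    pres <- rec[rec$present, ][1, ]
    expect_lt(abs(lookup(pres$x, pres$y) -
                  (gz(pres$x, pres$y) + 0.8 + pres$CH)), tolM)
    abs1 <- rec[!rec$present, ][1, ]
    expect_lt(abs(lookup(abs1$x, abs1$y) - gz(abs1$x, abs1$y)), tolM)
    # mid inter-row: offset across the row from a vine
    expect_lt(abs(lookup(pres$x, pres$y - 1.25) -
                  gz(pres$x, pres$y - 1.25)), tolM)
})

test_that("DEM and cloud are mutually consistent surfaces", {
    spec <- cleanSiteSpec(seed = 4L, terrainNoiseSd = 0.005,
                          pointDensity = 600)
    tr <- generateSite(spec)
    dem <- renderDem(tr)
    cl <- renderCloud(tr)
    # rasterise the cloud's upper envelope at a coarse pitch and compare
    pitch <- 0.1
    xy <- coords(cl)
    o <- rasterOrigin(dem)
    cx <- floor((xy[, 1] - o[1]) / pitch)
    cy <- floor((o[2] - xy[, 2]) / pitch)
    env <- tapply(xy[, 3], paste(cy, cx), max)
    # matching DEM maxima on the same coarse grid
    d <- elevation(dem)
    px <- demPix <- pixelSize(dem)
    colBlock <- floor(((col(d) - 0.5) * px) / pitch)
    rowBlock <- floor(((row(d) - 0.5) * px) / pitch)
    demEnv <- tapply(d, paste(rowBlock, colBlock), max)
    common <- intersect(names(env), names(demEnv))
    dif <- env[common] - demEnv[common]
    # envelopes agree to a few noise SDs over nearly all blocks
    expect_gt(mean(abs(dif) < 6 * spec$terrainNoiseSd + 0.02), 0.97)
})
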