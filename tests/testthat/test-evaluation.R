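test_that("volume regression reports slope, R2 and agreement RMSE", {
    r <- volumeRegression(c(1, 2, 3), c(1, 2, 3))
    expect_equal(r$rSquared, 1)
    expect_equal(r$rmse, 0)
    r2 <- volumeRegression(c(1, 2, 3), c(2, 4, 6))
    expect_equal(r2$rSquared, 1)
    expect_equal(r2$rmse, sqrt(14 / 3))
    expect_equal(r2$slope, 2)
    rr <- volumeRegression(c(1, 2, 3), c(2, 4, 6), rmseType = "residual")
    expect_equal(rr$rmse, 0, tolerance = 1e-12)
    expect_error(volumeRegression(c(1, 2, 3), c(2, 2, 2)), "variance")
    expect_error(volumeRegression(1:2, 1:2), "at least 3")
})

test_that("accuracy percentages reproduce the site arithmetic", {
    expect_equal(accuracyPercent(446, 521), -14.40)
    expect_equal(accuracyPercent(553, 521), 6.14)
    expect_equal(accuracyPercent(100, 100), 0)
    expect_error(accuracyPercent(5, 0), "positive")
    expect_equal(pctOfPotential(521, 3111), 16.75)
    expect_equal(pctOfPotential(1931, 6233), 30.98)
    expect_equal(pctOfPotential(0, 100), 0)
    expect_error(pctOfPotential(1, 0), "positive")
})

test_that("mean canopy volume per vine uses detected plants", {
    expect_equal(meanCanopyVolumePerVine(100, 300, 50), 0.4)
    expect_equal(meanCanopyVolumePerVine(0, 10, 2), 0)
    expect_error(meanCanopyVolumePerVine(10, 5, 5), "detected")
})

test_that("per-vine volume recovered on a synthetic site is within 10%", {
    spec <- cleanSiteSpec(missingFraction = 0.2, seed = 17L)
    tr <- generateSite(spec)
    m <- runMethod25D(renderDem(tr), gridFor(tr))
    total <- sum(m$vP * (m$nSlots - m$nExt))
    slots <- sum(m$nSlots)
    rec <- meanCanopyVolumePerVine(total, slots, sum(m$nExt))
    truth <- mean(vineRecords(tr)$trueVolume[vineRecords(tr)$present])
    expect_lt(abs(rec - truth) / truth, 0.1)
})

test_that("ground-truth matching is conservative and exact for a perfect detector", {
    spec <- cleanSiteSpec(missingFraction = 0.25, seed = 19L)
    tr <- generateSite(spec)
    grid <- gridFor(tr)
    m <- runMethod25D(renderDem(tr), grid)
    gt <- matchGroundTruth(m, missingPoints(tr), grid)
    expect_true(all(gt$perCell$error == 0L))
    expect_equal(gt$accuracyPct, 0)
    # a null detector under-counts by the whole truth
    m0 <- m; m0$nMissing <- 0L
    gt0 <- matchGroundTruth(m0, missingPoints(tr), grid)
    expect_equal(gt0$estimatedTotal, 0L)
    expect_equal(gt0$observedTotal + gt0$unassigned,
                 nrow(missingPoints(tr)))
    expect_equal(gt0$cellsUnder, sum(gt0$perCell$observed > 0))
})

test_that("hollow ellipsoid canopies reproduce the 2.5D over 3D volume bias", {
    spec <- syntheticSiteSpec(nRows = 2, rowLength = 8.1, interRow = 2.5,
        intraRow = 0.9, rowAzimuth = 90, missingFraction = 0,
        perVineSizeCV = 0.05, terrainSlope = 0.02, terrainNoiseSd = 0.01,
        demDp = 0.01, pointDensity = 250, canopyShape = "ellipsoid",
        seed = 23L)
    tr <- generateSite(spec)
    grid <- gridFor(tr)
    m25 <- suppressWarnings(runMethod25D(renderDem(tr), grid))
    m3 <- suppressWarnings(suppressMessages(
        runMethod3D(renderCloud(tr), grid)))
    both <- merge(m25[, c("cellId", "vDem")],
                  m3[, c("cellId", "volume")], by = "cellId")
    expect_true(all(both$vDem >= both$volume))
})
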