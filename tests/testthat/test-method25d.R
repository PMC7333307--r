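test_that("terrain normalisation flattens slopes and preserves canopy height", {
    # constant DEM -> all ~0
    flat <- DemRaster(matrix(50, 80, 80), dp = 0.01)
    expect_lt(max(abs(elevation(mitigateSlope(flat)))), 1e-12)

    # bare tilted plane: residual bounded by slope x (radius + dp)
    slope <- 0.05; dp <- 0.01
    z <- outer(rep(1, 120), seq_len(150)) * slope * dp + 50
    ramp <- DemRaster(z, dp = dp)
    h <- elevation(mitigateSlope(ramp, seRadiusM = 0.5))
    expect_lte(max(h), slope * (0.5 + dp) + 1e-9)

    # slab canopy on a 5% slope: canopy pixels ~ cordon + CH above ground
    # (residual bound slope x radius, so a 0.3 m disc keeps it under 2 cm)
    spec <- cleanSiteSpec(terrainSlope = 0.05, seed = 6L)
    tr <- generateSite(spec)
    hh <- elevation(mitigateSlope(renderDem(tr), seRadiusM = 0.3))
    canopy <- hh[hh > 1]
    expect_lt(max(abs(canopy - 2.0)), 0.02)
})

test_that("mitigateSlope warns when the disc cannot clear the canopy", {
    dem <- DemRaster(matrix(50, 40, 40), dp = 0.01)
    expect_warning(mitigateSlope(dem, seRadiusM = 0.2,
                                 expectedCanopyWidthM = 0.4), "canopy")
})

test_that("Otsu binarisation separates bimodal grids and is symmetric", {
    m <- matrix(c(rep(0, 50), rep(2, 50)), 10, 10)
    dem <- DemRaster(m + 50, dp = 0.01)
    msk <- binarizeOtsu(dem)
    expect_true(all(msk@mask[m == 2] == 0))   # high -> vine/black
    expect_true(all(msk@mask[m == 0] == 1))   # low -> soil/white

    # inverting heights swaps the classes exactly
    inv <- DemRaster(50 + max(m) - m, dp = 0.01)
    mskInv <- binarizeOtsu(inv)
    expect_identical(mskInv@mask, 1 - msk@mask)

    expect_error(binarizeOtsu(DemRaster(matrix(5, 4, 4), dp = 1)),
                 "degenerate")
})

test_that("Otsu threshold equals the brute-force within-class minimiser", {
    set.seed(42)
    for (k in 1:5) {
        g <- c(rnorm(300, 0.25, 0.08), rnorm(120, 0.8, 0.05))
        g <- pmin(pmax(g, 0), 1)
        expect_equal(otsuThreshold(g), bruteOtsu(g), tolerance = 1e-12)
    }
})

test_that("the vine-row angle is recovered from the mask principal axis", {
    mk <- function(m) new("VineMask", mask = m, dp = 0.01, theta = NA_real_,
                          threshold = 0.5)
    horiz <- matrix(1, 60, 60); horiz[28:32, ] <- 0
    expect_equal(estimateTheta(mk(horiz)), 0, tolerance = 1e-6)

    # band rotated 30 degrees (in image coords the angle is signed; its
    # magnitude is what the thickness correction uses)
    n <- 200
    m <- matrix(1, n, n)
    for (cc in seq_len(n)) {
        r <- round(n / 2 - tan(pi / 6) * (cc - n / 2)) + seq(-3, 3)
        r <- r[r >= 1 & r <= n]
        m[r, cc] <- 0
    }
    expect_lt(abs(abs(estimateTheta(mk(m))) - pi / 6), 0.5 * pi / 180)

    single <- matrix(1, 30, 30); single[5:25, 7] <- 0
    expect_warning(th <- estimateTheta(mk(single)), "single column")
    expect_equal(th, 0)
    expect_error(estimateTheta(mk(matrix(1, 5, 5))), "fewer than 2")
})

test_that("thickness profiles follow the pixel count and angle", {
    m <- matrix(1, 40, 30); m[11:20, ] <- 0      # band 10 px thick
    mk <- new("VineMask", mask = m, dp = 0.005, theta = NA_real_,
              threshold = 0.5)
    p0 <- thicknessProfile(mk, theta = 0)
    expect_equal(p0$deltaP, rep(10 * 0.005, 30))
    p60 <- thicknessProfile(mk, theta = pi / 3)
    expect_equal(p60$deltaP, rep(0.05 * 0.5, 30))  # cos 60 = 0.5
    empty <- new("VineMask", mask = matrix(1, 10, 10), dp = 0.005,
                 theta = NA_real_, threshold = 0.5)
    expect_equal(thicknessProfile(empty, theta = 0)$deltaP, rep(0, 10))
})

test_that("gap detection counts missing plants from sub-threshold runs", {
    dp <- 0.01
    mkProf <- function(deltaP) list(delta = deltaP / dp, deltaP = deltaP,
                                    dp = dp, theta = 0)
    # fully empty 2.7 m cell
    g <- detectGaps(mkProf(rep(0, 270)), lp = 0.9)
    expect_equal(g$Lv, 2.7)
    expect_equal(g$Next, 3L)
    # one 0.9 m sub-threshold run amid 0.4 m canopy
    prof <- mkProf(c(rep(0.4, 90), rep(0.05, 90), rep(0.4, 90)))
    g2 <- detectGaps(prof, lp = 0.9)
    expect_equal(g2$Next, 1L)
    expect_equal(nrow(g2$segments), 1L)
    expect_equal(unname(g2$segments[1, ]), c(0.9, 1.8))
    # continuous canopy
    expect_equal(detectGaps(mkProf(rep(0.4, 270)), lp = 0.9)$Next, 0L)
    # speckle shorter than bridgePx is bridged
    spik <- rep(0.4, 270); spik[100:101] <- 0
    expect_equal(detectGaps(mkProf(spik), lp = 0.9)$Lv, 0)
    # raising the threshold never decreases Lv
    set.seed(1)
    rnd <- mkProf(runif(270, 0, 0.5))
    lvs <- vapply(c(0.05, 0.1, 0.2, 0.4),
                  function(t) detectGaps(rnd, 0.9, threshold = t)$Lv,
                  numeric(1))
    expect_true(all(diff(lvs) >= 0))
})

test_that("mean thickness excludes sub-threshold columns", {
    prof <- function(v) list(delta = v / 0.01, deltaP = v, dp = 0.01,
                             theta = 0)
    expect_equal(meanThickness(prof(rep(0.4, 10))), 0.4)
    expect_equal(meanThickness(prof(c(rep(0.4, 5), rep(0.05, 5)))), 0.4)
    expect_equal(meanThickness(prof(c(0.2, 0.3, 0.4))), 0.3)
    expect_equal(meanThickness(prof(rep(0.01, 5))), 0)
})

test_that("canopy height uses elevation quartiles minus the cordon", {
    # constant profiles: vines at 2.0, soil at 0.0
    el <- matrix(0, 40, 20); el[11:20, ] <- 2
    msk <- matrix(1, 40, 20); msk[11:20, ] <- 0
    dem <- DemRaster(el + 100, dp = 0.01)
    mk <- new("VineMask", mask = msk, dp = 0.01, theta = 0,
              threshold = 0.5)
    expect_equal(cellHeight(dem, mk, cordon = 0.8), 1.2)

    # quartile oracle on a 4-value vine profile {1.9, 2.0, 2.1, 2.2}
    el2 <- matrix(0, 8, 10)
    el2[1:4, ] <- c(1.9, 2.0, 2.1, 2.2)   # one vine row per image row
    msk2 <- matrix(1, 8, 10); msk2[1:4, ] <- 0
    dem2 <- DemRaster(el2 + 100, dp = 0.01)
    mk2 <- new("VineMask", mask = msk2, dp = 0.01, theta = 0,
               threshold = 0.5)
    q1 <- as.numeric(quantile(c(1.9, 2.0, 2.1, 2.2), 0.25, type = 7))
    expect_equal(cellHeight(dem2, mk2, cordon = 0.8), q1 - 0 - 0.8)

    # soil above vines: clip to 0 with a warning
    el3 <- matrix(3, 8, 10); el3[1:4, ] <- 0.5
    msk3 <- matrix(1, 8, 10); msk3[1:4, ] <- 0
    expect_warning(
        dh <- cellHeight(DemRaster(el3 + 100, dp = 0.01), mk2, 0.8),
        "clipped")
    expect_equal(dh, 0)
    expect_error(cellHeight(dem2, new("VineMask",
        mask = matrix(0, 8, 10), dp = 0.01, theta = 0, threshold = 0.5)),
        "soil")
})

test_that("cuboid volumes follow their closed forms and monotonicity", {
    v <- volumes25d(dh = 1.0, deltaM = 0.5, nPx = 100, dp = 0.01,
                    theta = 0, dL = 0.9)
    expect_equal(v$vP, 0.45)
    v2 <- volumes25d(dh = 1.3, deltaM = 0.4, nPx = 40000, dp = 0.005,
                     theta = 0, dL = 0.9)
    expect_equal(v2$dA, 1.0)
    expect_equal(v2$vDem, 1.3)
    # the cuboid ground-measurement model itself
    expect_equal(1.2 * 0.4 * 0.9, 0.432)
    # adding vine pixels never decreases dA or Vdem
    seqA <- vapply(seq(0, 5000, by = 500), function(n)
        volumes25d(1, 0.4, n, 0.005, 0.3, 0.9)$vDem, numeric(1))
    expect_true(all(diff(seqA) >= 0))
})

test_that("the full 2.5D pipeline recovers slab volumes and gaps exactly", {
    spec <- cleanSiteSpec(seed = 3L)
    tr <- generateSite(spec)
    m <- runMethod25D(renderDem(tr), gridFor(tr))
    expect_true(all(abs(m$vP - 0.432) / 0.432 < 0.03))
    expect_true(all(m$nExt == 0L))
    expect_true(all(abs(m$dh - 1.2) < 0.02))
    expect_true(all(abs(m$deltaM - 0.4) < 0.02))
})

test_that("2.5D results are invariant to a 15-degree site rotation", {
    run <- function(az) {
        tr <- generateSite(cleanSiteSpec(rowAzimuth = az, seed = 5L))
        colMeans(runMethod25D(renderDem(tr),
                              gridFor(tr))[, c("deltaM", "dh", "vP")])
    }
    a <- run(90); b <- run(75)
    expect_true(all(abs(b - a) / a < 0.02))
})
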