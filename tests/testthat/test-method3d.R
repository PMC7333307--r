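test_that("ground-plane fitting separates a clean slab world exactly", {
    set.seed(10)
    nG <- 600
    ground <- cbind(runif(nG, 0, 5), runif(nG, 0, 5), 0)
    canopy <- cbind(runif(250, 1, 4), runif(250, 2, 2.4),
                    runif(250, 0.8, 2.0))
    cl <- PointCloud3D(rbind(ground, canopy))
    f <- fitGroundPlane(cl)
    expect_lt(abs(f$plane@offset), 1e-6)
    expect_equal(sort(f$inliers), seq_len(nG))
})

test_that("a gently tilted noisy ground is recovered within 0.3 degrees", {
    set.seed(11)
    n <- 6000
    x <- runif(n, 0, 12); y <- runif(n, 0, 12)
    for (dipDeg in c(1, 3, 5)) {
        z <- 40 + tan(dipDeg * pi / 180) * x + rnorm(n, 0, 0.01)
        f <- fitGroundPlane(PointCloud3D(cbind(x, y, z)))
        dip <- acos(f$plane@normal[3]) * 180 / pi
        expect_lt(abs(dip - dipDeg), 0.3)
    }
})

test_that("terrain steeper than the angular constraint is rejected", {
    set.seed(12)
    n <- 3000
    x <- runif(n, 0, 12); y <- runif(n, 0, 12)
    z <- 40 + tan(10 * pi / 180) * x + rnorm(n, 0, 0.01)
    expect_error(fitGroundPlane(PointCloud3D(cbind(x, y, z))),
                 "no admissible ground plane")
    expect_error(fitGroundPlane(PointCloud3D(matrix(runif(6), 2, 3))),
                 "at least 3")
})

test_that("ground/canopy split keeps the generator's own labels", {
    spec <- cleanSiteSpec(nRows = 1, rowLength = 2.7, seed = 14L,
                          terrainNoiseSd = 0.005, pointDensity = 300)
    tr <- generateSite(spec)
    cl <- renderCloud(tr)
    f <- fitGroundPlane(cl)
    sp <- splitGroundCanopy(cl, f$plane, f$inliers)
    # canopy points are those the generator placed on slab faces (z >=
    # cordon above ground); boundary ambiguity only at the noise scale
    zs <- coords(cl)[, 3] - tr@groundPlane[3]
    nTrueCanopy <- sum(zs > 0.4)
    expect_lt(abs(nPoints(sp$canopy) - nTrueCanopy) / nTrueCanopy, 0.02)

    # all points on the plane: canopy empty, ground = all
    flat <- PointCloud3D(cbind(runif(50), runif(50), 0))
    ff <- fitGroundPlane(flat)
    expect_warning(spf <- splitGroundCanopy(flat, ff$plane, ff$inliers),
                   "empty")
    expect_equal(nPoints(spf$ground), 50L)
    expect_equal(nPoints(spf$canopy), 0L)
})

test_that("cell clipping is half-open and conservative", {
    cfg <- siteConfig(2.5, 0.9)
    rows <- data.frame(rowId = 1, x0 = 0, y0 = 0, x1 = 5.4, y1 = 0)
    grid <- buildGrid(rows, cfg)          # two cells split at x = 2.7
    cl <- PointCloud3D(rbind(c(2.7, 0, 1),      # on the shared edge
                             c(1.0, 0.5, 1), c(4.0, -1.0, 1),
                             c(9.9, 0, 1)))     # outside
    c1 <- clipCell(cl, grid, 1L)
    c2 <- clipCell(cl, grid, 2L)
    expect_equal(nPoints(c1), 1L)
    expect_equal(nPoints(c2), 2L)          # edge point goes to...
    expect_true(any(coords(c2)[, 1] == 2.7))   # ...the cell owning [2.7, 5.4)
    expect_lte(nPoints(c1) + nPoints(c2), nPoints(cl))
    far <- buildGrid(data.frame(rowId = 1, x0 = 100, y0 = 0, x1 = 105.4,
                                y1 = 0), cfg)
    expect_equal(nPoints(clipCell(cl, far, 1L)), 0L)
})

test_that("alpha-shape volume matches closed forms and the alpha limits", {
    e <- 0.2
    tet <- rbind(c(0, 0, 0), c(e, 0, 0), c(e / 2, e * sqrt(3) / 2, 0),
                 c(e / 2, e * sqrt(3) / 6, e * sqrt(2 / 3)))
    circumR <- e * sqrt(3 / 8)
    expect_equal(alphashapeVolume(tet, alpha = circumR + 1e-9),
                 e^3 / (6 * sqrt(2)), tolerance = 1e-12)
    expect_equal(alphashapeVolume(tet, alpha = 1e-6), 0)
    expect_equal(alphashapeVolume(tet[1:3, ], alpha = 1), 0)  # < 4 points
    expect_warning(v <- alphashapeVolume(cbind(runif(30), runif(30), 0), 1),
                   "degenerate")
    expect_equal(v, 0)

    # monotone in alpha; convex hull at alpha = Inf
    set.seed(20)
    pts <- matrix(runif(120, 0, 1.5), ncol = 3)
    vols <- vapply(c(0.1, 0.25, 0.5, 1, Inf),
                   function(a) alphashapeVolume(pts, a), numeric(1))
    expect_true(all(diff(vols) >= 0))
    # hull oracle: cube corners + interior points have hull volume 1
    set.seed(21)
    cubeish <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
                     matrix(runif(90), ncol = 3))
    expect_equal(alphashapeVolume(cubeish, Inf), 1, tolerance = 1e-6)
})

test_that("alpha-shape volume equals the brute-force Delaunay oracle", {
    set.seed(22)
    for (k in 1:8) {
        n <- sample(8:30, 1)
        pts <- matrix(runif(3 * n, 0, 2), ncol = 3)
        a <- sample(c(0.4, 0.7, 1.5, Inf), 1)
        expect_equal(alphashapeVolume(pts, a), bruteAlphaVolume(pts, a),
                     tolerance = 1e-9)
    }
})

test_that("average vine volume divides reference-cell means by the slots", {
    av <- averageVineVolume(c(1.2, 0.9, 1.5), 1:3)
    expect_equal(av$vBar, 0.4)
    expect_equal(av$nReferenceCells, 3L)
    expect_equal(averageVineVolume(0.93, 1)$vBar, 0.31)
    expect_equal(averageVineVolume(rep(0.6, 5), 1:5)$vBar, 0.2)
    expect_error(averageVineVolume(c(1, 2), integer()), "vBar")
})

test_that("volume deficits convert to missing-plant counts", {
    vb <- 0.4
    expect_equal(missingPlants3D(1.8 * vb, vb), 1L)
    expect_equal(missingPlants3D(0, vb), 3L)
    expect_equal(missingPlants3D(3.2 * vb, vb), 0L)
    expect_equal(missingPlants3D(2.2 * vb, vb), 1L)
    expect_equal(missingPlants3D(2.2 * vb, vb, rounding = "ceiling"), 0L)
    expect_equal(missingPlants3D(1.9 * vb, vb, rounding = "ceiling"), 1L)
    expect_error(missingPlants3D(1, 0), "positive")
})

test_that("row volume maps are ordered projections conserving volume", {
    cfg <- siteConfig(2.5, 0.9)
    rows <- data.frame(rowId = 1, x0 = 0, y0 = 0, x1 = 27, y1 = 0)
    grid <- buildGrid(rows, cfg)
    met <- data.frame(cellId = rev(cells(grid)$cellId), volume = 2)
    rv <- rowVolumeMap(met, grid)
    expect_equal(rv$volume, rep(2, 10))
    expect_equal(rv$alongMid, seq(1.35, by = 2.7, length.out = 10))
    expect_equal(sum(rv$volume), sum(met$volume))
})
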