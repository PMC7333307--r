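test_that("cells take the paper geometry of both spacings", {
    rows <- data.frame(rowId = 1, x0 = 0, y0 = 0, x1 = 27, y1 = 0)
    g1 <- buildGrid(rows, siteConfig(interRow = 2.5, intraRow = 0.9))
    cc <- cells(g1)
    expect_equal(nrow(cc), 10L)                       # 27 m / 2.7 m
    expect_true(all(abs((cc$a1 - cc$a0) - 2.7) < 1e-9))
    expect_equal(unique(2 * cc$halfWidth), 2.5)

    rows2 <- data.frame(rowId = 1, x0 = 0, y0 = 0, x1 = 30, y1 = 0)
    g2 <- buildGrid(rows2, siteConfig(interRow = 3.0, intraRow = 1.0))
    expect_true(all(abs((cells(g2)$a1 - cells(g2)$a0) - 3) < 1e-9))
    expect_equal(unique(2 * cells(g2)$halfWidth), 3)
})

test_that("partial terminal cells are dropped unless kept with prorated slots", {
    rows <- data.frame(rowId = 1, x0 = 0, y0 = 0, x1 = 8.0, y1 = 0)
    cfg <- siteConfig(interRow = 2.5, intraRow = 0.9)
    expect_equal(nrow(cells(buildGrid(rows, cfg))), 2L)   # 8 m = 2 full + 2.6
    gp <- buildGrid(rows, cfg, keepPartial = TRUE)
    expect_equal(nrow(cells(gp)), 3L)
    expect_equal(cells(gp)$nSlots, c(3L, 3L, 2L))         # 2.6 m -> 2 slots
})

test_that("non-parallel rows are rejected", {
    rows <- data.frame(rowId = 1:2, x0 = 0, y0 = c(0, 2.5),
                       x1 = c(10, 9.8), y1 = c(0, 4.0))
    expect_error(buildGrid(rows, siteConfig(2.5, 0.9)), "parallel")
})

test_that("every synthetic vine lands in exactly one cell", {
    tr <- generateSite(benchSiteSpec(seed = 9L))
    grid <- gridFor(tr)
    rec <- vineRecords(tr)
    idx <- vinecanopy:::assignToCells(cbind(rec$x, rec$y), grid)
    covered <- rec$along < max(cells(grid)$a1)    # inside the tiled extent
    expect_true(all(!is.na(idx[covered])))
    # counts per cell match slot arithmetic: 3 per full cell
    expect_true(all(table(idx) == 3L))
})

test_that("grid construction is equivariant under rigid rotation", {
    cfg0 <- siteConfig(2.5, 0.9, rowAzimuth = 90)
    rows0 <- data.frame(rowId = 1:2, x0 = 0, y0 = c(0, 2.5),
                        x1 = 10.8, y1 = c(0, 2.5))
    phi <- 25 * pi / 180
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    rot <- function(x, y) cbind(x, y) %*% t(R)
    se <- rot(rows0$x0, rows0$y0); ee <- rot(rows0$x1, rows0$y1)
    rows1 <- data.frame(rowId = 1:2, x0 = se[, 1], y0 = se[, 2],
                        x1 = ee[, 1], y1 = ee[, 2])
    g0 <- buildGrid(rows0, cfg0)
    g1 <- buildGrid(rows1, cfg0)
    expect_equal(cells(g1)$a0, cells(g0)$a0)
    expect_equal(cells(g1)$halfWidth, cells(g0)$halfWidth)
    ctr0 <- rot(cells(g0)$cx, cells(g0)$cy)
    expect_equal(cbind(cells(g1)$cx, cells(g1)$cy), ctr0,
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("potential plant counts follow density x surface", {
    expect_identical(potentialPlants(4444, 0.7), 3111L)
    expect_identical(potentialPlants(1000, 1.0), 1000L)
    expect_identical(potentialPlants(3333, 1.9), 6333L)
    expect_error(potentialPlants(0, 1), "positive")
    expect_error(potentialPlants(1000, -1), "positive")
})

test_that("inconsistent density and spacing warn at construction", {
    expect_warning(siteConfig(2.5, 0.9, densityPerHa = 3000), "disagrees")
    expect_silent(siteConfig(2.5, 0.9, densityPerHa = 4444))
})
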