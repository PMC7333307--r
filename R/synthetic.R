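#' Parameters of a synthetic vineyard
#'
#' Builds the validated parameter list the generator consumes.  Defaults
#' follow the geometry of a cordon-trained vineyard flown at very high
#' resolution: 2.5 m x 0.9 m vine spacing, rows at 45 degrees (NE/SW), a
#' 0.8 m cordon with 1.2 m of canopy above it, 0.4 m canopy thickness, and
#' a 0.005 m/pixel DEM.  \code{missingFraction} is the independent
#' probability that a plant slot is empty; \code{perVineSizeCV} the
#' coefficient of variation of the per-vine canopy dimensions;
#' \code{canopyLengthFrac} the fraction of the intra-row slot each vine's
#' canopy occupies (1 gives the continuous hedgerow of shoot-wrapped
#' training).  \code{overhangFrac} > 0 makes the canopies of plants
#' adjacent to an empty slot overhang it near the top wire by that fraction
#' of the slot length (the "hidden gap" situation).
#'
#' @param nRows number of vine rows
#' @param rowLength row length (m)
#' @param interRow inter-row spacing (m)
#' @param intraRow intra-row plant spacing \eqn{\ell_p} (m)
#' @param rowAzimuth row direction, degrees clockwise from north
#' @param canopyHeight mean canopy height above the cordon, CH (m)
#' @param cordonHeight cordon height above ground (m)
#' @param canopyThickness mean canopy thickness, CT (m)
#' @param canopyLengthFrac fraction of \eqn{\ell_p} occupied per vine
#' @param missingFraction probability a plant slot is empty, in [0, 1)
#' @param perVineSizeCV CV of per-vine CH/CT/CL
#' @param terrainSlope terrain gradient (m/m), applied along world x
#' @param terrainNoiseSd sd of surface noise (m), terrain and canopy alike
#' @param pointDensity cloud sampling density on surfaces (points/m^2)
#' @param demDp DEM pixel size (m/pixel)
#' @param overhangFrac neighbor-canopy overhang into empty slots, as a
#'   fraction of \eqn{\ell_p} (per side), in [0, 0.5]
#' @param canopyShape "slab" (rectangular cuboid) or "ellipsoid"
#' @param hollow logical; sample canopy surfaces only (TRUE, as
#'   photogrammetry does) or fill the interior (FALSE)
#' @param seed integer seed; the whole site is a deterministic function of it
#' @return a named list of class-checked generator parameters
#' @examples
#' spec <- syntheticSiteSpec(nRows = 2, rowLength = 9, seed = 7)
#' @export
syntheticSiteSpec <- function(nRows = 6, rowLength = 27, interRow = 2.5,
                              intraRow = 0.9, rowAzimuth = 45,
                              canopyHeight = 1.2, cordonHeight = 0.8,
                              canopyThickness = 0.4, canopyLengthFrac = 0.9,
                              missingFraction = 0.15, perVineSizeCV = 0.08,
                              terrainSlope = 0.05, terrainNoiseSd = 0.01,
                              pointDensity = 500, demDp = 0.005,
                              overhangFrac = 0, canopyShape = "slab",
                              hollow = TRUE, seed = 1L) {
    spec <- list(nRows = as.integer(nRows), rowLength = rowLength,
                 interRow = interRow, intraRow = intraRow,
                 rowAzimuth = rowAzimuth, canopyHeight = canopyHeight,
                 cordonHeight = cordonHeight,
                 canopyThickness = canopyThickness,
                 canopyLengthFrac = canopyLengthFrac,
                 missingFraction = missingFraction,
                 perVineSizeCV = perVineSizeCV, terrainSlope = terrainSlope,
                 terrainNoiseSd = terrainNoiseSd, pointDensity = pointDensity,
                 demDp = demDp, overhangFrac = overhangFrac,
                 canopyShape = match.arg(canopyShape, c("slab", "ellipsoid")),
                 hollow = isTRUE(hollow), seed = as.integer(seed))
    lenFields <- c("rowLength", "interRow", "intraRow", "canopyHeight",
                   "cordonHeight", "canopyThickness", "canopyLengthFrac",
                   "pointDensity", "demDp")
    for (f in lenFields)
        if (!is.finite(spec[[f]]) || spec[[f]] <= 0)
            stop(f, " must be positive")
    if (spec$missingFraction < 0 || spec$missingFraction >= 1)
        stop("missingFraction must lie in [0, 1)")
    if (spec$overhangFrac < 0 || spec$overhangFrac > 0.5)
        stop("overhangFrac must lie in [0, 0.5]")
    if (spec$nRows < 1L) stop("nRows must be >= 1")
    spec
}

# along/across unit vectors for an azimuth (deg clockwise from north)
rowUnitVectors <- function(azimuthDeg) {
    a <- azimuthDeg * pi / 180
    list(u = c(sin(a), cos(a)),        # along row
         v = c(cos(a), -sin(a)))       # across, 90 deg clockwise
}

# site frame: row k start point; everything shifted so the bounding box
# (rows +- interRow/2 across, the full row length along) starts at (0, 0)
siteFrame <- function(spec) {
    uv <- rowUnitVectors(spec$rowAzimuth)
    starts0 <- t(vapply(seq_len(spec$nRows) - 1L,
                        function(k) k * spec$interRow * uv$v, numeric(2)))
    corners <- NULL
    for (k in seq_len(spec$nRows))
        for (s in c(0, spec$rowLength))
            for (t in c(-spec$interRow / 2, spec$interRow / 2))
                corners <- rbind(corners,
                                 starts0[k, ] + s * uv$u + t * uv$v)
    shift <- -apply(corners, 2, min)
    starts <- sweep(starts0, 2, shift, "+")
    bbox <- rbind(lo = c(0, 0), hi = apply(corners, 2, max) + shift)
    list(u = uv$u, v = uv$v, starts = starts, bbox = bbox)
}

#' Generate a synthetic vineyard layout with known ground truth
#'
#' Places plant slots at the intra-row spacing along parallel rows, drops
#' each vine independently with probability \code{missingFraction}, and
#' draws per-vine canopy dimensions around the spec means with the stated
#' CV (truncated at 20 per cent of the mean; CL is capped at the slot
#' length).  Deterministic given \code{spec$seed}.
#'
#' @param spec parameters from [syntheticSiteSpec()]
#' @return a \linkS4class{VineyardTruth}
#' @export
generateSite <- function(spec) {
    frame <- siteFrame(spec)
    nSlots <- floor(spec$rowLength / spec$intraRow + 1e-9)
    if (nSlots < 1L) stop("rowLength shorter than one plant slot")
    withSeed(spec$seed, {
        rec <- do.call(rbind, lapply(seq_len(spec$nRows), function(k) {
            slot <- seq_len(nSlots)
            along <- (slot - 0.5) * spec$intraRow
            n <- length(slot)
            draw <- function(mean) mean * pmax(0.2,
                1 + spec$perVineSizeCV * rnorm(n))
            data.frame(rowId = k, slot = slot, along = along,
                       x = frame$starts[k, 1] + along * frame$u[1],
                       y = frame$starts[k, 2] + along * frame$u[2],
                       present = runif(n) >= spec$missingFraction,
                       CH = draw(spec$canopyHeight),
                       CT = draw(spec$canopyThickness),
                       CL = pmin(spec$intraRow,
                                 draw(spec$canopyLengthFrac * spec$intraRow)))
        }))
    })
    rec$trueVolume <- ifelse(rec$present, rec$CH * rec$CT * rec$CL, 0)
    miss <- as.matrix(rec[!rec$present, c("x", "y")])
    colnames(miss) <- c("x", "y")
    rows <- data.frame(rowId = seq_len(spec$nRows),
                       x0 = frame$starts[, 1], y0 = frame$starts[, 2],
                       x1 = frame$starts[, 1] + spec$rowLength * frame$u[1],
                       y1 = frame$starts[, 2] + spec$rowLength * frame$u[2])
    # gentle terrain: gradient of magnitude terrainSlope along world x
    plane <- c(sx = spec$terrainSlope, sy = 0, z0 = 50)
    new("VineyardTruth", vineRecords = rec, missingPoints = miss,
        rows = rows, groundPlane = plane, seed = spec$seed, spec = spec)
}

groundZ <- function(truth, x, y)
    truth@groundPlane[3] + truth@groundPlane[1] * x + truth@groundPlane[2] * y

# overhang flaps into empty slots: for each absent slot with a present
# neighbor, a flap of the neighbor's canopy (full CT wide, flapDepth thick
# at the top of the canopy) extends overhangFrac * lp into the slot.
# Returns data.frame of flaps (rowId, alongStart, alongEnd, CT, CH).
overhangFlaps <- function(truth) {
    spec <- truth@spec
    if (spec$overhangFrac <= 0) return(NULL)
    rec <- truth@vineRecords
    lp <- spec$intraRow
    out <- NULL
    for (k in unique(rec$rowId)) {
        rk <- rec[rec$rowId == k, ]
        rk <- rk[order(rk$slot), ]
        for (i in which(!rk$present)) {
            lo <- (rk$slot[i] - 1) * lp
            hi <- rk$slot[i] * lp
            if (i > 1 && rk$present[i - 1])
                out <- rbind(out, data.frame(rowId = k, alongStart = lo,
                    alongEnd = lo + spec$overhangFrac * lp,
                    CT = rk$CT[i - 1], CH = rk$CH[i - 1]))
            if (i < nrow(rk) && rk$present[i + 1])
                out <- rbind(out, data.frame(rowId = k,
                    alongStart = hi - spec$overhangFrac * lp, alongEnd = hi,
                    CT = rk$CT[i + 1], CH = rk$CH[i + 1]))
        }
    }
    out
}

#' Render the DEM of a synthetic vineyard
#'
#' Surface-model semantics: each pixel carries the elevation of the highest
#' surface above it — the canopy top over present vines, bare terrain
#' elsewhere — plus Gaussian noise of sd \code{terrainNoiseSd}.  The canopy
#' top over a slab vine is flat at (local ground + cordon + CH); in
#' ellipsoid mode it follows the upper half of the ellipsoid with semi-axes
#' (CL/2, CT/2, CH/2) resting on the cordon.
#'
#' @param truth a \linkS4class{VineyardTruth}
#' @param spec the generating spec (defaults to the one stored in truth)
#' @return a \linkS4class{DemRaster}
#' @export
renderDem <- function(truth, spec = truth@spec) {
    frame <- siteFrame(spec)
    dp <- spec$demDp
    nc <- ceiling((frame$bbox[2, 1] - frame$bbox[1, 1]) / dp)
    nr <- ceiling((frame$bbox[2, 2] - frame$bbox[1, 2]) / dp)
    xs <- (seq_len(nc) - 0.5) * dp
    ys <- frame$bbox[2, 2] - (seq_len(nr) - 0.5) * dp   # north-up rows
    X <- matrix(xs, nr, nc, byrow = TRUE)
    Y <- matrix(ys, nr, nc)
    Z <- groundZ(truth, X, Y)

    rec <- truth@vineRecords
    flaps <- overhangFlaps(truth)
    for (k in seq_len(spec$nRows)) {
        p0 <- frame$starts[k, ]
        s <- (X - p0[1]) * frame$u[1] + (Y - p0[2]) * frame$u[2]
        t <- (X - p0[1]) * frame$v[1] + (Y - p0[2]) * frame$v[2]
        rk <- rec[rec$rowId == k & rec$present, ]
        for (i in seq_len(nrow(rk))) {
            ds <- s - rk$along[i]
            if (spec$canopyShape == "slab") {
                sel <- abs(ds) <= rk$CL[i] / 2 & abs(t) <= rk$CT[i] / 2
                if (any(sel))
                    Z[sel] <- pmax(Z[sel], groundZ(truth, X[sel], Y[sel]) +
                                   spec$cordonHeight + rk$CH[i])
            } else {
                q <- 1 - (2 * ds / rk$CL[i])^2 - (2 * t / rk$CT[i])^2
                sel <- q > 0
                if (any(sel))
                    Z[sel] <- pmax(Z[sel], groundZ(truth, X[sel], Y[sel]) +
                                   spec$cordonHeight +
                                   rk$CH[i] / 2 * (1 + sqrt(q[sel])))
            }
        }
        if (!is.null(flaps)) {
            fk <- flaps[flaps$rowId == k, ]
            for (i in seq_len(nrow(fk))) {
                sel <- s >= fk$alongStart[i] & s < fk$alongEnd[i] &
                    abs(t) <= fk$CT[i] / 2
                if (any(sel))
                    Z[sel] <- pmax(Z[sel], groundZ(truth, X[sel], Y[sel]) +
                                   spec$cordonHeight + fk$CH[i])
            }
        }
    }
    if (spec$terrainNoiseSd > 0)
        Z <- withSeed(spec$seed + 1L,
                      Z + matrix(rnorm(length(Z), 0, spec$terrainNoiseSd),
                                 nrow(Z)))
    DemRaster(Z, dp = dp, origin = c(0, frame$bbox[2, 2]))
}

# uniform samples on a rectangle embedded in 3D, given two in-plane extents
# and a mapping closure; helper for renderCloud
sampleFace <- function(n, w1, w2) cbind(runif(n, -w1 / 2, w1 / 2),
                                        runif(n, -w2 / 2, w2 / 2))

#' Render the dense point cloud of a synthetic vineyard
#'
#' Terrain is sampled uniformly over the site footprint at
#' \code{pointDensity} points/m^2 on the (noisy) ground plane.  Each
#' present vine contributes surface samples of its canopy at the same
#' density: for slabs, the top face, both long side faces and both end
#' faces (no bottom face — airborne photogrammetry never sees it); with
#' \code{hollow = FALSE} the same number of points is drawn uniformly from
#' the slab interior instead.  Gaussian noise of sd \code{terrainNoiseSd}
#' is added to every coordinate.  Deterministic given \code{spec$seed}.
#'
#' @inheritParams renderDem
#' @return a \linkS4class{PointCloud3D}
#' @export
renderCloud <- function(truth, spec = truth@spec) {
    frame <- siteFrame(spec)
    withSeed(spec$seed + 2L, {
        area <- prod(frame$bbox[2, ] - frame$bbox[1, ])
        nG <- round(area * spec$pointDensity)
        gx <- runif(nG, frame$bbox[1, 1], frame$bbox[2, 1])
        gy <- runif(nG, frame$bbox[1, 2], frame$bbox[2, 2])
        pts <- cbind(gx, gy, groundZ(truth, gx, gy))

        rec <- truth@vineRecords
        rec <- rec[rec$present, ]
        for (i in seq_len(nrow(rec))) {
            k <- rec$rowId[i]
            p0 <- frame$starts[k, ]
            center <- c(rec$x[i], rec$y[i])
            CL <- rec$CL[i]; CT <- rec$CT[i]; CH <- rec$CH[i]
            toWorld <- function(ds, dt, h) {
                x <- center[1] + ds * frame$u[1] + dt * frame$v[1]
                y <- center[2] + ds * frame$u[2] + dt * frame$v[2]
                cbind(x, y, groundZ(truth, x, y) + spec$cordonHeight + h)
            }
            if (!spec$hollow) {
                nn <- round(spec$pointDensity *
                            (CL * CT + 2 * CL * CH + 2 * CT * CH))
                pts <- rbind(pts, toWorld(runif(nn, -CL / 2, CL / 2),
                                          runif(nn, -CT / 2, CT / 2),
                                          runif(nn, 0, CH)))
            } else if (spec$canopyShape == "slab") {
                nTop <- round(spec$pointDensity * CL * CT)
                f <- sampleFace(nTop, CL, CT)
                pts <- rbind(pts, toWorld(f[, 1], f[, 2], rep(CH, nTop)))
                nSide <- round(spec$pointDensity * CL * CH)
                for (sgn in c(-1, 1)) {
                    f <- sampleFace(nSide, CL, CH)
                    pts <- rbind(pts, toWorld(f[, 1], rep(sgn * CT / 2, nSide),
                                              f[, 2] + CH / 2))
                }
                nEnd <- round(spec$pointDensity * CT * CH)
                for (sgn in c(-1, 1)) {
                    f <- sampleFace(nEnd, CT, CH)
                    pts <- rbind(pts, toWorld(rep(sgn * CL / 2, nEnd), f[, 1],
                                              f[, 2] + CH / 2))
                }
            } else {  # ellipsoid surface (upper half + equator skirt)
                nn <- round(spec$pointDensity * pi * CL * CT / 2)
                u <- matrix(rnorm(3 * nn), nn, 3)
                u <- u / sqrt(rowSums(u^2))
                u[, 3] <- abs(u[, 3])
                pts <- rbind(pts, toWorld(u[, 1] * CL / 2, u[, 2] * CT / 2,
                                          CH / 2 + u[, 3] * CH / 2))
            }
        }
        flaps <- overhangFlaps(truth)
        if (!is.null(flaps)) {
            flapDepth <- 0.1   # vertical thickness of the wrapped-shoot flap
            for (i in seq_len(nrow(flaps))) {
                k <- flaps$rowId[i]
                p0 <- frame$starts[k, ]
                len <- flaps$alongEnd[i] - flaps$alongStart[i]
                mid <- (flaps$alongEnd[i] + flaps$alongStart[i]) / 2
                nn <- max(4L, round(spec$pointDensity * len * flaps$CT[i]))
                for (h in c(flaps$CH[i] - flapDepth, flaps$CH[i])) {
                    f <- sampleFace(nn, len, flaps$CT[i])
                    x <- p0[1] + (mid + f[, 1]) * frame$u[1] +
                        f[, 2] * frame$v[1]
                    y <- p0[2] + (mid + f[, 1]) * frame$u[2] +
                        f[, 2] * frame$v[2]
                    pts <- rbind(pts, cbind(x, y, groundZ(truth, x, y) +
                                            spec$cordonHeight + h))
                }
            }
        }
        if (spec$terrainNoiseSd > 0)
            pts <- pts + matrix(rnorm(length(pts), 0, spec$terrainNoiseSd),
                                nrow(pts))
    })
    colnames(pts) <- c("x", "y", "z")
    PointCloud3D(pts)
}

#' Write a synthetic site to disk
#'
#' Writes \code{dem.asc}, \code{cloud.xyz}, \code{truth.csv},
#' \code{missing.geojson} and \code{spec.cfg} (flat key=value, units in the
#' key names) under \code{dir}.
#'
#' @param truth a \linkS4class{VineyardTruth}
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
writeSite <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    spec <- truth@spec
    paths <- c(dem = file.path(dir, "dem.asc"),
               cloud = file.path(dir, "cloud.xyz"),
               truth = file.path(dir, "truth.csv"),
               missing = file.path(dir, "missing.geojson"),
               spec = file.path(dir, "spec.cfg"))
    writeDem(renderDem(truth), paths["dem"])
    writeCloud(renderCloud(truth), paths["cloud"])
    write.csv(truth@vineRecords, paths["truth"], row.names = FALSE)
    writeMissingPlantPoints(truth@missingPoints, paths["missing"])
    keys <- vapply(spec, function(v) as.character(v), character(1))
    writeLines(paste0(names(spec), "=", keys), paths["spec"])
    invisible(paths)
}

#' Read a generator spec from a flat key=value config file
#'
#' @param path config path as written by [writeSite()]
#' @return a spec list (validated through [syntheticSiteSpec()])
#' @export
readSiteSpec <- function(path) {
    kv <- strsplit(readLines(path), "=", fixed = TRUE)
    vals <- lapply(kv, function(p) p[2])
    names(vals) <- vapply(kv, function(p) p[1], character(1))
    num <- setdiff(names(vals), c("canopyShape", "hollow"))
    vals[num] <- lapply(vals[num], as.numeric)
    if ("hollow" %in% names(vals)) vals$hollow <- as.logical(vals$hollow)
    do.call(syntheticSiteSpec, vals)
}
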