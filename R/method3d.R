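#' PlaneModel: a fitted ground plane
#'
#' The plane is \code{normal . p = offset} with \code{normal} a unit
#' vector pointing upward (positive z component).  \code{maxDistance} is
#' the inlier band half-width (m) and \code{maxAngularDistance} the
#' largest admissible angle (degrees) between \code{normal} and the
#' vertical.
#'
#' @slot normal unit length-3 numeric
#' @slot offset scalar, meters
#' @slot maxDistance inlier distance (m)
#' @slot maxAngularDistance angular constraint (degrees)
#' @export
setClass("PlaneModel",
    representation(normal = "numeric", offset = "numeric",
                   maxDistance = "numeric", maxAngularDistance = "numeric"))

setValidity("PlaneModel", function(object) {
    if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-6)
        return("normal must have unit length")
    TRUE
})

# signed height of points above a plane
planeHeight <- function(xyz, plane)
    xyz %*% plane@normal - plane@offset

#' Fit the ground plane by angle-constrained random sample consensus
#'
#' Repeatedly samples 3 points, forms their plane, discards candidates
#' whose normal deviates from the vertical by more than
#' \code{maxAngularDistance} degrees, and scores the rest by the number of
#' points within \code{maxDistance} of the plane.  The best candidate is
#' refined by a least-squares plane through its inliers (centroid +
#' smallest principal direction) and the inlier set recomputed.  If the
#' refined plane violates the angular constraint — e.g. the terrain is
#' genuinely steeper than allowed — the fit is rejected.  Deterministic
#' given \code{seed}.  For large clouds the consensus score is evaluated
#' on a fixed subsample of \code{maxConsensusPoints} points; the final
#' inlier set always uses every point.
#'
#' @param cloud a \linkS4class{PointCloud3D}
#' @param maxDistance inlier band half-width (m), default 0.5
#' @param maxAngularDistance max angle of the normal to the vertical
#'   (degrees), default 5
#' @param nIter number of consensus iterations (fixed, default 1000)
#' @param seed RNG seed for the sampling
#' @param maxConsensusPoints subsample size for consensus scoring
#' @return list with \code{plane} (a \linkS4class{PlaneModel}) and
#'   \code{inliers} (integer indices of ground points)
#' @export
fitGroundPlane <- function(cloud, maxDistance = 0.5, maxAngularDistance = 5,
                           nIter = 1000L, seed = 42L,
                           maxConsensusPoints = 3000L) {
    xyz <- coords(cloud)
    n <- nrow(xyz)
    if (n < 3L) stop("at least 3 points are required to fit a plane")
    cosMax <- cos(maxAngularDistance * pi / 180)
    ctrXY <- colMeans(xyz[, 1:2, drop = FALSE])
    withSeed(seed, {
        sub <- if (n > maxConsensusPoints)
            xyz[sample.int(n, maxConsensusPoints), , drop = FALSE] else xyz
        cand <- vector("list", nIter)
        for (it in seq_len(nIter)) {
            idx <- sample.int(n, 3L)
            p <- xyz[idx, , drop = FALSE]
            nv <- c(
                (p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
                    (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
                (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
                    (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
                (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                    (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
            nn <- sqrt(sum(nv^2))
            if (nn < 1e-12) next                  # collinear sample
            nv <- nv / nn
            if (nv[3] < 0) nv <- -nv
            if (nv[3] < cosMax) next              # too far from vertical
            off <- sum(nv * p[1, ])
            score <- sum(abs(sub %*% nv - off) <= maxDistance)
            cand[[it]] <- c(nv, off, score)
        }
    })
    cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
    if (is.null(cand) || nrow(cand) == 0L)
        stop("no admissible ground plane within the angular constraint ",
             "(all candidate planes exceed ", maxAngularDistance,
             " degrees from vertical, or the points are collinear)")
    # the ground is the LOWEST of the dominant near-horizontal planes: a
    # continuous canopy presents a second admissible plane a canopy-height
    # up, so among candidates scoring within 80% of the best consensus we
    # take the one lying lowest at the site center
    top <- cand[cand[, 5] >= 0.8 * max(cand[, 5]), , drop = FALSE]
    zc <- (top[, 4] - top[, 1] * ctrXY[1] - top[, 2] * ctrXY[2]) / top[, 3]
    bestRow <- top[which.min(zc), ]
    best <- list(bestRow[1:3], bestRow[4])
    refine <- function(nv, off) {
        h <- xyz %*% nv - off
        inl <- which(abs(h) <= maxDistance)
        if (length(inl) < 3L) stop("degenerate consensus set")
        pts <- xyz[inl, , drop = FALSE]
        ctrd <- colMeans(pts)
        ev <- eigen(crossprod(sweep(pts, 2, ctrd)), symmetric = TRUE)
        nv2 <- ev$vectors[, 3]
        if (nv2[3] < 0) nv2 <- -nv2
        list(normal = nv2, offset = sum(nv2 * ctrd), inliers = inl)
    }
    r <- refine(best[[1]], best[[2]])
    r <- refine(r$normal, r$offset)   # once more with the refined band
    if (r$normal[3] < cosMax)
        stop("no admissible ground plane within the angular constraint ",
             "(refined plane is ",
             sprintf("%.2f", acos(r$normal[3]) * 180 / pi),
             " degrees from vertical)")
    plane <- new("PlaneModel", normal = r$normal, offset = r$offset,
                 maxDistance = maxDistance,
                 maxAngularDistance = maxAngularDistance)
    list(plane = plane, inliers = r$inliers)
}

#' Split a cloud into ground and canopy
#'
#' Plane inliers become the ground; the remaining points above the plane
#' become the canopy.  Remaining points more than \code{maxDistance}
#' below the plane are photogrammetric noise and are discarded (their
#' count is reported via a message and the \code{nDiscarded} element).
#' An empty canopy is legitimate (a cell with no vines) and only warns.
#'
#' @param cloud a \linkS4class{PointCloud3D}
#' @param plane a fitted \linkS4class{PlaneModel}
#' @param inliers integer indices of ground points (from
#'   [fitGroundPlane()])
#' @return list with \code{ground}, \code{canopy}
#'   (\linkS4class{PointCloud3D}) and \code{nDiscarded}
#' @export
splitGroundCanopy <- function(cloud, plane, inliers) {
    xyz <- coords(cloud)
    h <- planeHeight(xyz, plane)
    rest <- setdiff(seq_len(nrow(xyz)), inliers)
    above <- rest[h[rest] > 0]
    below <- rest[h[rest] <= 0]
    if (length(below))
        message(length(below), " points below the ground plane discarded")
    if (!length(above)) warning("canopy is empty")
    sel <- function(i) PointCloud3D(xyz[i, , drop = FALSE],
        color = if (nrow(cloud@color)) cloud@color[i, , drop = FALSE])
    list(ground = sel(inliers), canopy = sel(above),
         nDiscarded = length(below))
}

#' Clip a cloud to one grid cell
#'
#' Keeps the points whose (x, y) fall inside the half-open cell rectangle;
#' a point on a boundary shared by two cells belongs to the lower-index
#' cell only.
#'
#' @param cloud a \linkS4class{PointCloud3D}
#' @param grid a \linkS4class{VineGrid}
#' @param cell a cellId (character) or cell row index (integer)
#' @return a \linkS4class{PointCloud3D}
#' @export
clipCell <- function(cloud, grid, cell) {
    cc <- cells(grid)
    i <- if (is.character(cell)) match(cell, cc$cellId) else as.integer(cell)
    if (is.na(i) || i < 1L || i > nrow(cc)) stop("unknown cell: ", cell)
    idx <- assignToCells(coords(cloud)[, 1:2, drop = FALSE], grid)
    sel <- which(idx == i)
    PointCloud3D(coords(cloud)[sel, , drop = FALSE],
                 color = if (nrow(cloud@color))
                     cloud@color[sel, , drop = FALSE])
}

#' Alpha-shape volume of a point set
#'
#' Volume of the alpha complex at radius \code{alpha}: the points are
#' Delaunay-tetrahedralised and every tetrahedron whose circumsphere
#' radius is at most \code{alpha} is kept; the volume is the sum of the
#' kept tetrahedra.  \code{alpha} is a length in meters (the MATLAB-style
#' radius convention, not the reciprocal one); \code{alpha = Inf} gives
#' the convex-hull volume, and fewer than 4 points (or a degenerate,
#' coplanar set) give volume 0 with a warning.
#'
#' Very dense cells may be decimated to \code{maxPoints} by a
#' deterministic even stride first; at the densities photogrammetry
#' delivers the alpha-shape volume is insensitive to this (point spacing
#' remains far below alpha).
#'
#' @param x a \linkS4class{PointCloud3D} or an n x 3 matrix
#' @param alpha alpha radius (m), default 0.5
#' @param maxPoints decimation cap (default: no decimation)
#' @return volume (m^3)
#' @export
alphashapeVolume <- function(x, alpha = 0.5, maxPoints = Inf) {
    xyz <- if (is(x, "PointCloud3D")) coords(x) else as.matrix(x)
    if (is.na(alpha) || alpha <= 0) stop("alpha must be positive")
    n <- nrow(xyz)
    if (n < 4L) return(0)
    if (is.finite(maxPoints) && n > maxPoints) {
        keep <- unique(as.integer(round(seq(1, n, length.out = maxPoints))))
        xyz <- xyz[keep, , drop = FALSE]
    }
    r <- .alphaVolumeCpp(xyz, alpha)
    if (r$hullVolume <= 1e-12) {
        warning("degenerate (coplanar or coincident) point set: volume 0")
        return(0)
    }
    r$volume
}

#' Average vine volume from complete reference cells
#'
#' The mean alpha-shape volume of the cells known (or assumed) to contain
#' their full complement of plants, divided by the per-cell plant count.
#'
#' @param cellVolumes named (by cellId) or plain numeric vector of
#'   per-cell alpha-shape volumes (m^3)
#' @param completeCells indices, logical mask, or cellIds of the
#'   reference cells with no missing plants
#' @param plantsPerCell plants per complete cell (default 3)
#' @return list with \code{vBar} (m^3/vine) and \code{nReferenceCells}
#' @export
averageVineVolume <- function(cellVolumes, completeCells,
                              plantsPerCell = 3L) {
    v <- if (is.character(completeCells))
        cellVolumes[match(completeCells, names(cellVolumes))]
    else cellVolumes[completeCells]
    v <- v[is.finite(v)]
    if (!length(v))
        stop("no complete reference cells: supply the average vine volume ",
             "(vBar) manually")
    list(vBar = mean(v) / plantsPerCell, nReferenceCells = length(v))
}

#' Missing plants of a cell from its volume deficit
#'
#' The number of plants present is the cell volume divided by the average
#' vine volume, rounded to a count and clamped to [0, plantsPerCell]; the
#' missing count is the complement.  \code{rounding = "nearest"} (default)
#' is robust to per-vine size variation; \code{"ceiling"} treats any
#' deficit below the next whole plant as that plant being present.
#'
#' @param cellVolume alpha-shape volume of the cell (m^3)
#' @param vBar average vine volume (m^3/vine), > 0
#' @param plantsPerCell plant slots in the cell
#' @param rounding "nearest" or "ceiling"
#' @return integer missing-plant count in [0, plantsPerCell]
#' @export
missingPlants3D <- function(cellVolume, vBar, plantsPerCell = 3L,
                            rounding = c("nearest", "ceiling")) {
    rounding <- match.arg(rounding)
    if (!is.finite(vBar) || vBar <= 0) stop("vBar must be positive")
    ratio <- cellVolume / vBar
    present <- if (rounding == "ceiling") ceiling(ratio)
               else roundHalfUp(ratio)
    present <- min(max(0, present), plantsPerCell)
    as.integer(plantsPerCell - present)
}

#' Project per-cell volumes onto their row axes
#'
#' Orders the cells of each row by their along-row midpoint and returns
#' the (midpoint, volume) profile per row — the row volume map; the site
#' map is the union of rows.
#'
#' @param metrics per-cell data.frame with \code{cellId} and \code{volume}
#' @param grid the \linkS4class{VineGrid}
#' @return data.frame \code{rowId}, \code{cellId}, \code{alongMid} (m from
#'   the row start), \code{volume}, ordered within row
#' @export
rowVolumeMap <- function(metrics, grid) {
    cc <- cells(grid)
    i <- match(metrics$cellId, cc$cellId)
    if (any(is.na(i))) stop("metrics contain cellIds not in the grid")
    out <- data.frame(rowId = cc$rowId[i], cellId = metrics$cellId,
                      alongMid = (cc$a0[i] + cc$a1[i]) / 2,
                      volume = metrics$volume)
    out[order(out$rowId, out$alongMid), ]
}

#' Run the complete 3D alpha-shape pipeline
#'
#' Fits the ground plane over the whole site ([fitGroundPlane()]),
#' removes it ([splitGroundCanopy()]), clips the canopy cloud to every
#' grid cell, measures each cell's alpha-shape volume
#' ([alphashapeVolume()]), calibrates the average vine volume
#' ([averageVineVolume()]) and converts per-cell volume deficits into
#' missing-plant counts ([missingPlants3D()]).
#'
#' When neither \code{vBar} nor \code{completeCellIds} is given the
#' reference cells are selected automatically: an initial guess of the
#' per-vine volume (the upper-quartile cell volume divided by the slot
#' count) classifies the cells once, and the cells classified complete
#' become the reference set.
#'
#' @param cloud a \linkS4class{PointCloud3D} of the site
#' @param grid a \linkS4class{VineGrid}
#' @param cfg a \linkS4class{SiteConfig}; defaults to the grid's
#' @param alpha alpha radius (m); defaults to \code{cfg@alpha}
#' @param maxDistance,maxAngularDistance ground-plane parameters
#' @param vBar average vine volume (m^3); overrides calibration
#' @param completeCellIds cellIds of known-complete reference cells
#' @param rounding rounding rule for [missingPlants3D()]
#' @param maxPoints per-cell decimation cap for the alpha shape
#' @param sparseFloor cells with fewer canopy points are flagged sparse
#' @param seed RNG seed for the plane consensus
#' @return data.frame with one row per cell: \code{cellId}, \code{rowId},
#'   \code{nPoints}, \code{volume} (m^3), \code{nMissing}, \code{sparse},
#'   \code{nSlots}, \code{method = "3D"}; attributes \code{vBar},
#'   \code{plane}, \code{nDiscarded}
#' @export
runMethod3D <- function(cloud, grid, cfg = grid@config, alpha = cfg@alpha,
                        maxDistance = 0.5, maxAngularDistance = 5,
                        vBar = NULL, completeCellIds = NULL,
                        rounding = c("nearest", "ceiling"),
                        maxPoints = 2000L, sparseFloor = 20L, seed = 42L) {
    rounding <- match.arg(rounding)
    fit <- fitGroundPlane(cloud, maxDistance = maxDistance,
                          maxAngularDistance = maxAngularDistance,
                          seed = seed)
    sp <- splitGroundCanopy(cloud, fit$plane, fit$inliers)
    canopy <- coords(sp$canopy)
    cc <- cells(grid)
    idx <- assignToCells(canopy[, 1:2, drop = FALSE], grid)

    vols <- numeric(nrow(cc))
    npts <- integer(nrow(cc))
    for (i in seq_len(nrow(cc))) {
        pts <- canopy[which(idx == i), , drop = FALSE]
        npts[i] <- nrow(pts)
        vols[i] <- if (nrow(pts) >= 4L)
            suppressWarnings(alphashapeVolume(pts, alpha = alpha,
                                              maxPoints = maxPoints)) else 0
    }
    names(vols) <- cc$cellId

    if (is.null(vBar)) {
        if (!is.null(completeCellIds)) {
            vBar <- averageVineVolume(vols, completeCellIds,
                                      cc$nSlots[1])$vBar
        } else {
            v0 <- as.numeric(quantile(vols, 0.75, type = 7)) / cc$nSlots[1]
            if (v0 <= 0) stop("cannot calibrate the average vine volume: ",
                              "all cell volumes are 0")
            complete <- which(vapply(seq_along(vols), function(i)
                missingPlants3D(vols[i], v0, cc$nSlots[i],
                                rounding = rounding) == 0L, logical(1)))
            vBar <- averageVineVolume(vols, complete, cc$nSlots[1])$vBar
        }
    }
    nMiss <- vapply(seq_along(vols), function(i)
        missingPlants3D(vols[i], vBar, cc$nSlots[i], rounding = rounding),
        integer(1))

    out <- data.frame(cellId = cc$cellId, rowId = cc$rowId, nPoints = npts,
                      volume = vols, nMissing = nMiss,
                      sparse = npts < sparseFloor, nSlots = cc$nSlots,
                      method = "3D", row.names = NULL)
    attr(out, "vBar") <- vBar
    attr(out, "plane") <- fit$plane
    attr(out, "nDiscarded") <- sp$nDiscarded
    out
}
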