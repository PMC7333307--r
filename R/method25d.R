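#' VineMask: binary vine/soil mask of a height grid
#'
#' Follows the surface-method convention: soil pixels are 1 (white), vine
#' pixels are 0 (black).  \code{theta} is the vine-row slope with respect
#' to the horizontal image axis, in radians; \code{NA} until estimated or
#' supplied.
#'
#' @slot mask matrix of 0 (vine) / 1 (soil)
#' @slot dp pixel size (m/pixel)
#' @slot theta vine-row angle (radians), \code{NA} if not set
#' @slot threshold the Otsu threshold used, on the rescaled [0, 1] scale
#' @export
setClass("VineMask",
    representation(mask = "matrix", dp = "numeric", theta = "numeric",
                   threshold = "numeric"))

#' Terrain normalisation by morphological top-hat
#'
#' Estimates the ground surface as the grayscale morphological opening of
#' the DEM with a flat disc structuring element and returns the
#' height-above-terrain surface (input minus opening).  Soil pixels map to
#' about 0 and canopy pixels to their height above local ground, removing
#' the effect of terrain slope.  The disc must be wider than the canopy
#' cross-section for the opening to roll under the canopy: the default
#' radius of 0.5 m (1 m diameter) covers hedgerow canopies well over twice
#' the usual 0.4 m thickness.  The residual left on a bare slope is bounded
#' by slope x radius.
#'
#' @param dem a \linkS4class{DemRaster}; no-data cells are filled with the
#'   minimum finite elevation for the opening and restored to \code{NA}
#' @param seRadiusM structuring-element radius in meters
#' @param expectedCanopyWidthM optional canopy cross-width (m); a warning
#'   is issued when the disc diameter does not exceed it
#' @return a \linkS4class{DemRaster} of heights above estimated terrain
#' @export
mitigateSlope <- function(dem, seRadiusM = 0.5, expectedCanopyWidthM = NULL) {
    stopifnot(is(dem, "DemRaster"))
    rPx <- max(1L, round(seRadiusM / dem@dp))
    if (!is.null(expectedCanopyWidthM) &&
        2 * seRadiusM <= expectedCanopyWidthM)
        warning("structuring element (diameter ", 2 * seRadiusM,
                " m) does not exceed the canopy width (",
                expectedCanopyWidthM, " m); canopy will leak into the ",
                "terrain estimate")
    m <- dem@elevation
    na <- !is.finite(m)
    if (all(na)) stop("DEM has no finite elevations")
    if (any(na)) m[na] <- min(m[!na])
    # grayscale morphology expects [0, 1]; opening commutes with affine
    # rescaling, so normalise, open, and take the top-hat on the raw scale
    lo <- min(m); hi <- max(m)
    brush <- EBImage::makeBrush(2L * rPx + 1L, shape = "disc")
    if (hi > lo) {
        g <- (m - lo) / (hi - lo)
        ground <- EBImage::opening(g, brush) * (hi - lo) + lo
    } else ground <- m
    h <- m - ground
    h[h < 0] <- 0
    h[na] <- NA_real_
    DemRaster(h, dp = dem@dp, origin = dem@origin, crsNote = dem@crsNote)
}

#' Otsu threshold by exhaustive search
#'
#' Chooses, among \code{levels} equally spaced candidate thresholds on
#' [0, 1], the one that minimises the within-class (intraclass) variance of
#' the two classes — equivalently, maximises the between-class variance.
#' The input is binned into \code{levels} bins; bin centers act as the
#' class values.
#'
#' @param g numeric values already rescaled to [0, 1]
#' @param levels number of gray levels (default 256)
#' @return the threshold, a value in (0, 1)
#' @export
otsuThreshold <- function(g, levels = 256L) {
    g <- g[is.finite(g)]
    if (!length(g) || diff(range(g)) == 0)
        stop("degenerate histogram: constant grid")
    breaks <- seq(0, 1, length.out = levels + 1L)
    cnt <- as.numeric(tabulate(
        pmin(pmax(findInterval(g, breaks, rightmost.closed = TRUE), 1L),
             levels), nbins = levels))
    mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
    w <- cumsum(cnt)
    mu <- cumsum(cnt * mids)
    tot <- w[levels]
    muT <- mu[levels]
    k <- seq_len(levels - 1L)
    w0 <- w[k]; w1 <- tot - w0
    valid <- w0 > 0 & w1 > 0
    sb <- rep(-Inf, levels - 1L)
    sb[valid] <- (muT * w0[valid] - mu[k][valid] * tot)^2 /
        (w0[valid] * w1[valid])          # between-class variance (x total^3)
    breaks[which.max(sb) + 1L]
}

#' Binarise a height grid into vine and soil by Otsu's method
#'
#' The grid is min-max rescaled to [0, 1] and thresholded globally with
#' [otsuThreshold()].  Pixels above the threshold become vine (0, black),
#' pixels at or below it soil (1, white).  No-data pixels are classed as
#' soil.
#'
#' @param heights a \linkS4class{DemRaster}, normally the output of
#'   [mitigateSlope()]
#' @param levels number of gray levels for the threshold search
#' @return a \linkS4class{VineMask}
#' @export
binarizeOtsu <- function(heights, levels = 256L) {
    stopifnot(is(heights, "DemRaster"))
    m <- heights@elevation
    fin <- is.finite(m)
    if (!any(fin) || diff(range(m[fin])) == 0)
        stop("degenerate histogram: constant grid")
    lo <- min(m[fin]); hi <- max(m[fin])
    g <- (m - lo) / (hi - lo)
    thr <- otsuThreshold(g[fin], levels)
    mask <- matrix(1, nrow(m), ncol(m))
    mask[fin & g > thr] <- 0
    new("VineMask", mask = mask, dp = heights@dp, theta = NA_real_,
        threshold = thr)
}

#' Estimate the vine-row angle from a mask
#'
#' Returns the orientation of the principal axis of the vine (black)
#' pixels with respect to the horizontal image axis, in radians in
#' (-pi/2, pi/2].  A mask whose vine pixels occupy a single column is
#' degenerate for the downstream column-profile geometry; by convention it
#' adopts theta = 0 with a warning.
#'
#' @param mask a \linkS4class{VineMask}
#' @return angle in radians
#' @export
estimateTheta <- function(mask) {
    idx <- which(mask@mask == 0, arr.ind = TRUE)
    if (nrow(idx) < 2L) stop("mask contains fewer than 2 vine pixels")
    xs <- idx[, 2]          # image x = column
    ys <- idx[, 1]          # image y = row (downward)
    if (length(unique(xs)) == 1L) {
        warning("vine pixels occupy a single column; adopting theta = 0")
        return(0)
    }
    cxx <- stats::var(xs); cyy <- stats::var(ys)
    cxy <- stats::cov(xs, ys)
    th <- 0.5 * atan2(2 * cxy, cxx - cyy)
    # fold into (-pi/2, pi/2]
    if (th <= -pi / 2) th <- th + pi
    if (th > pi / 2) th <- th - pi
    th
}

#' Column-wise canopy thickness profile
#'
#' For each image column x of the (cell-clipped) mask, the number of vine
#' pixels delta(x) is converted to meters of canopy thickness
#' perpendicular to the row: \code{deltaP = delta * dp * cos(theta)}.
#'
#' @param mask a \linkS4class{VineMask} (cell-clipped)
#' @param theta vine-row angle (radians); defaults to the angle stored in
#'   the mask
#' @param include optional logical matrix of the mask's shape restricting
#'   which pixels belong to the cell
#' @param cols optional integer vector of columns making up the profile
#' @return list with \code{delta} (pixel counts), \code{deltaP} (m),
#'   \code{dp}, \code{theta}
#' @export
thicknessProfile <- function(mask, theta = mask@theta, include = NULL,
                             cols = NULL) {
    if (is.na(theta)) theta <- 0
    vine <- mask@mask == 0
    if (!is.null(include)) vine <- vine & include
    if (is.null(cols)) cols <- seq_len(ncol(vine))
    delta <- colSums(vine[, cols, drop = FALSE])
    list(delta = as.numeric(delta),
         deltaP = as.numeric(delta) * mask@dp * cos(theta),
         dp = mask@dp, theta = theta)
}

#' Detect missing-plant gaps in a thickness profile
#'
#' Columns with \code{deltaP < threshold} (default 0.1 m) are gap columns.
#' Gap runs shorter than \code{bridgePx} pixels are bridged (closed) first
#' to suppress single-pixel speckle.  The total gap extension is converted
#' to along-row meters, \code{Lv = nGap * dp / cos(theta)}, and the
#' missing-plant count is \code{Next = round(Lv / lp)} (half-up), clamped
#' to [0, plantsPerCell].
#'
#' @param profile output of [thicknessProfile()]
#' @param lp intra-row plant length \eqn{\ell_p} (m)
#' @param threshold gap threshold on thickness (m)
#' @param plantsPerCell clamp for the missing count
#' @param bridgePx minimum run length (pixels) for a gap to count
#' @return list with \code{Lv} (m), \code{Next} (count), \code{segments}
#'   (two-column matrix of along-row start/end, m)
#' @export
detectGaps <- function(profile, lp, threshold = 0.1, plantsPerCell = 3L,
                       bridgePx = 3L) {
    gap <- profile$deltaP < threshold
    r <- rle(gap)
    r$values[r$values & r$lengths < bridgePx] <- FALSE
    gap <- inverse.rle(r)
    scale <- profile$dp / cos(profile$theta)   # column -> along-row meters
    Lv <- sum(gap) * scale
    Next <- min(max(0L, as.integer(roundHalfUp(Lv / lp))),
                as.integer(plantsPerCell))
    r2 <- rle(gap)
    ends <- cumsum(r2$lengths)
    starts <- ends - r2$lengths + 1L
    segs <- cbind(start = (starts[r2$values] - 1L) * scale,
                  end = ends[r2$values] * scale)
    list(Lv = Lv, Next = Next, segments = segs)
}

#' Mean canopy thickness of a profile
#'
#' Mean of \code{deltaP(x)} over the columns at or above the gap
#' threshold, so that missing-plant stretches do not dilute the canopy
#' thickness; 0 when no column qualifies.
#'
#' @inheritParams detectGaps
#' @return mean thickness \eqn{\delta_m} (m)
#' @export
meanThickness <- function(profile, threshold = 0.1) {
    v <- profile$deltaP[profile$deltaP >= threshold]
    if (!length(v)) return(0)
    mean(v)
}

#' Canopy height above the cordon from elevation quartiles
#'
#' For every image row of the cell, the mean elevation of vine pixels
#' gives the vine profile \code{hv(y)} and of soil pixels the soil profile
#' \code{hs(y)}.  The representative vine elevation is the first quartile
#' of \code{hv}, the representative soil elevation the third quartile of
#' \code{hs} (linear-interpolation quartiles), and the canopy height is
#' their difference minus the cordon height.  A negative result is clipped
#' to 0 with a warning.
#'
#' @param dem the original (not slope-mitigated) \linkS4class{DemRaster}
#'   clipped to the cell
#' @param mask matching \linkS4class{VineMask}
#' @param cordon cordon height (m) to subtract
#' @param include optional logical matrix restricting pixels to the cell
#' @return canopy height \code{dh} (m)
#' @export
cellHeight <- function(dem, mask, cordon = 0.8, include = NULL) {
    el <- dem@elevation
    vine <- mask@mask == 0
    soil <- mask@mask == 1
    if (!is.null(include)) { vine <- vine & include; soil <- soil & include }
    vine[!is.finite(el)] <- FALSE
    soil[!is.finite(el)] <- FALSE
    if (!any(vine)) stop("cell contains no vine pixels")
    if (!any(soil)) stop("cell contains no soil pixels")
    rowMean <- function(selRow) {
        n <- rowSums(selRow)
        s <- rowSums(el * selRow, na.rm = TRUE)
        (s / n)[n > 0]
    }
    hv <- rowMean(vine)
    hs <- rowMean(soil)
    q1v <- as.numeric(quantile(hv, 0.25, type = 7))
    q3s <- as.numeric(quantile(hs, 0.75, type = 7))
    dh <- q1v - q3s - cordon
    if (dh < 0) {
        warning("negative canopy height clipped to 0")
        dh <- 0
    }
    dh
}

#' Cuboid volume estimates of the 2.5D method
#'
#' The mean-plant volume is \code{Vp = dh * dL * deltaM} and the
#' region volume \code{Vdem = dh * dA} with the vine area
#' \code{dA = nPx * (dp * cos(theta))^2}.
#'
#' @param dh canopy height above cordon (m)
#' @param deltaM mean canopy thickness (m)
#' @param nPx vine pixel count of the cell
#' @param dp pixel size (m)
#' @param theta vine-row angle (radians)
#' @param dL per-plant length, normally \eqn{\ell_p} (m)
#' @return list with \code{vP}, \code{dA}, \code{vDem}
#' @export
volumes25d <- function(dh, deltaM, nPx, dp, theta, dL) {
    stopifnot(all(is.finite(c(dh, deltaM, nPx, dp, theta, dL))),
              dh >= 0, deltaM >= 0, nPx >= 0)
    dA <- nPx * (dp * cos(theta))^2
    list(vP = dh * dL * deltaM, dA = dA, vDem = dh * dA)
}

# pixel bounding box of a cell polygon: pixel col c covers
# x in [ox + (c-1) dp, ox + c dp], row r covers y in [oy - r dp, oy - (r-1) dp]
cellPixelBox <- function(dem, poly) {
    d <- dim(dem@elevation)
    ox <- dem@origin[1]; oy <- dem@origin[2]; dp <- dem@dp
    cmin <- max(1L, as.integer(floor((min(poly[, 1]) - ox) / dp)) + 1L)
    cmax <- min(d[2], as.integer(ceiling((max(poly[, 1]) - ox) / dp)))
    rmin <- max(1L, as.integer(floor((oy - max(poly[, 2])) / dp)) + 1L)
    rmax <- min(d[1], as.integer(ceiling((oy - min(poly[, 2])) / dp)))
    if (cmax < cmin || rmax < rmin) stop("cell outside the DEM extent")
    list(rows = rmin:rmax, cols = cmin:cmax)
}

#' Run the complete 2.5D surface pipeline
#'
#' Normalises the DEM for terrain ([mitigateSlope()]), binarises vine
#' versus soil over the whole site ([binarizeOtsu()]), then walks the grid
#' cells: clips the mask and DEM to each cell, builds the thickness
#' profile along the row, measures gaps ([detectGaps()]), mean thickness,
#' canopy height ([cellHeight()]) and the cuboid volumes ([volumes25d()]).
#'
#' @param dem a \linkS4class{DemRaster}
#' @param grid a \linkS4class{VineGrid}
#' @param cfg a \linkS4class{SiteConfig}; defaults to the grid's
#' @param seRadiusM structuring-element radius for terrain removal (m)
#' @param bridgePx speckle-bridging length for gap runs (pixels)
#' @param thetaSource "config" derives the row angle from the cell's row
#'   axis (robust for sparse cells); "estimate" measures it from the
#'   cell's vine pixels
#' @return data.frame with one row per cell: \code{cellId}, \code{rowId},
#'   \code{theta}, \code{deltaM}, \code{dh}, \code{nPx}, \code{dA},
#'   \code{vP}, \code{vDem}, \code{Lv}, \code{nExt}, \code{nSlots},
#'   \code{method = "25D"}, and \code{volume} (the per-cell \code{vDem})
#' @export
runMethod25D <- function(dem, grid, cfg = grid@config, seRadiusM = 0.5,
                         bridgePx = 3L, thetaSource = c("config", "estimate")) {
    thetaSource <- match.arg(thetaSource)
    heights <- mitigateSlope(dem, seRadiusM)
    siteMask <- binarizeOtsu(heights)
    cc <- cells(grid)
    polys <- cellPolygons(grid)
    ctr <- demPixelCenters(dem)

    res <- lapply(seq_len(nrow(cc)), function(i) {
        poly <- polys[[i]]
        box <- cellPixelBox(dem, poly)
        sub <- function(m) m[box$rows, box$cols, drop = FALSE]
        X <- matrix(ctr$x[box$cols], length(box$rows), length(box$cols),
                    byrow = TRUE)
        Y <- matrix(ctr$y[box$rows], length(box$rows), length(box$cols))
        u <- c(cc$ux[i], cc$uy[i]); v <- c(u[2], -u[1])
        rx <- X - cc$x0[i]; ry <- Y - cc$y0[i]
        s <- rx * u[1] + ry * u[2]
        t <- rx * v[1] + ry * v[2]
        inCell <- s >= cc$a0[i] & s < cc$a1[i] &
            t >= -cc$halfWidth[i] & t < cc$halfWidth[i]

        cmask <- new("VineMask", mask = sub(siteMask@mask), dp = dem@dp,
                     theta = NA_real_, threshold = siteMask@threshold)
        theta <- if (thetaSource == "config") {
            th <- atan2(u[2], u[1])
            if (th <= -pi / 2) th <- th + pi
            if (th > pi / 2) th <- th - pi
            th
        } else tryCatch(estimateTheta(cmask), error = function(e) 0)

        # profile columns: those the row axis crosses inside the cell
        axisX <- cc$x0[i] + c(cc$a0[i], cc$a1[i]) * u[1]
        colX <- ctr$x[box$cols]
        colSel <- which(colX >= min(axisX) & colX <= max(axisX))
        if (!length(colSel)) colSel <- seq_along(box$cols)

        prof <- thicknessProfile(cmask, theta = theta, include = inCell,
                                 cols = colSel)
        gaps <- detectGaps(prof, lp = cfg@intraRow,
                           threshold = cfg@thicknessThreshold,
                           plantsPerCell = cc$nSlots[i], bridgePx = bridgePx)
        dM <- meanThickness(prof, threshold = cfg@thicknessThreshold)
        nPx <- sum(cmask@mask == 0 & inCell)
        dh <- if (nPx == 0) 0 else tryCatch(
            cellHeight(DemRaster(sub(dem@elevation), dp = dem@dp),
                       cmask, cordon = cfg@cordonHeight, include = inCell),
            error = function(e) 0)
        vol <- volumes25d(dh, dM, nPx, dem@dp, theta, dL = cfg@intraRow)
        data.frame(cellId = cc$cellId[i], rowId = cc$rowId[i], theta = theta,
                   deltaM = dM, dh = dh, nPx = nPx, dA = vol$dA,
                   vP = vol$vP, vDem = vol$vDem, Lv = gaps$Lv,
                   nExt = gaps$Next, nSlots = cc$nSlots[i])
    })
    out <- do.call(rbind, res)
    out$method <- "25D"
    out$volume <- out$vDem
    out$nMissing <- out$nExt
    out
}
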