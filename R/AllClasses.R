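#' DemRaster: a georeferenced elevation grid
#'
#' A single-band elevation raster in a local metric frame.  The grid follows
#' the north-up raster convention: row 1 is the northernmost row and the row
#' index increases southward.  \code{origin} is the world coordinate of the
#' outer (north-west) corner of pixel (1, 1), so the center of pixel
#' \code{(r, c)} lies at \code{origin + dp * (c - 0.5, -(r - 0.5))}.
#' No-data cells are stored as \code{NA}.
#'
#' @slot elevation numeric matrix of elevations in meters (\code{NA} = no data)
#' @slot dp pixel size in meters per pixel (square pixels)
#' @slot origin length-2 numeric, world (x, y) of the NW outer corner
#' @slot crsNote free-text tag of the (metric) CRS; no reprojection is done
#' @export
setClass("DemRaster",
    representation(elevation = "matrix", dp = "numeric",
                   origin = "numeric", crsNote = "character"),
    prototype(dp = 0.005, origin = c(0, 0), crsNote = "local-metric"))

setValidity("DemRaster", function(object) {
    msg <- character()
    if (length(object@dp) != 1L || !is.finite(object@dp) || object@dp <= 0)
        msg <- c(msg, "dp must be a single positive number")
    if (length(object@origin) != 2L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be two finite numbers")
    if (length(object@elevation) == 0L)
        msg <- c(msg, "elevation grid is empty")
    fin <- object@elevation[is.finite(object@elevation)]
    if (length(fin) && (min(fin) < -500 || max(fin) > 9000))
        msg <- c(msg, "finite elevations must lie within [-500, 9000] m")
    if (length(msg)) msg else TRUE
})

#' Construct a DemRaster
#'
#' @param elevation numeric matrix of elevations (m); \code{NA} marks no-data
#' @param dp pixel size (m/pixel, square pixels)
#' @param origin world (x, y) of the north-west outer corner of the grid
#' @param crsNote free-text CRS tag
#' @return a \linkS4class{DemRaster}
#' @examples
#' dem <- DemRaster(matrix(0, 10, 10), dp = 0.1)
#' pixelSize(dem)
#' @export
DemRaster <- function(elevation, dp, origin = c(0, 0),
                      crsNote = "local-metric") {
    new("DemRaster", elevation = elevation, dp = as.numeric(dp),
        origin = as.numeric(origin), crsNote = as.character(crsNote)[1])
}

#' PointCloud3D: a set of XYZ points in meters
#'
#' @slot xyz numeric matrix with three columns (x, y, z), meters
#' @slot color numeric matrix with three columns (r, g, b in [0, 1]) and the
#'   same number of rows as \code{xyz}, or a 0-row matrix when absent
#' @export
setClass("PointCloud3D",
    representation(xyz = "matrix", color = "matrix"),
    prototype(color = matrix(numeric(), 0, 3)))

setValidity("PointCloud3D", function(object) {
    msg <- character()
    if (ncol(object@xyz) != 3L)
        msg <- c(msg, "xyz must have 3 columns")
    if (nrow(object@xyz) && any(!is.finite(object@xyz)))
        msg <- c(msg, "all coordinates must be finite")
    if (nrow(object@color) && nrow(object@color) != nrow(object@xyz))
        msg <- c(msg, "color must have one row per point")
    if (nrow(object@color) && ncol(object@color) != 3L)
        msg <- c(msg, "color must have 3 columns")
    if (length(msg)) msg else TRUE
})

#' Construct a PointCloud3D
#'
#' @param xyz numeric matrix (n x 3) of point coordinates in meters
#' @param color optional numeric matrix (n x 3) of RGB in [0, 1]
#' @return a \linkS4class{PointCloud3D}
#' @export
PointCloud3D <- function(xyz, color = NULL) {
    xyz <- as.matrix(xyz)
    if (is.null(dim(xyz)) || ncol(xyz) != 3L)
        stop("xyz must be an n x 3 matrix")
    storage.mode(xyz) <- "double"
    colnames(xyz) <- c("x", "y", "z")
    if (is.null(color)) color <- matrix(numeric(), 0, 3)
    else { color <- as.matrix(color); storage.mode(color) <- "double" }
    new("PointCloud3D", xyz = xyz, color = color)
}

#' SiteConfig: vineyard geometry and method thresholds
#'
#' Holds the planting geometry of a site and the tunable thresholds shared by
#' the two pipelines: the inter-row and intra-row spacing, the per-cell plant
#' count, the thickness threshold under which a profile column counts as a
#' gap (0.1 m), the cordon height subtracted from canopy elevation (0.8 m),
#' and the alpha radius of the 3D method (0.5 m).
#'
#' @slot interRow inter-row spacing (m)
#' @slot intraRow intra-row plant spacing \eqn{\ell_p} (m)
#' @slot rowAzimuth row direction, degrees clockwise from north
#' @slot surfaceHa site surface (ha); \code{NA} when unknown
#' @slot densityPerHa planting density (plants/ha); \code{NA} when unknown
#' @slot cordonHeight cordon height (m), default 0.8
#' @slot thicknessThreshold gap threshold on canopy thickness (m), default 0.1
#' @slot alpha alpha-shape radius (m), default 0.5
#' @slot plantsPerCell plant slots per grid cell, default 3
#' @export
setClass("SiteConfig",
    representation(interRow = "numeric", intraRow = "numeric",
                   rowAzimuth = "numeric", surfaceHa = "numeric",
                   densityPerHa = "numeric", cordonHeight = "numeric",
                   thicknessThreshold = "numeric", alpha = "numeric",
                   plantsPerCell = "integer"))

setValidity("SiteConfig", function(object) {
    msg <- character()
    pos <- function(x) length(x) == 1L && is.finite(x) && x > 0
    if (!pos(object@interRow)) msg <- c(msg, "interRow must be positive")
    if (!pos(object@intraRow)) msg <- c(msg, "intraRow must be positive")
    if (!pos(object@thicknessThreshold))
        msg <- c(msg, "thicknessThreshold must be positive")
    if (!pos(object@alpha)) msg <- c(msg, "alpha must be positive")
    if (object@plantsPerCell < 1L) msg <- c(msg, "plantsPerCell must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a SiteConfig
#'
#' When both \code{densityPerHa} and the spacings are supplied, consistency
#' is checked (\code{1e4 / (interRow * intraRow)} plants/ha) and a warning is
#' emitted on disagreement beyond 5 per cent.
#'
#' @param interRow inter-row spacing (m)
#' @param intraRow intra-row spacing \eqn{\ell_p} (m)
#' @param rowAzimuth row direction, degrees from north (default 0)
#' @param surfaceHa site surface in hectares (optional)
#' @param densityPerHa planting density in plants/ha (optional)
#' @param cordonHeight cordon height (m)
#' @param thicknessThreshold gap threshold (m)
#' @param alpha alpha-shape radius (m)
#' @param plantsPerCell plant slots per grid cell
#' @return a \linkS4class{SiteConfig}
#' @examples
#' cfg <- siteConfig(interRow = 2.5, intraRow = 0.9)
#' @export
siteConfig <- function(interRow, intraRow, rowAzimuth = 0,
                       surfaceHa = NA_real_, densityPerHa = NA_real_,
                       cordonHeight = 0.8, thicknessThreshold = 0.1,
                       alpha = 0.5, plantsPerCell = 3L) {
    if (is.finite(densityPerHa)) {
        implied <- 1e4 / (interRow * intraRow)
        if (abs(densityPerHa - implied) / implied > 0.05)
            warning(sprintf(
                "densityPerHa (%.0f) disagrees with spacing-implied density (%.0f)",
                densityPerHa, implied))
    }
    new("SiteConfig", interRow = as.numeric(interRow),
        intraRow = as.numeric(intraRow), rowAzimuth = as.numeric(rowAzimuth),
        surfaceHa = as.numeric(surfaceHa),
        densityPerHa = as.numeric(densityPerHa),
        cordonHeight = as.numeric(cordonHeight),
        thicknessThreshold = as.numeric(thicknessThreshold),
        alpha = as.numeric(alpha), plantsPerCell = as.integer(plantsPerCell))
}

#' VineGrid: the uniform polygon grid over vine rows
#'
#' Rectangular cells centered on row axes.  Each cell spans the full
#' inter-row width across the row (midpoint to midpoint between adjacent
#' rows) and \code{plantsPerCell * intraRow} along it.  Cells tile each row
#' from its start; along-row intervals are half-open, so every point belongs
#' to at most one cell of a row.
#'
#' @slot cells data.frame with one row per cell: \code{cellId}, \code{rowId},
#'   \code{x0}, \code{y0} (row start), \code{ux}, \code{uy} (along-row unit
#'   vector), \code{a0}, \code{a1} (half-open along-row interval from the row
#'   start, m), \code{halfWidth} (half of the across-row extent, m),
#'   \code{cx}, \code{cy} (cell center)
#' @slot config the \linkS4class{SiteConfig} the grid was built from
#' @export
setClass("VineGrid",
    representation(cells = "data.frame", config = "SiteConfig"))

#' VineyardTruth: a generated synthetic vineyard and its ground truth
#'
#' @slot vineRecords data.frame, one row per plant slot: \code{rowId},
#'   \code{slot}, \code{along} (m from row start), \code{x}, \code{y},
#'   \code{present}, \code{CH}, \code{CT}, \code{CL} (m), \code{trueVolume}
#'   (m^3, \code{CH * CT * CL}, 0 for absent vines)
#' @slot missingPoints numeric matrix (k x 2) of world (x, y) of absent vines
#' @slot rows data.frame of row axes: \code{rowId}, \code{x0,y0,x1,y1}
#' @slot groundPlane numeric length 3: \code{(sx, sy, z0)} of the ground
#'   plane \code{z = z0 + sx x + sy y}
#' @slot seed the integer seed the site was drawn with
#' @slot spec the generating parameter list (see [syntheticSiteSpec()])
#' @export
setClass("VineyardTruth",
    representation(vineRecords = "data.frame", missingPoints = "matrix",
                   rows = "data.frame", groundPlane = "numeric",
                   seed = "integer", spec = "list"))

setValidity("VineyardTruth", function(object) {
    msg <- character()
    vr <- object@vineRecords
    if (nrow(object@missingPoints) != sum(!vr$present))
        msg <- c(msg, "missingPoints must have one row per absent vine")
    if (any(vr$trueVolume[vr$present] <= 0))
        msg <- c(msg, "present vines must have positive trueVolume")
    if (length(msg)) msg else TRUE
})
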