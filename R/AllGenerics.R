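#' @rdname DemRaster-class
#' @param object,x a DemRaster / PointCloud3D / VineGrid
#' @export
setGeneric("elevation", function(x) standardGeneric("elevation"))

#' @rdname DemRaster-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname DemRaster-class
#' @export
setGeneric("rasterOrigin", function(x) standardGeneric("rasterOrigin"))

#' @rdname PointCloud3D-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname PointCloud3D-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname VineGrid-class
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname VineGrid-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname VineGrid-class
#' @export
setGeneric("cellPolygons", function(x) standardGeneric("cellPolygons"))

#' @rdname VineyardTruth-class
#' @export
setGeneric("vineRecords", function(x) standardGeneric("vineRecords"))

#' @rdname VineyardTruth-class
#' @export
setGeneric("missingPoints", function(x) standardGeneric("missingPoints"))

#' @rdname VineyardTruth-class
#' @export
setGeneric("rowAxes", function(x) standardGeneric("rowAxes"))

# ---- accessors ----

#' @rdname DemRaster-class
#' @export
setMethod("elevation", "DemRaster", function(x) x@elevation)

#' @rdname DemRaster-class
#' @export
setMethod("pixelSize", "DemRaster", function(x) x@dp)

#' @rdname DemRaster-class
#' @export
setMethod("rasterOrigin", "DemRaster", function(x) x@origin)

#' @rdname DemRaster-class
#' @export
setMethod("dim", "DemRaster", function(x) dim(x@elevation))

#' @rdname PointCloud3D-class
#' @export
setMethod("coords", "PointCloud3D", function(x) x@xyz)

#' @rdname PointCloud3D-class
#' @export
setMethod("nPoints", "PointCloud3D", function(x) nrow(x@xyz))

#' @rdname VineGrid-class
#' @export
setMethod("cells", "VineGrid", function(x) x@cells)

#' @rdname VineGrid-class
#' @export
setMethod("nCells", "VineGrid", function(x) nrow(x@cells))

#' @rdname VineyardTruth-class
#' @export
setMethod("vineRecords", "VineyardTruth", function(x) x@vineRecords)

#' @rdname VineyardTruth-class
#' @export
setMethod("missingPoints", "VineyardTruth", function(x) x@missingPoints)

#' @rdname VineyardTruth-class
#' @export
setMethod("rowAxes", "VineyardTruth", function(x) x@rows)

# ---- show methods ----

setMethod("show", "DemRaster", function(object) {
    d <- dim(object@elevation)
    fin <- object@elevation[is.finite(object@elevation)]
    cat(sprintf("DemRaster: %d x %d pixels at %.4g m/pixel (%s)\n",
                d[1], d[2], object@dp, object@crsNote))
    cat(sprintf("  origin (NW corner): (%.3f, %.3f)\n",
                object@origin[1], object@origin[2]))
    if (length(fin))
        cat(sprintf("  elevation range: [%.3f, %.3f] m; %d no-data pixels\n",
                    min(fin), max(fin), sum(!is.finite(object@elevation))))
})

setMethod("show", "PointCloud3D", function(object) {
    cat(sprintf("PointCloud3D: %d points%s\n", nrow(object@xyz),
                if (nrow(object@color)) " (colored)" else ""))
    if (nrow(object@xyz)) {
        rg <- apply(object@xyz, 2, range)
        cat(sprintf("  x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] m\n",
                    rg[1, 1], rg[2, 1], rg[1, 2], rg[2, 2], rg[1, 3], rg[2, 3]))
    }
})

setMethod("show", "SiteConfig", function(object) {
    cat(sprintf(
        "SiteConfig: %.2f x %.2f m spacing, azimuth %.1f deg, %d plants/cell\n",
        object@interRow, object@intraRow, object@rowAzimuth,
        object@plantsPerCell))
    cat(sprintf("  cordon %.2f m | gap threshold %.2f m | alpha %.2f m\n",
                object@cordonHeight, object@thicknessThreshold, object@alpha))
})

setMethod("show", "VineGrid", function(object) {
    cat(sprintf("VineGrid: %d cells on %d rows (%.2f x %.2f m each)\n",
                nrow(object@cells), length(unique(object@cells$rowId)),
                2 * object@cells$halfWidth[1],
                object@cells$a1[1] - object@cells$a0[1]))
})

setMethod("show", "VineyardTruth", function(object) {
    vr <- object@vineRecords
    cat(sprintf(
        "VineyardTruth: %d slots on %d rows, %d present, %d missing (seed %d)\n",
        nrow(vr), length(unique(vr$rowId)), sum(vr$present),
        sum(!vr$present), object@seed))
})
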