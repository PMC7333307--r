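#' Write a per-cell report (CSV + GeoJSON)
#'
#' Writes one CSV row per grid cell (cell id, row id, method tag, volume in
#' m^3, missing-plant count) and a companion GeoJSON FeatureCollection of the
#' cell polygons carrying the same attributes, for thematic mapping of
#' missing plants.  The GeoJSON path is the CSV path with its extension
#' replaced by \code{.geojson}.
#'
#' @param metrics data.frame with at least \code{cellId}, \code{rowId},
#'   \code{method}, \code{volume}, \code{nMissing}
#' @param grid the \linkS4class{VineGrid} the cells belong to
#' @param path output CSV path
#' @return invisibly, c(csv = path, geojson = derived path)
#' @export
writeCellReport <- function(metrics, grid, path) {
    if (!is.data.frame(metrics) || nrow(metrics) == 0L)
        stop("metrics must be a non-empty data.frame")
    need <- c("cellId", "rowId", "method", "volume", "nMissing")
    if (!all(need %in% names(metrics)))
        stop("metrics must contain columns: ", paste(need, collapse = ", "))
    out <- metrics[, need]
    write.csv(out, path, row.names = FALSE, quote = FALSE)

    polys <- cellPolygons(grid)
    gj <- sub("\\.[^.]+$", ".geojson", path)
    idx <- match(out$cellId, cells(grid)$cellId)
    if (any(is.na(idx))) stop("metrics contain cellIds not in the grid")
    feats <- lapply(seq_len(nrow(out)), function(i) {
        p <- polys[[idx[i]]]
        ring <- rbind(p, p[1, , drop = FALSE])
        list(type = "Feature",
             properties = list(cellId = out$cellId[i], rowId = out$rowId[i],
                               method = out$method[i],
                               volume = out$volume[i],
                               nMissing = out$nMissing[i]),
             geometry = list(type = "Polygon",
                             coordinates = list(lapply(seq_len(nrow(ring)),
                                 function(k) c(ring[k, 1], ring[k, 2])))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         gj, auto_unbox = TRUE, digits = NA)
    invisible(c(csv = path, geojson = gj))
}

#' Read cell polygons back from a report GeoJSON
#'
#' @param path a GeoJSON file written by [writeCellReport()] (or any
#'   FeatureCollection of simple polygons)
#' @return list with \code{polygons} (list of n x 2 vertex matrices, closing
#'   vertex dropped) and \code{properties} (data.frame)
#' @export
readCellGeoJSON <- function(path) {
    g <- jsonlite::read_json(path)
    if (is.null(g$type) || g$type != "FeatureCollection")
        stop("not a GeoJSON FeatureCollection: ", path)
    polys <- lapply(g$features, function(f) {
        ring <- f$geometry$coordinates[[1]]
        m <- do.call(rbind, lapply(ring, function(v)
            c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
        m[-nrow(m), , drop = FALSE]   # drop closing vertex
    })
    props <- do.call(rbind, lapply(g$features, function(f)
        as.data.frame(f$properties, stringsAsFactors = FALSE)))
    list(polygons = polys, properties = props)
}

#' Read geolocated missing-plant ground truth
#'
#' Accepts a CSV with \code{x}, \code{y} columns or a GeoJSON
#' FeatureCollection of Point features, in the same local metric frame as
#' the rasters/clouds.
#'
#' @param path input path
#' @return numeric matrix (n x 2) of world (x, y)
#' @export
readMissingPlantPoints <- function(path) {
    if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE)) {
        g <- jsonlite::read_json(path)
        pts <- do.call(rbind, lapply(g$features, function(f) {
            cc <- f$geometry$coordinates
            c(as.numeric(cc[[1]]), as.numeric(cc[[2]]))
        }))
    } else {
        d <- read.csv(path)
        if (!all(c("x", "y") %in% names(d)))
            stop("CSV must have x and y columns: ", path)
        pts <- as.matrix(d[, c("x", "y")])
    }
    if (is.null(pts)) pts <- matrix(numeric(), 0, 2)
    colnames(pts) <- c("x", "y")
    pts
}

#' Write missing-plant points as GeoJSON
#'
#' @param pts numeric matrix (n x 2) of world (x, y)
#' @param path output GeoJSON path
#' @return \code{path}, invisibly
#' @export
writeMissingPlantPoints <- function(pts, path) {
    feats <- lapply(seq_len(nrow(pts)), function(i)
        list(type = "Feature", properties = list(id = i),
             geometry = list(type = "Point",
                             coordinates = c(pts[i, 1], pts[i, 2]))))
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read per-vine validation measurements
#'
#' CSV with columns \code{vine_id}, \code{CH}, \code{CT}, \code{CL}
#' (meters) and optionally \code{observed_volume} (m^3).  When
#' \code{observed_volume} is present it must equal \code{CH * CT * CL}
#' (the cuboid ground-measurement model) to 1e-9, otherwise the file is
#' rejected.
#'
#' @param path CSV path
#' @return data.frame with an \code{observed_volume} column (computed when
#'   absent)
#' @export
readVineMeasurements <- function(path) {
    d <- read.csv(path)
    need <- c("vine_id", "CH", "CT", "CL")
    if (!all(need %in% names(d)))
        stop("CSV must have columns: ", paste(need, collapse = ", "))
    vol <- d$CH * d$CT * d$CL
    if ("observed_volume" %in% names(d)) {
        if (any(abs(d$observed_volume - vol) > 1e-9))
            stop("observed_volume inconsistent with CH*CT*CL: ", path)
    } else d$observed_volume <- vol
    d
}
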