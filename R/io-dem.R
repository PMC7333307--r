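#' Read a digital elevation model
#'
#' Reads an ESRI ASCII grid (\code{.asc}/\code{.agr}/\code{.grd} or any text
#' file with the standard \code{ncols/nrows/xllcorner/yllcorner/cellsize}
#' header) into a \linkS4class{DemRaster}.  The ASCII grid stores rows north
#' to south, which matches the DemRaster convention directly.  Files using
#' the rectangular-pixel variant (\code{dx}/\code{dy} headers with
#' \code{dx != dy}) are rejected, as are GeoTIFFs (no GDAL-backed reader is
#' available; convert to ASCII grid, which is lossless).
#'
#' @param path path to the raster file
#' @return a \linkS4class{DemRaster}; no-data cells are \code{NA}
#' @seealso [writeDem()]
#' @export
readDem <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (grepl("\\.tiff?$", path, ignore.case = TRUE))
        stop("GeoTIFF input is not supported (no GDAL reader available); ",
             "export the DEM as an ESRI ASCII grid instead")
    con <- file(path, "r")
    on.exit(close(con))
    hdr <- list()
    nHeader <- 0L
    repeat {
        pos <- seek(con)
        line <- readLines(con, n = 1L)
        if (!length(line)) stop("unexpected end of file in header: ", path)
        tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
        if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
            hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
            nHeader <- nHeader + 1L
        } else break
    }
    need <- c("ncols", "nrows", "xllcorner", "yllcorner")
    if (!all(need %in% names(hdr)))
        stop("missing georeference header (need ",
             paste(need, collapse = ", "), "): ", path)
    if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
        if (is.null(hdr$dx) || is.null(hdr$dy) || hdr$dx != hdr$dy)
            stop("rectangular pixels (dx != dy) are not supported: ", path)
        dp <- hdr$dx
    } else if (!is.null(hdr$cellsize)) {
        dp <- hdr$cellsize
    } else stop("missing cellsize in header: ", path)
    nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999

    seek(con, pos)
    vals <- scan(con, what = numeric(), quiet = TRUE)
    nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
    if (length(vals) != nc * nr)
        stop(sprintf("expected %d values, found %d: %s", nc * nr,
                     length(vals), path))
    m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
    m[m == nodata] <- NA_real_
    origin <- c(hdr$xllcorner, hdr$yllcorner + nr * dp)  # NW outer corner
    DemRaster(m, dp = dp, origin = origin)
}

#' Write a digital elevation model
#'
#' Writes a \linkS4class{DemRaster} as an ESRI ASCII grid.  \code{NA} cells
#' are written as the no-data sentinel (-9999).  The round trip
#' \code{readDem(writeDem(x))} reproduces the grid exactly (values are
#' printed with 17 significant digits).
#'
#' @param dem a \linkS4class{DemRaster}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeDem <- function(dem, path) {
    stopifnot(is(dem, "DemRaster"))
    m <- dem@elevation
    nr <- nrow(m); nc <- ncol(m)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        sprintf("ncols %d", nc),
        sprintf("nrows %d", nr),
        sprintf("xllcorner %.17g", dem@origin[1]),
        sprintf("yllcorner %.17g", dem@origin[2] - nr * dem@dp),
        sprintf("cellsize %.17g", dem@dp),
        "NODATA_value -9999"), con)
    m[!is.finite(m)] <- -9999
    for (r in seq_len(nr))
        writeLines(paste(sprintf("%.17g", m[r, ]), collapse = " "), con)
    invisible(path)
}

# world coordinates of all pixel centers; returns list(x = col centers,
# y = row centers) following the north-up convention
demPixelCenters <- function(dem) {
    d <- dim(dem@elevation)
    list(x = dem@origin[1] + (seq_len(d[2]) - 0.5) * dem@dp,
         y = dem@origin[2] - (seq_len(d[1]) - 0.5) * dem@dp)
}
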