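#' Read a 3D point cloud
#'
#' Supports whitespace-delimited XYZ[RGB] text (\code{.xyz}, \code{.txt},
#' \code{.csv} with no header) and PLY files (\code{ascii} or
#' \code{binary_little_endian}).  LAS/LAZ are not supported in this build
#' (no reader available); convert to PLY or XYZ text.  Point order is
#' preserved as stored and units are passed through unchanged (meters
#' assumed).
#'
#' @param path path to the cloud file
#' @return a \linkS4class{PointCloud3D}
#' @seealso [writeCloud()]
#' @export
readCloud <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ext <- tolower(sub(".*\\.", "", path))
    if (ext %in% c("las", "laz"))
        stop("LAS/LAZ input is not supported; convert to PLY or XYZ text")
    if (ext == "ply") return(readPly(path))
    if (!ext %in% c("xyz", "txt", "csv", "pts"))
        stop("unknown point-cloud extension '.", ext, "'")
    readXyzText(path)
}

readXyzText <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no points in file: ", path)
    sep <- if (grepl(",", lines[1])) "," else "[[:space:]]+"
    rows <- strsplit(trimws(lines), sep)
    nf <- lengths(rows)
    if (any(nf != nf[1]))
        stop("malformed record at line ", which(nf != nf[1])[1], ": ", path)
    if (!nf[1] %in% c(3L, 6L))
        stop("expected 3 (xyz) or 6 (xyzrgb) fields, found ", nf[1])
    v <- suppressWarnings(as.numeric(unlist(rows)))
    bad <- which(is.na(v))
    if (length(bad))
        stop("malformed record at line ", ceiling(bad[1] / nf[1]), ": ", path)
    m <- matrix(v, ncol = nf[1], byrow = TRUE)
    col <- if (nf[1] == 6L) {
        cc <- m[, 4:6, drop = FALSE]
        if (max(cc) > 1) cc <- cc / 255
        cc
    } else NULL
    PointCloud3D(m[, 1:3, drop = FALSE], color = col)
}

readPly <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    readHeaderLine <- function() {
        chars <- raw()
        repeat {
            b <- readBin(con, "raw", 1)
            if (!length(b) || b == as.raw(10)) break
            chars <- c(chars, b)
        }
        sub("\r$", "", rawToChar(chars))
    }
    if (readHeaderLine() != "ply") stop("not a PLY file: ", path)
    fmt <- NULL; nVert <- NULL; inVertex <- FALSE
    props <- character(); propTypes <- character()
    otherElements <- FALSE
    repeat {
        line <- readHeaderLine()
        tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
        if (!length(tok)) next
        if (tok[1] == "comment") next
        if (tok[1] == "format") fmt <- tok[2]
        else if (tok[1] == "element") {
            inVertex <- tok[2] == "vertex"
            if (inVertex) nVert <- as.integer(tok[3])
            else if (as.integer(tok[3]) > 0) otherElements <- TRUE
        } else if (tok[1] == "property" && inVertex) {
            propTypes <- c(propTypes, tok[2])
            props <- c(props, tok[3])
        } else if (tok[1] == "end_header") break
    }
    if (is.null(fmt) || is.null(nVert)) stop("malformed PLY header: ", path)
    if (!all(c("x", "y", "z") %in% props))
        stop("PLY vertex element lacks x/y/z properties: ", path)
    if (nVert == 0L) stop("no points in file: ", path)

    sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
               ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
               int32 = 4, uint32 = 4, float = 4, float32 = 4, double = 8,
               float64 = 8)
    if (fmt == "ascii") {
        vals <- scan(con, what = numeric(), n = nVert * length(props),
                     quiet = TRUE)
        if (length(vals) < nVert * length(props))
            stop("truncated PLY vertex data (record ",
                 floor(length(vals) / length(props)) + 1, "): ", path)
        m <- matrix(vals, ncol = length(props), byrow = TRUE)
    } else if (fmt == "binary_little_endian") {
        if (!all(propTypes %in% names(sizes)))
            stop("unsupported PLY property type: ",
                 paste(setdiff(propTypes, names(sizes)), collapse = ", "))
        stride <- sum(sizes[propTypes])
        blob <- readBin(con, "raw", n = nVert * stride)
        if (length(blob) < nVert * stride)
            stop("truncated PLY vertex data (record ",
                 floor(length(blob) / stride) + 1, "): ", path)
        m <- matrix(NA_real_, nVert, length(props))
        off <- 0L
        for (j in seq_along(props)) {
            sz <- sizes[[propTypes[j]]]
            idx <- as.vector(outer(seq_len(sz) + off,
                                   (seq_len(nVert) - 1L) * stride, "+"))
            sub <- blob[idx]
            m[, j] <- switch(propTypes[j],
                float = , float32 = readBin(sub, "double", nVert, size = 4,
                                            endian = "little"),
                double = , float64 = readBin(sub, "double", nVert, size = 8,
                                             endian = "little"),
                char = , int8 = readBin(sub, "integer", nVert, size = 1,
                                        signed = TRUE, endian = "little"),
                uchar = , uint8 = readBin(sub, "integer", nVert, size = 1,
                                          signed = FALSE, endian = "little"),
                short = , int16 = readBin(sub, "integer", nVert, size = 2,
                                          signed = TRUE, endian = "little"),
                ushort = , uint16 = readBin(sub, "integer", nVert, size = 2,
                                            signed = FALSE, endian = "little"),
                readBin(sub, "integer", nVert, size = 4, endian = "little"))
            off <- off + sz
        }
    } else stop("unsupported PLY format '", fmt, "'")
    xyz <- m[, match(c("x", "y", "z"), props), drop = FALSE]
    col <- if (all(c("red", "green", "blue") %in% props)) {
        cc <- m[, match(c("red", "green", "blue"), props), drop = FALSE]
        if (max(cc) > 1) cc <- cc / 255
        cc
    } else NULL
    PointCloud3D(xyz, color = col)
}

#' Write a 3D point cloud
#'
#' Writes XYZ[RGB] text (\code{.xyz}/\code{.txt}) or ascii PLY
#' (\code{.ply}).  Coordinates are printed with enough digits for a
#' round trip well below 1e-6 m.
#'
#' @param cloud a \linkS4class{PointCloud3D}
#' @param path output path; format chosen from the extension
#' @return \code{path}, invisibly
#' @export
writeCloud <- function(cloud, path) {
    stopifnot(is(cloud, "PointCloud3D"))
    ext <- tolower(sub(".*\\.", "", path))
    xyz <- cloud@xyz
    hasCol <- nrow(cloud@color) > 0
    if (ext == "ply") {
        con <- file(path, "wb")
        on.exit(close(con))
        hdr <- c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(xyz)),
                 "property double x", "property double y",
                 "property double z")
        if (hasCol)
            hdr <- c(hdr, "property uchar red", "property uchar green",
                     "property uchar blue")
        hdr <- c(hdr, "end_header")
        writeLines(hdr, con)
        body <- if (hasCol)
            sprintf("%.12f %.12f %.12f %d %d %d", xyz[, 1], xyz[, 2],
                    xyz[, 3], round(cloud@color[, 1] * 255),
                    round(cloud@color[, 2] * 255),
                    round(cloud@color[, 3] * 255))
        else sprintf("%.12f %.12f %.12f", xyz[, 1], xyz[, 2], xyz[, 3])
        writeLines(body, con)
    } else if (ext %in% c("xyz", "txt")) {
        body <- if (hasCol)
            sprintf("%.12f %.12f %.12f %.6f %.6f %.6f", xyz[, 1], xyz[, 2],
                    xyz[, 3], cloud@color[, 1], cloud@color[, 2],
                    cloud@color[, 3])
        else sprintf("%.12f %.12f %.12f", xyz[, 1], xyz[, 2], xyz[, 3])
        writeLines(body, path)
    } else stop("unsupported output extension '.", ext, "'")
    invisible(path)
}
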