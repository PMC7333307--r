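#' Build the uniform polygon grid over vine rows
#'
#' Starting from the midpoint between adjacent rows, each cell is a
#' rectangle centered on a row axis spanning the full inter-row width
#' across the row and \code{plantsPerCell * intraRow} along it.  Cells tile
#' each row from its start coordinate; along-row intervals are half-open
#' (ties at a shared boundary belong to the lower-index cell).  Terminal
#' leftovers are dropped by default; with \code{keepPartial = TRUE} a
#' terminal partial cell at least one plant slot long is kept, carrying a
#' prorated slot count in \code{nSlots}.
#'
#' @param rows data.frame of row axes with columns \code{rowId},
#'   \code{x0}, \code{y0}, \code{x1}, \code{y1} (world meters), e.g. from
#'   [rowAxes()]; rows must be parallel within 1 degree
#' @param cfg a \linkS4class{SiteConfig}
#' @param keepPartial keep a terminal partial cell (>= one slot long)?
#' @return a \linkS4class{VineGrid}
#' @examples
#' cfg <- siteConfig(interRow = 2.5, intraRow = 0.9)
#' rows <- data.frame(rowId = 1, x0 = 0, y0 = 0, x1 = 27, y1 = 0)
#' grid <- buildGrid(rows, cfg)   # 10 cells of 2.5 x 2.7 m
#' @export
buildGrid <- function(rows, cfg, keepPartial = FALSE) {
    stopifnot(is(cfg, "SiteConfig"))
    need <- c("rowId", "x0", "y0", "x1", "y1")
    if (!all(need %in% names(rows)))
        stop("rows must have columns: ", paste(need, collapse = ", "))
    if (nrow(rows) < 1L) stop("at least one row is required")
    dx <- rows$x1 - rows$x0
    dy <- rows$y1 - rows$y0
    len <- sqrt(dx^2 + dy^2)
    if (any(len <= 0)) stop("zero-length row axis")
    ang <- atan2(dy, dx)
    rel <- (ang - ang[1] + pi / 2) %% pi - pi / 2    # mod 180 deg
    if (any(abs(rel) > pi / 180))
        stop("rows are not parallel within 1 degree")

    cellLen <- cfg@plantsPerCell * cfg@intraRow
    out <- NULL
    for (i in seq_len(nrow(rows))) {
        u <- c(dx[i], dy[i]) / len[i]
        nFull <- floor(len[i] / cellLen + 1e-9)
        a0 <- (seq_len(nFull) - 1) * cellLen
        a1 <- seq_len(nFull) * cellLen
        nSlots <- rep(cfg@plantsPerCell, nFull)
        rest <- len[i] - nFull * cellLen
        if (keepPartial && rest >= cfg@intraRow - 1e-9) {
            a0 <- c(a0, nFull * cellLen)
            a1 <- c(a1, len[i])
            nSlots <- c(nSlots, as.integer(floor(rest / cfg@intraRow + 1e-9)))
        }
        if (!length(a0)) next
        out <- rbind(out, data.frame(
            rowId = rows$rowId[i], cellIndex = seq_along(a0),
            x0 = rows$x0[i], y0 = rows$y0[i], ux = u[1], uy = u[2],
            a0 = a0, a1 = a1, halfWidth = cfg@interRow / 2,
            nSlots = nSlots))
    }
    if (is.null(out)) stop("no complete cells fit in any row")
    mid <- (out$a0 + out$a1) / 2
    out$cx <- out$x0 + mid * out$ux
    out$cy <- out$y0 + mid * out$uy
    out$cellId <- sprintf("r%02d_c%03d", out$rowId, out$cellIndex)
    out <- out[, c("cellId", "rowId", "cellIndex", "x0", "y0", "ux", "uy",
                   "a0", "a1", "halfWidth", "nSlots", "cx", "cy")]
    new("VineGrid", cells = out, config = cfg)
}

#' @rdname VineGrid-class
#' @export
setMethod("cellPolygons", "VineGrid", function(x) {
    cc <- x@cells
    lapply(seq_len(nrow(cc)), function(i) {
        u <- c(cc$ux[i], cc$uy[i])
        v <- c(u[2], -u[1])
        p0 <- c(cc$x0[i], cc$y0[i])
        w <- cc$halfWidth[i]
        m <- rbind(p0 + cc$a0[i] * u - w * v,
                   p0 + cc$a1[i] * u - w * v,
                   p0 + cc$a1[i] * u + w * v,
                   p0 + cc$a0[i] * u + w * v)
        colnames(m) <- c("x", "y")
        m
    })
})

# assign world points to cells; returns integer cell row index (into
# cells(grid)) or NA.  Half-open in both cell axes; ties go to the
# lower-index cell because rows/cells are scanned in order and the first
# match wins.
assignToCells <- function(xy, grid) {
    cc <- grid@cells
    xy <- matrix(as.numeric(xy), ncol = 2)
    res <- rep(NA_integer_, nrow(xy))
    for (i in seq_len(nrow(cc))) {
        u <- c(cc$ux[i], cc$uy[i])
        v <- c(u[2], -u[1])
        rx <- xy[, 1] - cc$x0[i]
        ry <- xy[, 2] - cc$y0[i]
        s <- rx * u[1] + ry * u[2]
        t <- rx * v[1] + ry * v[2]
        hit <- is.na(res) & s >= cc$a0[i] & s < cc$a1[i] &
            t >= -cc$halfWidth[i] & t < cc$halfWidth[i]
        res[hit] <- i
    }
    res
}

#' Potential number of plants of a site
#'
#' The number of plant positions implied by planting density and site
#' surface, rounded to the nearest integer.
#'
#' @param densityPerHa planting density (plants/ha)
#' @param surfaceHa site surface (ha)
#' @return integer count
#' @examples
#' potentialPlants(4444, 0.7)   # 3111
#' @export
potentialPlants <- function(densityPerHa, surfaceHa) {
    if (!is.finite(densityPerHa) || densityPerHa <= 0)
        stop("densityPerHa must be positive")
    if (!is.finite(surfaceHa) || surfaceHa <= 0)
        stop("surfaceHa must be positive")
    as.integer(roundHalfUp(densityPerHa * surfaceHa))
}
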