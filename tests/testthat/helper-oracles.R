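# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written along different computational routes than the package
# implementations they check.

# Brute-force alpha-shape volume: enumerate all C(n,4) tetrahedra, keep the
# Delaunay ones (no other point strictly inside the circumsphere) with
# circumradius <= alpha, and sum their volumes.  Fully vectorised over the
# 4-subsets (Cramer's rule for the circumcenters).
bruteAlphaVolume <- function(pts, alpha) {
    n <- nrow(pts)
    stopifnot(n >= 4)
    cmb <- utils::combn(n, 4)
    P1 <- pts[cmb[1, ], , drop = FALSE]
    P2 <- pts[cmb[2, ], , drop = FALSE]
    P3 <- pts[cmb[3, ], , drop = FALSE]
    P4 <- pts[cmb[4, ], , drop = FALSE]
    a1 <- 2 * (P2 - P1); a2 <- 2 * (P3 - P1); a3 <- 2 * (P4 - P1)
    b1 <- rowSums(P2^2) - rowSums(P1^2)
    b2 <- rowSums(P3^2) - rowSums(P1^2)
    b3 <- rowSums(P4^2) - rowSums(P1^2)
    D <- a1[, 1] * (a2[, 2] * a3[, 3] - a2[, 3] * a3[, 2]) -
         a1[, 2] * (a2[, 1] * a3[, 3] - a2[, 3] * a3[, 1]) +
         a1[, 3] * (a2[, 1] * a3[, 2] - a2[, 2] * a3[, 1])
    Dx <- b1 * (a2[, 2] * a3[, 3] - a2[, 3] * a3[, 2]) -
          a1[, 2] * (b2 * a3[, 3] - a2[, 3] * b3) +
          a1[, 3] * (b2 * a3[, 2] - a2[, 2] * b3)
    Dy <- a1[, 1] * (b2 * a3[, 3] - a2[, 3] * b3) -
          b1 * (a2[, 1] * a3[, 3] - a2[, 3] * a3[, 1]) +
          a1[, 3] * (a2[, 1] * b3 - b2 * a3[, 1])
    Dz <- a1[, 1] * (a2[, 2] * b3 - b2 * a3[, 2]) -
          a1[, 2] * (a2[, 1] * b3 - b2 * a3[, 1]) +
          b1 * (a2[, 1] * a3[, 2] - a2[, 2] * a3[, 1])
    vol <- abs(D) / 48                       # |det(P2-P1,P3-P1,P4-P1)|/6
    ok <- abs(D) > 1e-10
    cc <- cbind(Dx / D, Dy / D, Dz / D)
    r2 <- rowSums((cc - P1)^2)
    # strict-inside Delaunay test against every other point
    d2 <- outer(rowSums(cc^2), rep(1, n)) +
        outer(rep(1, nrow(cc)), rowSums(pts^2)) - 2 * cc %*% t(pts)
    for (k in 1:4) d2[cbind(seq_len(ncol(cmb)), cmb[k, ])] <- Inf
    minOther <- apply(d2, 1, min)
    delaunay <- minOther >= r2 * (1 - 1e-9)
    keep <- ok & delaunay & sqrt(r2) <= alpha
    sum(vol[keep])
}

# Brute-force Otsu: explicit two-class weighted within-class variance for
# every one of the 255 candidate thresholds over 256 bins.
bruteOtsu <- function(g, levels = 256L) {
    breaks <- seq(0, 1, length.out = levels + 1L)
    bin <- pmin(pmax(findInterval(g, breaks, rightmost.closed = TRUE), 1L),
                levels)
    mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
    wcv <- rep(Inf, levels - 1L)
    for (k in seq_len(levels - 1L)) {
        lo <- bin <= k
        n0 <- sum(lo); n1 <- sum(!lo)
        if (n0 == 0 || n1 == 0) next
        v0 <- mean((mids[bin[lo]] - mean(mids[bin[lo]]))^2)
        v1 <- mean((mids[bin[!lo]] - mean(mids[bin[!lo]]))^2)
        wcv[k] <- (n0 * v0 + n1 * v1) / (n0 + n1)
    }
    breaks[which.min(wcv) + 1L]
}
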