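#' Linear regression of observed against estimated canopy volumes
#'
#' Ordinary least squares of the observations on the estimates.  R^2 is
#' the squared Pearson correlation.  By default RMSE is the agreement
#' RMSE — the root mean squared difference between the paired values —
#' which is the relevant number when comparing one method's volumes with
#' another's (or with ground measurements) around the 1:1 line;
#' \code{rmseType = "residual"} gives the regression-residual RMSE
#' instead.
#'
#' @param estimates numeric vector of estimated volumes (m^3)
#' @param observations numeric vector of observed volumes (m^3)
#' @param rmseType "agreement" (default) or "residual"
#' @return list with \code{slope}, \code{intercept}, \code{rSquared},
#'   \code{rmse}, \code{n}
#' @examples
#' volumeRegression(c(1, 2, 3), c(2, 4, 6))   # R^2 = 1, rmse = sqrt(14/3)
#' @export
volumeRegression <- function(estimates, observations,
                             rmseType = c("agreement", "residual")) {
    rmseType <- match.arg(rmseType)
    if (length(estimates) != length(observations))
        stop("estimates and observations must have equal length")
    if (length(estimates) < 3L) stop("need at least 3 pairs")
    if (sd(estimates) == 0 || sd(observations) == 0)
        stop("zero variance in estimates or observations")
    fit <- lm(observations ~ estimates)
    r2 <- cor(estimates, observations)^2
    rmse <- if (rmseType == "agreement")
        sqrt(mean((estimates - observations)^2))
    else sqrt(mean(fit$residuals^2))
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         rSquared = r2, rmse = rmse, n = length(estimates))
}

#' Signed accuracy of an estimated count against ground truth
#'
#' \code{(estimated - observed) / observed * 100}, rounded half-up to two
#' decimals: positive for overestimation, negative for underestimation.
#'
#' @param estimated estimated count
#' @param observed ground-truth count, > 0
#' @return signed percentage (2 decimals)
#' @examples
#' accuracyPercent(446, 521)   # -14.40
#' accuracyPercent(553, 521)   # 6.14
#' @export
accuracyPercent <- function(estimated, observed) {
    if (!is.finite(observed) || observed <= 0)
        stop("observed must be positive")
    roundHalfUp((estimated - observed) / observed * 100, 2)
}

#' Observed missing plants as a percentage of potential plants
#'
#' @param observed observed missing-plant count
#' @param potential potential plant count, > 0
#' @return percentage (2 decimals)
#' @examples
#' pctOfPotential(521, 3111)   # 16.75
#' @export
pctOfPotential <- function(observed, potential) {
    if (!is.finite(potential) || potential <= 0)
        stop("potential must be positive")
    roundHalfUp(observed / potential * 100, 2)
}

#' Mean canopy volume per detected vine
#'
#' Total site canopy volume divided by the number of plants detected
#' (potential plants minus estimated missing plants).
#'
#' @param totalVolume summed canopy volume of the site (m^3)
#' @param potential potential plant count
#' @param estimatedMissing estimated missing-plant count
#' @return m^3 per vine
#' @export
meanCanopyVolumePerVine <- function(totalVolume, potential,
                                    estimatedMissing) {
    det <- potential - estimatedMissing
    if (!is.finite(det) || det <= 0)
        stop("no plants detected (potential <= estimated missing)")
    totalVolume / det
}

#' Compare per-cell missing-plant counts with geolocated ground truth
#'
#' Counts the ground-truth missing-plant points falling in each cell
#' (half-open cell rectangles, so each point lands in at most one cell)
#' and summarises agreement with the per-cell estimates.  Truth points
#' outside every cell are reported in the \code{unassigned} bucket.
#'
#' @param metrics per-cell data.frame with \code{cellId} and
#'   \code{nMissing} (from [runMethod25D()] or [runMethod3D()])
#' @param truthPoints n x 2 matrix of world (x, y) of missing plants
#' @param grid the \linkS4class{VineGrid}
#' @return list with \code{perCell} (data.frame: cellId, estimated,
#'   observed, error), \code{estimatedTotal}, \code{observedTotal} (only
#'   points inside cells), \code{unassigned}, \code{accuracyPct} (signed,
#'   \code{NA} when nothing observed), \code{cellsOver}, \code{cellsUnder}
#' @export
matchGroundTruth <- function(metrics, truthPoints, grid) {
    cc <- cells(grid)
    truthPoints <- matrix(as.numeric(truthPoints), ncol = 2)
    idx <- if (nrow(truthPoints)) assignToCells(truthPoints, grid)
           else integer()
    unassigned <- sum(is.na(idx))
    if (unassigned)
        message(unassigned, " ground-truth points fall outside all cells")
    obs <- tabulate(idx[!is.na(idx)], nbins = nrow(cc))
    m <- match(cc$cellId, metrics$cellId)
    est <- metrics$nMissing[m]
    est[is.na(est)] <- 0L
    perCell <- data.frame(cellId = cc$cellId, estimated = est,
                          observed = obs, error = est - obs)
    obsTotal <- sum(obs)
    list(perCell = perCell,
         estimatedTotal = sum(est), observedTotal = obsTotal,
         unassigned = unassigned,
         accuracyPct = if (obsTotal > 0)
             accuracyPercent(sum(est), obsTotal) else NA_real_,
         cellsOver = sum(perCell$error > 0),
         cellsUnder = sum(perCell$error < 0))
}
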