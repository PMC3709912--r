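#' Zung self-rating index score
#'
#' Converts a raw Zung scale sum (20 items scored 1-4, so 20-80) to the
#' index score by multiplying by 1.25.  Index scores below 53 (SDS,
#' depression) or 50 (SAS, anxiety) are in the normal range.
#'
#' @param raw raw sum score(s) in \code{[20, 80]}.
#' @param scale \code{"sds"} or \code{"sas"} (sets the normal-range cutoff).
#' @return data.frame with \code{raw}, \code{index} (25-100) and
#'   \code{normal} flag.
#' @export
#' @examples
#' zungIndex(42, "sds")   # index 52.5, normal (52.5 < 53)
zungIndex <- function(raw, scale = c("sds", "sas")) {
  scale <- match.arg(scale)
  if (any(raw < 20 | raw > 80))
    stop("raw Zung score must lie in [20, 80]")
  index <- raw * 1.25
  cutoff <- if (scale == "sds") 53 else 50
  data.frame(raw = raw, index = index, normal = index < cutoff)
}

#' Spherical ROI at a cluster's peak weight
#'
#' Centres a sphere of \code{radiusMM} at the in-cluster voxel with the
#' largest |weight| (ties break to the lowest linear index) and resolves it
#' to the gray-matter voxels whose centres lie within the radius.
#'
#' @param wmap observed [WeightMap-class].
#' @param cluster one element of the [extractClusters()] result (or any
#'   list with a \code{voxels} field).
#' @param radiusMM sphere radius in mm (default 6); 0 gives the peak voxel
#'   alone.
#' @param voxelSizeMM grid voxel size in mm.
#' @param gmMask optional logical mask to intersect with (defaults to the
#'   weight map's feature mask).
#' @return list: \code{centerVox}, \code{centerMM}, \code{radiusMM},
#'   \code{voxels} (linear indices of the resolved sphere).
#' @export
peakROI <- function(wmap, cluster, radiusMM = 6, voxelSizeMM = 3,
                    gmMask = NULL) {
  if (length(cluster$voxels) == 0L) stop("cluster is empty")
  if (is.null(gmMask)) gmMask <- wmap@mask
  d <- dim(wmap@mask)
  aw <- abs(wmap@wVoxel[cluster$voxels])
  peak <- min(cluster$voxels[aw == max(aw)])   # tie: lowest linear index
  pc <- drop(gridCoords(peak, d))
  sph <- sphereMask(pc, radiusMM, d, voxelSizeMM) & gmMask
  vox <- which(sph)
  if (length(vox) == 0L) stop("resolved ROI sphere contains no mask voxels")
  list(centerVox = pc, centerMM = drop(voxelToWorld(pc, d, voxelSizeMM)),
       radiusMM = radiusMM, voxels = vox)
}

#' Mean normalised ReHo inside an ROI
#'
#' @param reho a [ReHoMap-class] (normalised values are used).
#' @param roi an ROI from [peakROI()] (or any list with \code{voxels}).
#' @return scalar mean over the ROI voxels that are computable.
#' @export
meanRehoInROI <- function(reho, roi) {
  vox <- roi$voxels[reho@computable[roi$voxels]]
  if (length(vox) == 0L) stop("no computable voxels inside the ROI")
  mean(reho@normalized[vox])
}

#' Pearson correlation with a two-tailed t-test
#'
#' Product-moment r and its two-tailed p from the t-distribution with
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3, neither constant.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
pearsonCorrelation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bonferroni adjustment
#'
#' \code{p_adj = min(1, p * m)}; significant when \code{p_adj < alpha}.
#'
#' @param pRaw raw p-values.
#' @param m number of tests (default \code{length(pRaw)}).
#' @param alpha significance level after correction (default 0.01).
#' @return data.frame with \code{p_raw}, \code{p_adjusted},
#'   \code{significant}.
#' @export
bonferroniAdjust <- function(pRaw, m = length(pRaw), alpha = 0.01) {
  stopifnot(m >= 1)
  pAdj <- pmin(1, pRaw * m)
  data.frame(p_raw = pRaw, p_adjusted = pAdj, significant = pAdj < alpha)
}

#' Correlate ROI ReHo with symptom measures across patients
#'
#' For each ROI, extracts each patient's mean normalised ReHo and computes
#' the Pearson correlation with each behavioural variable.  Controls are
#' excluded (the symptom scales are patient measures).  Bonferroni
#' correction uses m = (number of ROIs) x (number of variables); the raw
#' per-test threshold variant (\code{p_raw < alpha / m}) is available via
#' \code{rawThreshold = TRUE} (equivalent decisions, reported for
#' completeness).
#'
#' @param rehoMaps list of per-subject [ReHoMap-class] (cohort order).
#' @param rois list of ROIs from [peakROI()].
#' @param pheno phenotype data.frame with a \code{group} column.
#' @param variables character names of phenotype columns to correlate
#'   (default \code{c("ndi", "duration_months")}).
#' @param alpha corrected significance level (default 0.01).
#' @param rawThreshold compare raw p against \code{alpha / m} instead.
#' @return data.frame: roi, variable, n, r, p_raw, p_adjusted, significant.
#' @export
roiCorrelations <- function(rehoMaps, rois, pheno,
                            variables = c("ndi", "duration_months"),
                            alpha = 0.01, rawThreshold = FALSE) {
  pat <- which(pheno$group == "patient")
  rows <- list()
  for (ri in seq_along(rois)) {
    vals <- vapply(pat, function(s) meanRehoInROI(rehoMaps[[s]], rois[[ri]]),
                   numeric(1))
    for (v in variables) {
      ct <- pearsonCorrelation(vals, pheno[[v]][pat])
      rows[[length(rows) + 1L]] <- data.frame(
        roi = ri, variable = v, n = ct$n, r = ct$r, p_raw = ct$p)
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out$significant <- if (rawThreshold) out$p_raw < alpha / m
  else out$p_adjusted < alpha
  out
}
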