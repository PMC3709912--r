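#' Observed discriminative weight map
#'
#' Trains PCA (all N - 1 components) and the linear SVM on the full data set
#' with the true labels, then back-projects the reduced-space weight vector
#' to voxel space: \code{w_voxel = U w}.  Because U has orthonormal columns
#' the identity \code{<w_voxel, x_i - xbar> = <w, y_i>} holds for every
#' training subject and \code{||w_voxel|| = ||w||}.
#'
#' @param se feature \code{SummarizedExperiment} from [buildFeatureMatrix()].
#' @param C SVM box constraint (default 1).
#' @return a [WeightMap-class].
#' @export
observedWeightMap <- function(se, C = 1) {
  X <- featureX(se)
  labels <- featureLabels(se)
  pca <- fitPCA(X)
  Y <- projectPCA(pca, X)
  svmFit <- trainSVM(Y, labels, C = C)
  md <- S4Vectors::metadata(se)
  wv <- array(0, md$dim)
  wv[md$voxelIndex] <- drop(pca@rotation %*% svmFit@w)
  new("WeightMap", wVoxel = wv, mask = md$mask, wReduced = svmFit@w,
      pca = pca, svm = svmFit)
}

#' Permutation null for the discriminative map
#'
#' For each of \code{nPerm} label permutations (uniform over permutations of
#' the label vector, so group sizes are preserved; seeded) the PCA + SVM is
#' retrained on all subjects and the weight vector back-projected.  PCA is
#' label-free, so its basis is identical across permutations and is computed
#' once.  Because the scale of an SVM weight vector is inversely tied to the
#' attained margin (not to the strength of the pattern), every stored map is
#' normalised to unit L2 norm over the mask: inference compares pattern
#' direction, which is what the discriminative map carries.  Each permuted
#' map is additionally thresholded at its own
#' rank-based voxel-level criterion (the top \code{voxelAlpha} fraction of
#' |w| across mask voxels) and the maximum surviving connected-component
#' size is recorded, yielding the max-cluster-size null distribution.
#'
#' @param se feature \code{SummarizedExperiment}.
#' @param nPerm number of permutations (default 5000; a warning is issued
#'   below 100, and when \code{nPerm < 1/clusterAlpha} cluster p-values
#'   cannot resolve the requested level).
#' @param voxelAlpha voxel-level threshold (default 0.02).
#' @param clusterAlpha cluster-level threshold (default 0.001).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26).
#' @param C SVM box constraint.
#' @param seed integer seed for the permutation stream.
#' @param thresholdBy \code{"own_quantile"} (default; rank-based within each
#'   permuted map) or \code{"observed_null"} (threshold permuted maps at the
#'   voxelwise critical values of the permutation null itself).
#' @return list: \code{nullW} (nPerm x D matrix of permuted voxel weights),
#'   \code{maxClusterSizes} (per permutation), \code{nPerm},
#'   \code{voxelAlpha}, \code{connectivity}, \code{seed}.
#' @export
permutationNull <- function(se, nPerm = 5000L, voxelAlpha = 0.02,
                            clusterAlpha = 0.001, connectivity = 26L,
                            C = 1, seed = 1L,
                            thresholdBy = c("own_quantile", "observed_null")) {
  thresholdBy <- match.arg(thresholdBy)
  stopifnot(voxelAlpha > 0, voxelAlpha < 1, clusterAlpha > 0, clusterAlpha < 1)
  if (nPerm < 100L) warning("nPerm < 100: permutation p-values will be coarse")
  if (nPerm < 1 / clusterAlpha)
    warning("nPerm < 1/clusterAlpha: the requested cluster level (",
            clusterAlpha, ") cannot be resolved with ", nPerm, " permutations")
  X <- featureX(se)
  labels <- featureLabels(se)
  md <- S4Vectors::metadata(se)
  D <- ncol(X); N <- nrow(X)
  pca <- fitPCA(X)
  Y <- projectPCA(pca, X)
  U <- pca@rotation

  set.seed(as.integer(seed))
  nullW <- matrix(0, nPerm, D)
  for (p in seq_len(nPerm)) {
    labp <- labels[sample.int(N)]
    sv <- trainSVM(Y, labp, C = C)
    wv <- drop(U %*% sv@w)
    nrm <- sqrt(sum(wv^2))
    nullW[p, ] <- if (nrm > 0) wv / nrm else wv
  }

  k <- max(1L, floor(voxelAlpha * D))
  maxSizes <- integer(nPerm)
  maskIdx <- md$voxelIndex
  if (thresholdBy == "observed_null") {
    # voxelwise critical |w|: the (1 - voxelAlpha) quantile of each voxel's null
    crit <- apply(abs(nullW), 2, quantile, probs = 1 - voxelAlpha, names = FALSE)
  }
  for (p in seq_len(nPerm)) {
    aw <- abs(nullW[p, ])
    supra <- if (thresholdBy == "own_quantile") {
      rank(-aw, ties.method = "first") <= k
    } else aw > crit
    bin <- array(FALSE, md$dim)
    bin[maskIdx[supra]] <- TRUE
    lab <- floodFill3d(bin, connectivity)
    maxSizes[p] <- if (max(lab) == 0L) 0L else max(tabulate(lab[lab > 0L]))
  }
  list(nullW = nullW, maxClusterSizes = maxSizes, nPerm = as.integer(nPerm),
       voxelAlpha = voxelAlpha, clusterAlpha = clusterAlpha,
       connectivity = as.integer(connectivity), seed = as.integer(seed))
}

#' Voxelwise empirical p-values
#'
#' Two-sided add-one empirical p per voxel:
#' \code{p = (1 + #\{perm: |w_perm| >= |w_obs|\}) / (nPerm + 1)}; p-values
#' are therefore never 0 and never exceed 1.  Observed and permuted maps
#' are compared at unit L2 norm (see [permutationNull()]).
#'
#' @param wmap observed [WeightMap-class].
#' @param null result of [permutationNull()].
#' @return 3D array of p-values, NA outside the feature mask.
#' @export
voxelPValues <- function(wmap, null) {
  vox <- which(wmap@mask)
  obs <- abs(wmap@wVoxel[vox])
  obs <- obs / sqrt(sum(obs^2))
  exceed <- colSums(sweep(abs(null$nullW), 2, obs, ">=") * 1)
  p <- (1 + exceed) / (null$nPerm + 1)
  out <- array(NA_real_, dim(wmap@mask))
  out[vox] <- p
  out
}

#' Label connected components of a 3D binary map
#'
#' Breadth-first flood fill under 6-, 18- or 26-connectivity.
#'
#' @param bin logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of component labels (0 = background), labelled in
#'   order of first (column-major) encounter.
#' @export
floodFill3d <- function(bin, connectivity = 26L) {
  d <- dim(bin)
  offs <- neighborOffsets(as.integer(connectivity))
  lab <- array(0L, d)
  active <- which(bin)
  if (length(active) == 0L) return(lab)
  nextLab <- 0L
  queue <- integer(length(active))
  for (v in active) {
    if (lab[v] != 0L) next
    nextLab <- nextLab + 1L
    lab[v] <- nextLab
    queue[1L] <- v
    qlen <- 1L
    while (qlen > 0L) {
      cur <- queue[qlen]; qlen <- qlen - 1L
      cc <- gridCoords(cur, d)
      nbc <- sweep(offs, 2, as.numeric(cc), "+")
      ok <- nbc[, 1] >= 1 & nbc[, 1] <= d[1] & nbc[, 2] >= 1 &
        nbc[, 2] <= d[2] & nbc[, 3] >= 1 & nbc[, 3] <= d[3]
      for (nb in linearIndex(nbc[ok, , drop = FALSE], d)) {
        if (bin[nb] && lab[nb] == 0L) {
          lab[nb] <- nextLab
          qlen <- qlen + 1L
          queue[qlen] <- nb
        }
      }
    }
  }
  lab
}

#' Extract candidate clusters from a voxel p-map
#'
#' Connected components of \code{\{p < voxelAlpha\}} under the chosen
#' connectivity; components smaller than \code{minClusterVoxels} are
#' discarded.  An empty result is allowed.
#'
#' @param pMap 3D p-value array (NA outside the mask).
#' @param voxelAlpha voxel threshold (default 0.02, strict inequality).
#' @param minClusterVoxels minimum extent (default 10).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return list of clusters, each \code{list(voxels = <linear indices>,
#'   size)}, ordered by decreasing size.
#' @export
extractClusters <- function(pMap, voxelAlpha = 0.02, minClusterVoxels = 10L,
                            connectivity = 26L) {
  bin <- !is.na(pMap) & pMap < voxelAlpha
  lab <- floodFill3d(bin, connectivity)
  if (max(lab) == 0L) return(list())
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minClusterVoxels)
  cl <- lapply(keep, function(k) list(voxels = which(lab == k),
                                      size = sizes[k]))
  cl[order(vapply(cl, `[[`, integer(1), "size"), decreasing = TRUE)]
}

#' Cluster-level inference against the max-cluster-size null
#'
#' Cluster-level p = \code{(1 + #\{perm: maxSize_perm >= size_obs\}) /
#' (nPerm + 1)}.  Clusters with p below \code{clusterAlpha} are flagged
#' significant; all candidates are reported.
#'
#' @param clusters candidate list from [extractClusters()].
#' @param wmap observed [WeightMap-class] (for peak locations).
#' @param null result of [permutationNull()] (provides the size null).
#' @param pMap voxel p-map (reports the voxel p at each peak).
#' @param clusterAlpha significance level (default 0.001).
#' @param voxelSizeMM voxel size for world-mm peak coordinates.
#' @return data.frame: cluster id, size, peak grid coordinates, peak world
#'   mm, peak weight, peak |weight|, voxel p at peak, cluster p,
#'   significant flag.  Peak ties break to the lowest linear index.
#' @export
clusterPValues <- function(clusters, wmap, null, pMap, clusterAlpha = 0.001,
                           voxelSizeMM = 3) {
  d <- dim(wmap@mask)
  if (length(clusters) == 0L)
    return(data.frame(cluster = integer(), size = integer(),
                      peak_i = integer(), peak_j = integer(),
                      peak_k = integer(), peak_x_mm = numeric(),
                      peak_y_mm = numeric(), peak_z_mm = numeric(),
                      peak_weight = numeric(), peak_abs_weight = numeric(),
                      voxel_p = numeric(), cluster_p = numeric(),
                      significant = logical()))
  rows <- lapply(seq_along(clusters), function(ci) {
    cl <- clusters[[ci]]
    aw <- abs(wmap@wVoxel[cl$voxels])
    peak <- min(cl$voxels[aw == max(aw)])            # lowest linear index tie-break
    pc <- gridCoords(peak, d)
    world <- voxelToWorld(pc, d, voxelSizeMM)
    pclu <- (1 + sum(null$maxClusterSizes >= cl$size)) / (null$nPerm + 1)
    data.frame(cluster = ci, size = cl$size,
               peak_i = pc[1], peak_j = pc[2], peak_k = pc[3],
               peak_x_mm = world[1], peak_y_mm = world[2], peak_z_mm = world[3],
               peak_weight = wmap@wVoxel[peak],
               peak_abs_weight = abs(wmap@wVoxel[peak]),
               voxel_p = pMap[peak], cluster_p = pclu,
               significant = pclu < clusterAlpha)
  })
  do.call(rbind, rows)
}
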