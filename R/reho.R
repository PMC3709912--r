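#' Kendall's coefficient of concordance
#'
#' Concordance W among K time series ranked over n time points:
#' \deqn{W = \frac{12 S}{K^2 (n^3 - n) - K \sum T_j}}
#' where S is the sum of squared deviations of the per-timepoint rank sums
#' from their mean and \eqn{T_j = \sum_g (t_g^3 - t_g)} is the tie
#' correction for series j (midranks).  With no ties the correction
#' vanishes and the classical formula is recovered.
#'
#' @param seriesSet n x K numeric matrix, one series per column (K >= 2,
#'   n >= 2).
#' @param tiePolicy \code{"midrank_corrected"} (default) applies midranks
#'   with the tie-corrected denominator; \code{"error_on_ties"} refuses tied
#'   input.
#' @return W in \code{[0, 1]}.
#' @export
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' kendallsW(cbind(1:5, 1:5, 1:5))      # 1: perfect concordance
#' kendallsW(cbind(1:3, 3:1))           # 0: two opposed rankings
kendallsW <- function(seriesSet,
                      tiePolicy = c("midrank_corrected", "error_on_ties")) {
  tiePolicy <- match.arg(tiePolicy)
  X <- as.matrix(seriesSet)
  n <- nrow(X); K <- ncol(X)
  if (K < 2L || n < 2L) stop("need K >= 2 series of length n >= 2")
  constant <- apply(X, 2, function(col) max(col) == min(col))
  if (all(constant))
    stop("degenerate input: all series are constant, W is undefined (0/0)")
  R <- apply(X, 2, rank)                       # midranks over time
  tieT <- vapply(seq_len(K), function(j) {
    if (!anyDuplicated(X[, j])) return(0)
    if (tiePolicy == "error_on_ties")
      stop("ties present in series ", j, " under tie_policy = error_on_ties")
    tt <- table(X[, j])
    sum(tt^3 - tt)
  }, numeric(1))
  S <- sum((rowSums(R) - K * (n + 1) / 2)^2)
  denom <- K^2 * (n^3 - n) - K * sum(tieT)
  if (denom <= 0) stop("degenerate input: tie-corrected denominator is zero")
  12 * S / denom
}

# Computable set under the strict edge rule: mask voxels whose whole
# neighbourhood (incl. center) lies inside the mask.
computableMask <- function(mask, offsets) {
  cnt <- array(0L, dim(mask))
  for (r in seq_len(nrow(offsets)))
    cnt <- cnt + shiftArray3d(mask, offsets[r, ])
  mask & (cnt == nrow(offsets))
}

#' Voxelwise ReHo map
#'
#' Computes Kendall's W of each gray-matter voxel's time series with those
#' of its neighbours (default: the 26 nearest, K = 27).  Under the default
#' strict edge rule a voxel is computable only when its entire neighbourhood
#' lies inside the mask; such voxels alone enter the map and the
#' normalisation mean.  The permissive rule (\code{edgePolicy =
#' "available_min7"}) uses whatever in-mask neighbours exist, requiring at
#' least 7 series.  The map is normalised by dividing each voxel's W by the
#' mean W over the computable gray matter.
#'
#' @param bold preprocessed 4D array.
#' @param gmMask logical 3D gray-matter mask on the same grid.
#' @param neighborhood 7, 19 or 27 (default 27).
#' @param edgePolicy \code{"all_neighbors_required"} (default) or
#'   \code{"available_min7"}.
#' @param tiePolicy passed to [kendallsW()].
#' @return a [ReHoMap-class].
#' @export
rehoMap <- function(bold, gmMask, neighborhood = 27L,
                    edgePolicy = c("all_neighbors_required", "available_min7"),
                    tiePolicy = "midrank_corrected") {
  edgePolicy <- match.arg(edgePolicy)
  d <- dim(gmMask)
  stopifnot(all(dim(bold)[1:3] == d))
  nt <- dim(bold)[4]
  if (nt < 2L) stop("need at least 2 time points")
  offsets <- rehoOffsets(neighborhood)
  K <- nrow(offsets)

  maskIdx <- which(gmMask)
  mat <- matrix(bold, prod(d), nt)
  Yt <- t(mat[maskIdx, , drop = FALSE])          # time x maskVoxels
  R <- apply(Yt, 2, rank)
  tieT <- vapply(seq_len(ncol(Yt)), function(j) {
    if (!anyDuplicated(Yt[, j])) return(0)
    if (tiePolicy == "error_on_ties")
      stop("ties present under tie_policy = error_on_ties")
    tt <- table(Yt[, j])
    sum(tt^3 - tt)
  }, numeric(1))
  colOf <- integer(prod(d))
  colOf[maskIdx] <- seq_along(maskIdx)
  offLin <- offsets[, 1] + offsets[, 2] * d[1] + offsets[, 3] * d[1] * d[2]

  kcc <- array(NA_real_, d)
  if (edgePolicy == "all_neighbors_required") {
    comp <- computableMask(gmMask, offsets)
    compIdx <- which(comp)
    if (length(compIdx) == 0L) stop("empty computable mask")
    RS <- matrix(0, nt, length(compIdx))
    Tsum <- numeric(length(compIdx))
    for (r in seq_len(K)) {
      nb <- colOf[compIdx + offLin[r]]
      RS <- RS + R[, nb, drop = FALSE]
      Tsum <- Tsum + tieT[nb]
    }
    S <- colSums((RS - K * (nt + 1) / 2)^2)
    denom <- K^2 * (nt^3 - nt) - K * Tsum
    w <- 12 * S / denom
    bad <- denom <= 0                          # all-constant neighbourhoods
    if (any(bad)) {
      comp[compIdx[bad]] <- FALSE
      compIdx <- compIdx[!bad]; w <- w[!bad]
      if (length(compIdx) == 0L) stop("empty computable mask")
    }
    kcc[compIdx] <- w
  } else {
    comp <- array(FALSE, d)
    coords <- gridCoords(maskIdx, d)
    for (v in seq_along(maskIdx)) {
      nbc <- sweep(offsets, 2, as.numeric(coords[v, ]), "+")
      ok <- nbc[, 1] >= 1 & nbc[, 1] <= d[1] & nbc[, 2] >= 1 &
        nbc[, 2] <= d[2] & nbc[, 3] >= 1 & nbc[, 3] <= d[3]
      nbl <- linearIndex(nbc[ok, , drop = FALSE], d)
      nbl <- nbl[colOf[nbl] > 0L]
      if (length(nbl) < 7L) next
      wv <- tryCatch(kendallsW(Yt[, colOf[nbl], drop = FALSE], tiePolicy),
                     error = function(e) NA_real_)
      if (!is.na(wv)) { kcc[maskIdx[v]] <- wv; comp[maskIdx[v]] <- TRUE }
    }
    if (!any(comp)) stop("empty computable mask")
  }
  normalized <- normalizeReho(kcc, comp)
  new("ReHoMap", kcc = kcc, computable = comp, normalized = normalized,
      neighborhood = as.integer(neighborhood))
}

#' Normalise a KCC map by its gray-matter mean
#'
#' Divides W at each voxel by the mean W over the computable mask, so the
#' normalised map averages exactly 1 over that mask.
#'
#' @param kccMap 3D numeric array (NA allowed outside the mask).
#' @param computable logical 3D mask of defined voxels.
#' @return 3D numeric array; NA outside \code{computable}.
#' @export
normalizeReho <- function(kccMap, computable) {
  m <- mean(kccMap[computable])
  if (!is.finite(m) || m <= 0) stop("mean W over the mask must be positive")
  out <- array(NA_real_, dim(kccMap))
  out[computable] <- kccMap[computable] / m
  out
}
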