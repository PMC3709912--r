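#' Motion quality control
#'
#' A subject fails when any translation exceeds \code{maxTranslationMM} on
#' any cardinal axis at any time point, or any rotation exceeds
#' \code{maxRotationDeg}.  The comparison is a strict inequality: a value
#' exactly at the threshold passes.
#'
#' @param motion t x 6 matrix/data.frame: translations (mm, 3 cols) then
#'   rotations (degrees, 3 cols).
#' @param maxTranslationMM translation threshold, mm (default 1.5).
#' @param maxRotationDeg rotation threshold, degrees (default 1.5).
#' @return list: \code{pass} (logical), and on failure \code{axis},
#'   \code{frame}, \code{value} of the worst offender.
#' @export
#' @examples
#' m <- matrix(0, 20, 6)
#' qcMotion(m)$pass                    # TRUE
#' m[5, 1] <- 1.6; qcMotion(m)$axis   # "trans_x"
qcMotion <- function(motion, maxTranslationMM = 1.5, maxRotationDeg = 1.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion table must have 6 columns")
  stopifnot(maxTranslationMM > 0, maxRotationDeg > 0)
  axes <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  thr <- c(rep(maxTranslationMM, 3), rep(maxRotationDeg, 3))
  excess <- sweep(abs(motion), 2, thr, "-")
  if (all(excess <= 0)) return(list(pass = TRUE))
  worst <- which(excess == max(excess), arr.ind = TRUE)[1, ]
  list(pass = FALSE, axis = axes[worst[2]], frame = unname(worst[1]),
       value = abs(motion[worst[1], worst[2]]))
}

#' Discard initial volumes
#'
#' @param bold 4D array (x, y, z, t).
#' @param nDiscard number of leading frames to drop (default 10).
#' @return the 4D array with the first \code{nDiscard} frames removed.
#' @export
discardInitial <- function(bold, nDiscard = 10L) {
  nt <- dim(bold)[4]
  if (nDiscard >= nt) stop("nDiscard (", nDiscard, ") must be < time length (", nt, ")")
  if (nDiscard == 0L) return(bold)
  bold[, , , (nDiscard + 1L):nt, drop = FALSE]
}

#' Remove nuisance variance by linear regression
#'
#' Least-squares residuals \code{ts - X beta-hat}; residuals are orthogonal
#' to every design column.  The caller supplies the full design (including
#' an intercept column if wanted); see [nuisanceDesign()].
#'
#' @param ts numeric t-vector, or t x V matrix of series in columns.
#' @param regressors t x k design matrix, full column rank.
#' @return residuals with the shape of \code{ts}.
#' @export
regressNuisance <- function(ts, regressors) {
  X <- as.matrix(regressors)
  Y <- if (is.matrix(ts)) ts else matrix(ts, ncol = 1)
  if (nrow(Y) != nrow(X)) stop("time lengths of series and design differ")
  if (nrow(X) <= ncol(X)) stop("need more time points than regressors")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    if (is.null(bad)) bad <- q$pivot[(q$rank + 1L):ncol(X)]
    stop("rank-deficient nuisance design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(q, Y)
  if (is.matrix(ts)) res else drop(res)
}

#' Build the nuisance design for one subject
#'
#' Columns per the enabled flags: intercept, linear trend, the 6 motion
#' parameters, and mean white-matter / CSF (ventricle) signals.
#'
#' @param motion t x 6 motion matrix (already discarded to match the data).
#' @param wmMean,csfMean optional t-vectors of tissue mean signals.
#' @param nuisanceSet character flags, any of \code{"intercept"},
#'   \code{"linear_trend"}, \code{"motion6"}, \code{"wm_mean"},
#'   \code{"csf_mean"}.
#' @return t x k design matrix with named columns.
#' @export
nuisanceDesign <- function(motion, wmMean = NULL, csfMean = NULL,
                           nuisanceSet = c("intercept", "linear_trend",
                                           "motion6", "wm_mean", "csf_mean")) {
  nt <- nrow(motion)
  cols <- list()
  if ("intercept" %in% nuisanceSet) cols$intercept <- rep(1, nt)
  if ("linear_trend" %in% nuisanceSet)
    cols$linear_trend <- seq_len(nt) - (nt + 1) / 2
  if ("motion6" %in% nuisanceSet) {
    m <- as.matrix(motion)
    colnames(m) <- paste0("motion", 1:6)
    for (j in 1:6) cols[[colnames(m)[j]]] <- m[, j]
  }
  if ("wm_mean" %in% nuisanceSet && !is.null(wmMean)) cols$wm_mean <- wmMean
  if ("csf_mean" %in% nuisanceSet && !is.null(csfMean)) cols$csf_mean <- csfMean
  do.call(cbind, cols)
}

#' Band-pass filter a time series
#'
#' Default is the ideal rectangular frequency-domain filter: discrete
#' Fourier bins with frequency inside \code{[lowHz, highHz]} are retained,
#' all others (including DC) are zeroed; the output is real.  A 2nd-order
#' Butterworth (zero-phase, via \pkg{signal}) is available behind
#' \code{type = "butterworth"}.
#'
#' @param ts numeric t-vector or t x V matrix (series in columns).
#' @param trS sampling interval, seconds.
#' @param lowHz,highHz pass band, Hz; must satisfy
#'   \code{0 <= lowHz < highHz < 1/(2 trS)}.
#' @param type \code{"ideal"} (default) or \code{"butterworth"}.
#' @return filtered series, same shape as \code{ts}.
#' @export
#' @examples
#' t <- seq(0, by = 2, length.out = 100)
#' x <- sin(2 * pi * 0.04 * t)         # 0.04 Hz, bin-aligned at n = 100
#' max(abs(bandpassFilter(x, 2, 0.01, 0.08) - x)) < 1e-10
bandpassFilter <- function(ts, trS, lowHz = 0.01, highHz = 0.08,
                           type = c("ideal", "butterworth")) {
  type <- match.arg(type)
  nyq <- 1 / (2 * trS)
  if (lowHz < 0 || lowHz >= highHz || highHz >= nyq)
    stop("band must satisfy 0 <= low < high < Nyquist (", nyq, " Hz)")
  Y <- if (is.matrix(ts)) ts else matrix(ts, ncol = 1)
  if (type == "butterworth") {
    if (!requireNamespace("signal", quietly = TRUE))
      stop("the Butterworth filter requires the 'signal' package")
    bf <- signal::butter(2, c(max(lowHz, 1e-6), highHz) / nyq, type = "pass")
    out <- apply(Y, 2, function(col) signal::filtfilt(bf, col))
  } else {
    n <- nrow(Y)
    f <- pmin(0:(n - 1), n - (0:(n - 1))) / (n * trS)
    keep <- f >= lowHz & f <= highHz & f > 0
    Fy <- mvfft(Y)
    Fy[!keep, ] <- 0
    out <- Re(mvfft(Fy, inverse = TRUE)) / n
  }
  if (is.matrix(ts)) out else drop(out)
}

#' Temporal preprocessing of one subject
#'
#' Pipeline order: initial-volume discard, nuisance regression (motion,
#' linear trend, mean white-matter and ventricle signals, intercept), then
#' band-pass.  Only voxels inside the union of the tissue masks are
#' processed; others are left at zero.
#'
#' @param bold 4D array.
#' @param motion t x 6 motion matrix aligned with \code{bold}.
#' @param gmMask,wmMask,csfMask logical 3D masks.
#' @param nDiscard leading frames to drop (default 10).
#' @param lowHz,highHz pass band (defaults 0.01, 0.08).
#' @param trS repetition time, seconds.
#' @param nuisanceSet see [nuisanceDesign()].
#' @param filterType see [bandpassFilter()].
#' @return list: \code{bold} (preprocessed 4D array), \code{stages}
#'   (character log of the stage order).
#' @export
preprocessSubject <- function(bold, motion, gmMask, wmMask = NULL,
                              csfMask = NULL, nDiscard = 10L,
                              lowHz = 0.01, highHz = 0.08, trS = 2,
                              nuisanceSet = c("intercept", "linear_trend",
                                              "motion6", "wm_mean", "csf_mean"),
                              filterType = "ideal") {
  stages <- character()
  bold <- discardInitial(bold, nDiscard)
  motion <- as.matrix(motion)[(nDiscard + 1L):(nrow(motion)), , drop = FALSE]
  stages <- c(stages, "discard")
  nt <- dim(bold)[4]
  nv <- prod(dim(bold)[1:3])
  mat <- matrix(bold, nv, nt)                       # voxels x time

  union <- gmMask
  if (!is.null(wmMask)) union <- union | wmMask
  if (!is.null(csfMask)) union <- union | csfMask
  vox <- which(union)
  Y <- t(mat[vox, , drop = FALSE])                  # time x voxels
  wmMean <- if (!is.null(wmMask) && any(wmMask))
    colMeans(mat[which(wmMask), , drop = FALSE]) else NULL
  csfMean <- if (!is.null(csfMask) && any(csfMask))
    colMeans(mat[which(csfMask), , drop = FALSE]) else NULL
  X <- nuisanceDesign(motion, wmMean, csfMean, nuisanceSet)
  Y <- regressNuisance(Y, X)
  stages <- c(stages, "nuisance_regression")
  Y <- bandpassFilter(Y, trS, lowHz, highHz, type = filterType)
  stages <- c(stages, "bandpass")

  out <- matrix(0, nv, nt)
  out[vox, ] <- t(Y)
  list(bold = array(out, c(dim(gmMask), nt)), stages = stages)
}
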