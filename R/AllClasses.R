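#' @import methods
#' @importFrom stats rnorm runif rlnorm sd cor fft mvfft pt qt quantile
#' @importFrom utils write.table read.table head
NULL

#' Simulation configuration for synthetic resting-state cohorts
#'
#' Holds the generative parameters of [simulateCohort()]: cohort and grid
#' geometry, acquisition timing, the planted-synchrony effect and the
#' behavioural coupling.  Defaults reproduce the study conditions the package
#' targets: two groups of 30 subjects, 150 volumes at TR = 2 s on a 3 mm
#' isotropic grid.
#'
#' @slot nPerGroup subjects per group.
#' @slot gridShape integer 3-vector of grid dimensions (voxels).
#' @slot voxelSizeMM isotropic voxel size in mm.
#' @slot nVolumes number of time points acquired per subject.
#' @slot trS repetition time in seconds.
#' @slot effectRois list of planted-effect regions, each
#'   \code{list(center = <voxel triplet>, radius = <voxels>)}.
#' @slot synchronyLambda mixing weight of the shared regional signal in
#'   \code{[0, 1)}; 0 plants nothing.
#' @slot synchronyJitter per-subject spread: patient i receives
#'   \code{lambda_i ~ U((1 - jitter) * lambda, lambda)}.
#' @slot noiseSD standard deviation of the baseline voxel noise (BOLD a.u.).
#' @slot behavSlope NDI score units per unit planted synchrony.
#' @slot behavNoiseSD behavioural noise standard deviation (score units).
#' @slot seed integer RNG seed; the whole cohort is deterministic given it.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nPerGroup = "integer", gridShape = "integer", voxelSizeMM = "numeric",
  nVolumes = "integer", trS = "numeric", effectRois = "list",
  synchronyLambda = "numeric", synchronyJitter = "numeric",
  noiseSD = "numeric", behavSlope = "numeric", behavNoiseSD = "numeric",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    msg <- c(msg, "gridShape must be three integers >= 4")
  if (object@nVolumes <= 10L)
    msg <- c(msg, "nVolumes must exceed 10 (preprocessing discards 10)")
  if (object@synchronyLambda < 0 || object@synchronyLambda >= 1)
    msg <- c(msg, "synchronyLambda must lie in [0, 1)")
  if (object@synchronyJitter < 0 || object@synchronyJitter > 1)
    msg <- c(msg, "synchronyJitter must lie in [0, 1]")
  if (object@noiseSD <= 0) msg <- c(msg, "noiseSD must be positive")
  if (object@trS <= 0) msg <- c(msg, "trS must be positive")
  if (length(msg)) msg else TRUE
})

#' A synthetic resting-state cohort with ground truth
#'
#' Container returned by [simulateCohort()]: per-subject 4D BOLD arrays and
#' motion tables, tissue masks on the common grid, a phenotype table, and the
#' planted-effect truth (ROI masks and the per-subject synchrony level)
#' needed for recovery tests.
#'
#' @slot subjects list; each element has \code{id}, \code{group}
#'   (\code{"patient"}/\code{"control"}), \code{bold} (4D array) and
#'   \code{motion} (t x 6 matrix: translations mm, rotations degrees).
#' @slot gmMask,wmMask,csfMask mutually disjoint logical 3D arrays.
#' @slot pheno \code{data.frame} with one row per subject: id, group, label
#'   (+1 patient / -1 control), ndi, sds_raw, sas_raw, sds_index, sas_index,
#'   duration_months.
#' @slot truth list: \code{roiMasks} (list of logical arrays),
#'   \code{effect} (per-subject planted synchrony level, 0 for controls).
#' @slot config the generating [SimConfig-class].
#' @exportClass FmriCohort
setClass("FmriCohort", representation(
  subjects = "list", gmMask = "array", wmMask = "array", csfMask = "array",
  pheno = "data.frame", truth = "list", config = "SimConfig"))

setValidity("FmriCohort", function(object) {
  msg <- character()
  if (!any(object@gmMask)) msg <- c(msg, "gray-matter mask is empty")
  if (any((object@gmMask & object@wmMask) | (object@gmMask & object@csfMask) |
          (object@wmMask & object@csfMask)))
    msg <- c(msg, "tissue masks must be mutually disjoint")
  for (rm in object@truth$roiMasks)
    if (any(rm & !object@gmMask))
      msg <- c(msg, "truth ROIs must lie inside the gray-matter mask")
  nv <- object@config@nVolumes
  for (s in object@subjects) {
    if (dim(s$bold)[4] != nv) msg <- c(msg, "bold time length != nVolumes")
    if (nrow(s$motion) != nv) msg <- c(msg, "motion table length != nVolumes")
  }
  if (any(object@pheno$ndi < 0)) msg <- c(msg, "ndi must be >= 0")
  if (length(msg)) unique(msg) else TRUE
})

#' Voxelwise regional-homogeneity map
#'
#' Kendall's coefficient of concordance W per voxel over its cubic
#' neighbourhood, the set of voxels on which W is computable under the edge
#' rule, and the map normalised by the mean W over that set.
#'
#' @slot kcc 3D numeric array; W in \code{[0, 1]} on the computable set,
#'   \code{NA} elsewhere.
#' @slot computable logical 3D array.
#' @slot normalized 3D numeric array, \code{kcc} divided by its mean over
#'   \code{computable}; its mean over the computable set is 1.
#' @slot neighborhood 7, 19 or 27.
#' @exportClass ReHoMap
setClass("ReHoMap", representation(
  kcc = "array", computable = "array", normalized = "array",
  neighborhood = "integer"))

setValidity("ReHoMap", function(object) {
  msg <- character()
  w <- object@kcc[object@computable]
  if (length(w) == 0L) msg <- c(msg, "computable set is empty")
  if (any(w < -1e-10 | w > 1 + 1e-10)) msg <- c(msg, "W outside [0, 1]")
  nm <- mean(object@normalized[object@computable])
  if (abs(nm - 1) > 1e-10)
    msg <- c(msg, "normalized map must average 1 over the computable set")
  if (length(msg)) msg else TRUE
})

#' PCA model with all informative components
#'
#' Column mean and orthonormal eigenvector basis of the training covariance,
#' retaining d = N - 1 components so the projection is lossless on the
#' centered training span.
#'
#' @slot center D-vector training mean.
#' @slot rotation D x d matrix of orthonormal eigenvector columns.
#' @slot d number of components (N_train - 1).
#' @exportClass PCAModel
setClass("PCAModel", representation(
  center = "numeric", rotation = "matrix", d = "integer"))

setValidity("PCAModel", function(object) {
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(ncol(object@rotation)))) > 1e-8)
    return("rotation columns must be orthonormal")
  if (ncol(object@rotation) != object@d) return("d != ncol(rotation)")
  TRUE
})

#' Linear soft-margin SVM model
#'
#' The decision function is \code{g(y) = <w, y> + b}; the predicted label is
#' +1 (patient) when \code{g > 0} and -1 (control) otherwise, with the tie
#' \code{g == 0} assigned to control.
#'
#' @slot w weight vector in the training feature space.
#' @slot b offset.
#' @slot alpha dual coefficients of the support vectors (0 < alpha_i <= C).
#' @slot svIndex training-row indices of the support vectors.
#' @slot C box constraint.
#' @exportClass LinearSVM
setClass("LinearSVM", representation(
  w = "numeric", b = "numeric", alpha = "numeric", svIndex = "integer",
  C = "numeric"))

#' Discriminative weight map
#'
#' SVM weight vector back-projected to voxel space: \code{wVoxel = U w} with
#' U the PCA eigenvector matrix, scattered onto the feature mask.
#'
#' @slot wVoxel 3D numeric array, 0 outside the feature mask.
#' @slot mask logical 3D feature mask (intersection computable mask).
#' @slot wReduced reduced-space weight vector.
#' @slot pca the full-data [PCAModel-class].
#' @slot svm the full-data [LinearSVM-class].
#' @exportClass WeightMap
setClass("WeightMap", representation(
  wVoxel = "array", mask = "array", wReduced = "numeric",
  pca = "PCAModel", svm = "LinearSVM"))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", 2L * object@nPerGroup, "subjects (",
      object@nPerGroup, "per group ),",
      paste(object@gridShape, collapse = "x"), "grid,",
      object@nVolumes, "volumes @ TR", object@trS, "s\n")
  cat("  planted synchrony lambda =", object@synchronyLambda,
      "in", length(object@effectRois), "ROI(s); seed", object@seed, "\n")
})

setMethod("show", "FmriCohort", function(object) {
  cat("FmriCohort:", length(object@subjects), "subjects on a",
      paste(dim(object@gmMask), collapse = "x"), "grid\n")
  cat("  gray matter:", sum(object@gmMask), "voxels;",
      sum(object@pheno$group == "patient"), "patients /",
      sum(object@pheno$group == "control"), "controls\n")
})

setMethod("show", "ReHoMap", function(object) {
  w <- object@kcc[object@computable]
  cat("ReHoMap:", sum(object@computable), "computable voxels,",
      "neighborhood", object@neighborhood, "\n")
  cat("  W: mean", signif(mean(w), 4), " range [",
      signif(min(w), 4), ",", signif(max(w), 4), "]\n")
})

setMethod("show", "WeightMap", function(object) {
  cat("WeightMap on", sum(object@mask), "voxels; ||w|| =",
      signif(sqrt(sum(object@wVoxel^2)), 5), "\n")
})
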