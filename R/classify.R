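#' Assemble the subjects x voxels feature matrix
#'
#' Restricts every subject's normalised ReHo map to the intersection of the
#' per-subject computable masks and packs the result into a
#' \linkS4class{SummarizedExperiment} (voxels as rows, subjects as columns):
#' the assay \code{"reho"} holds the features, \code{rowData} the voxel grid
#' coordinates, \code{colData} the labels and any phenotype supplied.
#'
#' @param rehoMaps list of [ReHoMap-class], one per subject, on a common grid.
#' @param labels numeric vector, +1 patient / -1 control, one per subject.
#' @param pheno optional data.frame of per-subject covariates.
#' @return a \code{SummarizedExperiment}; \code{metadata()} carries the grid
#'   dimension, the intersection mask and the voxel linear indices.
#' @export
buildFeatureMatrix <- function(rehoMaps, labels, pheno = NULL) {
  stopifnot(length(rehoMaps) == length(labels))
  if (sum(labels == 1) < 2L || sum(labels == -1) < 2L)
    stop("need at least 2 subjects per class")
  d <- dim(rehoMaps[[1]]@computable)
  common <- Reduce(`&`, lapply(rehoMaps, function(m) m@computable))
  if (!any(common)) stop("empty intersection of computable masks")
  vox <- which(common)
  X <- vapply(rehoMaps, function(m) m@normalized[vox], numeric(length(vox)))
  rd <- S4Vectors::DataFrame(gridCoords(vox, d))
  cd <- S4Vectors::DataFrame(label = as.integer(labels))
  if (!is.null(pheno)) cd <- cbind(cd, S4Vectors::DataFrame(pheno))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reho = X), rowData = rd, colData = cd,
    metadata = list(dim = d, mask = common, voxelIndex = vox))
  se
}

featureX <- function(se) t(SummarizedExperiment::assay(se, "reho"))  # N x D
featureLabels <- function(se) SummarizedExperiment::colData(se)$label

#' Fit a lossless PCA basis
#'
#' Column mean plus the top d = N - 1 eigenvectors of the training
#' covariance (all directions of nonzero variance), obtained from the SVD of
#' the centered data.  Projection is \code{y = U' (x - xbar)}; with all
#' N - 1 components it is an isometry on the centered training span.
#'
#' @param X N x D training matrix (rows = subjects).
#' @param d number of components; default \code{nrow(X) - 1}.
#' @return a [PCAModel-class].
#' @export
fitPCA <- function(X, d = nrow(X) - 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training rows")
  d <- min(as.integer(d), nrow(X) - 1L, ncol(X))
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0, nv = d)
  new("PCAModel", center = center, rotation = sv$v[, seq_len(d), drop = FALSE],
      d = d)
}

#' Project rows into the PCA space
#' @param model a [PCAModel-class].
#' @param X matrix (rows) or a single vector in the original space.
#' @return N x d matrix (or d-vector) of scores.
#' @export
projectPCA <- function(model, X) {
  single <- !is.matrix(X)
  X <- rbind(X)
  Y <- sweep(X, 2, model@center) %*% model@rotation
  if (single) drop(Y) else Y
}

#' Train a linear soft-margin SVM
#'
#' Solves the C-SVM with a linear kernel (libsvm via \pkg{e1071}) on
#' unscaled features.  The stored orientation follows the label convention
#' patient = +1: \code{g(y) = <w, y> + b} is positive on the patient side.
#'
#' @param Y N x d training matrix.
#' @param labels +1 / -1 vector, both classes present.
#' @param C box constraint (default 1).
#' @return a [LinearSVM-class].
#' @export
trainSVM <- function(Y, labels, C = 1) {
  Y <- as.matrix(Y)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  fit <- e1071::svm(x = Y, y = factor(labels, levels = c(1L, -1L)),
                    type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  w <- drop(t(fit$SV) %*% fit$coefs)
  b <- -fit$rho
  # libsvm orients decision values toward the first training label it sees;
  # normalise so that positive g means patient (+1)
  dv <- attr(stats::predict(fit, Y, decision.values = TRUE), "decision.values")
  pos <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (pos != "1") { w <- -w; b <- -b }
  newLinearSVM(as.numeric(w), b, as.numeric(abs(fit$coefs)),
               as.integer(fit$index), C)
}

#' Construct a [LinearSVM-class]
#'
#' Used instead of a named \code{C =} argument to \code{new()}, which would
#' partially match \code{new()}'s \code{Class} formal.
#' @param w,b,alpha,svIndex,C slot values.
#' @return a [LinearSVM-class].
#' @export
newLinearSVM <- function(w, b, alpha = numeric(), svIndex = integer(),
                         C = 1) {
  obj <- new("LinearSVM", w = as.numeric(w), b = as.numeric(b),
             alpha = as.numeric(alpha), svIndex = as.integer(svIndex))
  obj@C <- C
  obj
}

#' SVM decision values
#' @param model a [LinearSVM-class].
#' @param Y matrix of rows (or a single vector) in the model's space.
#' @return numeric decision values \code{g = Y w + b}.
#' @export
decisionValues <- function(model, Y) {
  drop(rbind(Y) %*% model@w + model@b)
}

#' Predict class labels (+1 patient / -1 control)
#'
#' The tie \code{g == 0} is assigned to control.
#' @inheritParams decisionValues
#' @return integer labels.
#' @export
predictSVM <- function(model, Y) {
  ifelse(decisionValues(model, Y) > 0, 1L, -1L)
}

#' Leave-one-out cross-validation of the PCA + linear-SVM classifier
#'
#' N folds: in each, PCA is fit on the N - 1 training subjects only
#' (d = N - 2 components), the SVM is trained in that reduced space, and the
#' held-out subject is projected with the fold's PCA and classified.  The
#' held-out subject therefore contributes to neither the PCA mean and
#' eigenvectors nor the SVM fit.  \code{pcaGlobal = TRUE} reproduces the
#' leaky variant (PCA fit once on everyone) for comparison.
#'
#' @param se feature \code{SummarizedExperiment} from
#'   [buildFeatureMatrix()], or an N x D matrix via \code{labels}.
#' @param labels required when \code{se} is a plain matrix.
#' @param C SVM box constraint.
#' @param pcaGlobal fit PCA on the full data set instead of per fold.
#' @param returnModels keep each fold's PCA + SVM (memory heavy).
#' @return list: \code{counts} (named TP/TN/FP/FN), \code{predicted},
#'   \code{decision}, \code{metrics} (GR/SS/SC, percent), and optionally
#'   \code{models}.
#' @export
loocv <- function(se, labels = NULL, C = 1, pcaGlobal = FALSE,
                  returnModels = FALSE) {
  X <- if (is.matrix(se)) se else featureX(se)
  if (is.null(labels)) labels <- featureLabels(se)
  N <- nrow(X)
  if (N < 4L || sum(labels == 1) < 2L || sum(labels == -1) < 2L)
    stop("LOOCV needs N >= 4 with at least 2 subjects per class")
  predicted <- integer(N)
  decision <- numeric(N)
  models <- if (returnModels) vector("list", N) else NULL
  pcaAll <- if (pcaGlobal) fitPCA(X) else NULL
  for (i in seq_len(N)) {
    trainLab <- labels[-i]
    if (length(unique(trainLab)) < 2L)
      stop("class absent from training fold ", i)
    pca <- if (pcaGlobal) pcaAll else fitPCA(X[-i, , drop = FALSE])
    Ytr <- projectPCA(pca, X[-i, , drop = FALSE])
    svmFit <- trainSVM(Ytr, trainLab, C = C)
    g <- decisionValues(svmFit, projectPCA(pca, X[i, ]))
    decision[i] <- g
    predicted[i] <- if (g > 0) 1L else -1L
    if (returnModels) models[[i]] <- list(pca = pca, svm = svmFit)
  }
  counts <- c(TP = sum(predicted == 1 & labels == 1),
              TN = sum(predicted == -1 & labels == -1),
              FP = sum(predicted == 1 & labels == -1),
              FN = sum(predicted == -1 & labels == 1))
  out <- list(counts = counts, predicted = predicted, decision = decision,
              metrics = classMetrics(counts))
  if (returnModels) out$models <- models
  out
}

#' Classification performance: GR, SS, SC
#'
#' Generalization rate \code{(TP + TN) / (TP + TN + FP + FN)}, sensitivity
#' \code{TP / (TP + FN)} (patient recall) and specificity
#' \code{TN / (TN + FP)} (control recall), reported as percentages.
#'
#' @param counts named vector with elements TP, TN, FP, FN (or TP as first
#'   argument with \code{tn}, \code{fp}, \code{fn}).
#' @param tn,fp,fn counts when \code{counts} is scalar TP.
#' @return named numeric: GR, SS, SC in percent (NA where a denominator is
#'   zero, with a warning).
#' @export
#' @examples
#' classMetrics(c(TP = 25, TN = 27, FP = 3, FN = 5))   # GR 86.67
classMetrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (!is.null(tn)) counts <- c(TP = counts, TN = tn, FP = fp, FN = fn)
  counts <- counts[c("TP", "TN", "FP", "FN")]
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be named non-negative TP/TN/FP/FN")
  tot <- sum(counts)
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: zero denominator"); return(NA_real_) }
    unname(100 * num / den)
  }
  c(GR = safe(counts["TP"] + counts["TN"], tot, "GR"),
    SS = safe(counts["TP"], counts["TP"] + counts["FN"], "SS"),
    SC = safe(counts["TN"], counts["TN"] + counts["FP"], "SC"))
}
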