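test_that("feature matrix restricts to the intersection mask and preserves order", {
  coh <- smallCohort(seed = 4, lambda = 0.5, nPerGroup = 3)
  cf <- cohortFeatures(coh)
  se <- cf$se
  X <- t(SummarizedExperiment::assay(se))
  common <- Reduce(`&`, lapply(cf$maps, function(m) m@computable))
  expect_equal(ncol(X), sum(common))
  expect_equal(nrow(X), 6)
  # voxel index round-trips to 3D coordinates
  md <- S4Vectors::metadata(se)
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  expect_equal(rehomvpa:::linearIndex(as.matrix(rd), md$dim), md$voxelIndex)
  # reordering subjects permutes rows identically
  perm <- c(3, 1, 4, 2, 6, 5)
  se2 <- buildFeatureMatrix(cf$maps[perm], coh@pheno$label[perm])
  expect_equal(t(SummarizedExperiment::assay(se2)), X[perm, ],
               ignore_attr = TRUE)
  # disjoint computable masks are an error
  m1 <- cf$maps[[1]]; m2 <- cf$maps[[2]]
  m2@computable[] <- FALSE
  expect_error(buildFeatureMatrix(list(m1, m2, m1, m2), c(1, 1, -1, -1)),
               "empty intersection")
})

test_that("PCA with N-1 components is lossless on the training span", {
  set.seed(23)
  X <- matrix(rnorm(10 * 50), 10, 50)
  pca <- fitPCA(X)
  expect_equal(pca@d, 9L)
  expect_lt(max(abs(crossprod(pca@rotation) - diag(9))), 1e-8)
  # reconstruction of every training row
  Y <- projectPCA(pca, X)
  Xhat <- sweep(Y %*% t(pca@rotation), 2, pca@center, "+")
  expect_equal(Xhat, X, tolerance = 1e-6)
  # the mean projects to the origin
  expect_lt(max(abs(projectPCA(pca, pca@center))), 1e-10)
  # pairwise distances are preserved (orthonormal isometry on the span)
  expect_equal(as.matrix(dist(Y)), as.matrix(dist(X)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(fitPCA(X[1, , drop = FALSE]), "at least 2")
})

test_that("the linear SVM solves small geometries exactly", {
  # two symmetric points: boundary through the origin
  fit <- trainSVM(rbind(c(1, 1), c(-1, -1)), c(1, -1))
  expect_lt(abs(fit@b), 1e-6)
  expect_equal(fit@w[1], fit@w[2], tolerance = 1e-6)
  expect_equal(predictSVM(fit, rbind(c(2, 2), c(-2, -2))), c(1L, -1L))

  # four points with margin 2 about x = 0: w along (1, 0)
  Y4 <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  lab4 <- c(1, 1, -1, -1)
  fit4 <- trainSVM(Y4, lab4)
  expect_equal(fit4@w / sqrt(sum(fit4@w^2)), c(1, 0), tolerance = 1e-4)
  expect_lt(abs(fit4@b), 1e-4)
  # dual feasibility: 0 <= alpha <= C, sum alpha_i y_i = 0
  expect_true(all(fit4@alpha >= -1e-8 & fit4@alpha <= 1 + 1e-8))

  # duplicating every training point leaves the decision function unchanged
  fitD <- trainSVM(rbind(Y4, Y4), c(lab4, lab4))
  probe <- rbind(c(0.3, 2), c(-2, 0.1), c(5, -5))
  expect_equal(decisionValues(fitD, probe), decisionValues(fit4, probe),
               tolerance = 1e-6)

  expect_error(trainSVM(Y4, rep(1, 4)), "single class")
})

test_that("reduced-space SVM equals a voxel-space SVM with all N-1 components", {
  set.seed(77)
  X <- matrix(rnorm(12 * 200), 12, 200)
  lab <- rep(c(1, -1), 6)
  Xc <- sweep(X, 2, colMeans(X))
  direct <- trainSVM(Xc, lab)
  pca <- fitPCA(X)
  reduced <- trainSVM(projectPCA(pca, X), lab)
  gDirect <- decisionValues(direct, Xc)
  gReduced <- decisionValues(reduced, projectPCA(pca, X))
  expect_equal(gReduced, gDirect, tolerance = 1e-6)
})

test_that("LOOCV holds each subject out exactly once, with leak-free folds", {
  set.seed(41)
  X <- matrix(rnorm(12 * 30), 12, 30)
  X[1:6, 1:5] <- X[1:6, 1:5] + 3          # separable classes
  lab <- rep(c(1, -1), each = 6)
  cv <- loocv(X, lab, returnModels = TRUE)
  expect_equal(length(cv$predicted), 12)
  expect_equal(sum(cv$counts), 12)
  expect_equal(unname(cv$counts["TP"] + cv$counts["FN"]), 6)
  expect_equal(unname(cv$counts["TN"] + cv$counts["FP"]), 6)
  # purity: perturbing the held-out subject cannot change the fold's model
  X2 <- X
  X2[3, ] <- X2[3, ] + rnorm(30, 0, 5)
  cv2 <- loocv(X2, lab, returnModels = TRUE)
  expect_equal(cv2$models[[3]]$svm@w, cv$models[[3]]$svm@w, tolerance = 1e-10)
  expect_equal(cv2$models[[3]]$pca@center, cv$models[[3]]$pca@center)
  # separable planted structure is classified perfectly
  expect_equal(unname(cv$metrics["GR"]), 100)
  expect_error(loocv(X[1:3, ], lab[1:3]), "N >= 4")
})

test_that("LOOCV on exchangeable null features shows no spurious discrimination", {
  set.seed(13)
  accs <- sapply(1:25, function(i) {
    X <- matrix(rnorm(16 * 60), 16, 60)
    loocv(X, rep(c(1, -1), each = 8))$metrics["GR"]
  })
  # chance-level or below (LOOCV at the null is slightly anti-conservative
  # downward); what must not happen is systematic above-chance accuracy
  expect_lt(mean(accs), 65)
})

test_that("classification metrics follow their closed forms", {
  m <- classMetrics(c(TP = 25, TN = 27, FP = 3, FN = 5))
  expect_equal(round(unname(m), 2), c(86.67, 83.33, 90.00))
  expect_equal(unname(classMetrics(c(TP = 30, TN = 30, FP = 0, FN = 0))),
               c(100, 100, 100))
  expect_equal(unname(classMetrics(c(TP = 0, TN = 0, FP = 3, FN = 5))["GR"]), 0)
  expect_warning(classMetrics(c(TP = 0, TN = 5, FP = 0, FN = 0)), "SS undefined")
  # identity GR = (SS n_pat + SC n_con) / (n_pat + n_con) on random counts
  set.seed(3)
  for (i in 1:20) {
    cts <- c(TP = sample(0:30, 1), TN = sample(0:30, 1),
             FP = sample(1:30, 1), FN = sample(1:30, 1))
    m <- classMetrics(cts)
    npat <- cts["TP"] + cts["FN"]; ncon <- cts["TN"] + cts["FP"]
    expect_equal(unname(m["GR"]),
                 unname((m["SS"] * npat + m["SC"] * ncon) / (npat + ncon)))
  }
})
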