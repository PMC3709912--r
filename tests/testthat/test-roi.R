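test_that("Zung index scoring and normal-range cutoffs", {
  expect_equal(zungIndex(20, "sds")$index, 25)
  expect_equal(zungIndex(80, "sas")$index, 100)
  z <- zungIndex(42, "sds")
  expect_equal(z$index, 52.5)
  expect_true(z$normal)                    # 52.5 < 53
  expect_false(zungIndex(43, "sds")$normal)  # 53.75 >= 53
  expect_true(zungIndex(39, "sas")$normal)   # 48.75 < 50
  expect_false(zungIndex(40, "sas")$normal)  # 50 is not < 50
  expect_error(zungIndex(19), "\\[20, 80\\]")
  expect_error(zungIndex(81), "\\[20, 80\\]")
})

makeWeightMap <- function(w, mask) {
  new("WeightMap", wVoxel = w, mask = mask, wReduced = 1,
      pca = fitPCA(matrix(rnorm(4), 2, 2)),
      svm = newLinearSVM(1, 0, 1, 1L, 1))
}

test_that("peak ROI spheres match a brute-force voxel-centre distance scan", {
  d <- c(10, 10, 10)
  mask <- array(TRUE, d)
  w <- array(0, d)
  w[5, 5, 5] <- 1
  wmap <- makeWeightMap(w, mask)
  cl <- list(voxels = which(w > 0), size = 1L)
  roi <- peakROI(wmap, cl, radiusMM = 6, voxelSizeMM = 3)
  # oracle: scan all voxels, Euclidean distance of centres on a 3 mm grid
  g <- as.matrix(expand.grid(1:10, 1:10, 1:10))
  keep <- sqrt(rowSums((sweep(g, 2, c(5, 5, 5)) * 3)^2)) <= 6
  expect_setequal(roi$voxels, rehomvpa:::linearIndex(g[keep, ], d))
  # centre + 6 faces + 12 edges + 8 corners + 6 at two voxels = 33 at 6 mm / 3 mm
  expect_equal(length(roi$voxels), 33)
  # radius 0 keeps the peak voxel alone
  expect_equal(peakROI(wmap, cl, radiusMM = 0, voxelSizeMM = 3)$voxels,
               which(w > 0))
  # tie at max |w| resolves to the lowest linear index
  w2 <- array(0, d); w2[c(2, 9), 5, 5] <- 1
  cl2 <- list(voxels = which(w2 > 0), size = 2L)
  roi2 <- peakROI(makeWeightMap(w2, mask), cl2, radiusMM = 0)
  expect_equal(roi2$voxels, which(w2 > 0)[1])
  # traversal order of the cluster voxels does not matter
  cl2r <- list(voxels = rev(cl2$voxels), size = 2L)
  expect_equal(peakROI(makeWeightMap(w2, mask), cl2r, radiusMM = 0)$voxels,
               roi2$voxels)
})

test_that("mean ReHo in an ROI averages computable normalised values", {
  d <- c(5, 5, 5)
  kcc <- array(0.5, d)
  comp <- array(TRUE, d)
  m <- new("ReHoMap", kcc = kcc, computable = comp,
           normalized = normalizeReho(kcc, comp), neighborhood = 27L)
  expect_equal(meanRehoInROI(m, list(voxels = 1:10)), 1)
  kcc2 <- array(NA_real_, d); comp2 <- array(FALSE, d)
  kcc2[1:2] <- c(0.8, 1.2) * 0.04; comp2[1:2] <- TRUE
  norm2 <- array(NA_real_, d); norm2[1:2] <- c(0.8, 1.2)
  m2 <- new("ReHoMap", kcc = kcc2, computable = comp2, normalized = norm2,
            neighborhood = 27L)
  expect_equal(meanRehoInROI(m2, list(voxels = 1:2)), 1.0)
  expect_error(meanRehoInROI(m2, list(voxels = 5:6)), "no computable")
  # random maps against a direct mean
  set.seed(4)
  kcc3 <- array(runif(125, 0.2, 0.9), d); comp3 <- array(TRUE, d)
  m3 <- new("ReHoMap", kcc = kcc3, computable = comp3,
            normalized = normalizeReho(kcc3, comp3), neighborhood = 27L)
  vox <- sample(125, 30)
  expect_equal(meanRehoInROI(m3, list(voxels = vox)),
               mean(kcc3[vox] / mean(kcc3)), tolerance = 1e-12)
})

test_that("Pearson correlation matches its closed form, with affine invariance", {
  res <- pearsonCorrelation(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4) + 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-10)

  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  res <- pearsonCorrelation(x, y)
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  tstat <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(res$p, 2 * pt(-tstat, df = 2), tolerance = 1e-12)

  # analytically orthogonal pair
  res0 <- pearsonCorrelation(c(-1, 0, 1, 0), c(0, 1, 0, -1))
  expect_equal(res0$r, 0, tolerance = 1e-12)

  # affine rescaling with positive slope leaves r unchanged
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearsonCorrelation(3 * a + 7, b)$r,
               pearsonCorrelation(a, b)$r, tolerance = 1e-12)
  expect_error(pearsonCorrelation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearsonCorrelation(1:2, 2:1), "at least 3")
})

test_that("Bonferroni adjustment multiplies, caps, and flags at the corrected level", {
  expect_equal(bonferroniAdjust(0.004, m = 1)$p_adjusted, 0.004)
  a <- bonferroniAdjust(0.004, m = 4, alpha = 0.01)
  expect_equal(a$p_adjusted, 0.016)
  expect_false(a$significant)
  expect_equal(bonferroniAdjust(0.3, m = 10)$p_adjusted, 1)
  b <- bonferroniAdjust(c(0.001, 0.04), alpha = 0.01)
  expect_equal(b$p_adjusted, c(0.002, 0.08))
  expect_equal(b$significant, c(TRUE, FALSE))
  # agrees with stats::p.adjust when m = length(p)
  p <- c(0.001, 0.02, 0.2, 0.9)
  expect_equal(bonferroniAdjust(p)$p_adjusted, p.adjust(p, "bonferroni"))
})

test_that("ROI-symptom correlations run over patients with m = rois x variables", {
  coh <- smallCohort(seed = 12, lambda = 0.9, nPerGroup = 6)
  cf <- cohortFeatures(coh)
  wmap <- observedWeightMap(cf$se)
  cl <- list(voxels = which(coh@truth$roiMasks[[1]] & wmap@mask), size = 10L)
  roi <- peakROI(wmap, cl, radiusMM = 6, voxelSizeMM = 3)
  out <- roiCorrelations(cf$maps, list(roi), coh@pheno[cf$keep, ],
                         variables = c("ndi", "duration_months"))
  expect_equal(nrow(out), 2)
  expect_equal(out$n, rep(6, 2))
  expect_equal(out$p_adjusted, pmin(1, out$p_raw * 2))
  expect_true(all(out$r >= -1 & out$r <= 1))
})
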