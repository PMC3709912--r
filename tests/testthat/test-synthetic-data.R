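test_that("identical seeds give bit-identical cohorts; effect is absent at lambda 0", {
  cfg <- simConfig(nPerGroup = 2, gridShape = c(12, 12, 12), nVolumes = 30,
                   synchronyLambda = 0.5, seed = 42)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a@subjects[[1]]$bold, b@subjects[[1]]$bold)
  expect_identical(a@subjects[[3]]$motion, b@subjects[[3]]$motion)
  expect_identical(a@pheno, b@pheno)

  null <- simulateCohort(simConfig(nPerGroup = 2, gridShape = c(12, 12, 12),
                                   nVolumes = 30, synchronyLambda = 0,
                                   seed = 42))
  expect_true(all(null@truth$effect == 0))
  # patients and controls share the generative distribution at lambda = 0:
  # after removing the common per-volume drift, voxel noise has the same SD
  noiseSD <- function(s) {
    m <- matrix(s$bold, ncol = dim(s$bold)[4])
    sd(sweep(m, 2, colMeans(m)))
  }
  expect_equal(noiseSD(null@subjects[[1]]), noiseSD(null@subjects[[3]]),
               tolerance = 0.01)
  expect_equal(noiseSD(null@subjects[[1]]), 1, tolerance = 0.02)
})

test_that("cohort container obeys its invariants", {
  coh <- smallCohort(seed = 3, lambda = 0.6)
  expect_true(validObject(coh))
  expect_false(any(coh@gmMask & coh@wmMask))
  expect_false(any(coh@gmMask & coh@csfMask))
  expect_true(all(coh@truth$roiMasks[[1]] <= coh@gmMask))
  expect_true(all(coh@pheno$ndi >= 0))
  expect_equal(coh@pheno$sds_index, coh@pheno$sds_raw * 1.25)
  expect_true(all(coh@pheno$sds_index >= 25 & coh@pheno$sds_index <= 100))
  # patient planted levels lie in [(1-jitter) lambda, lambda]
  eff <- coh@truth$effect[coh@pheno$group == "patient"]
  expect_true(all(eff >= 0.5 * 0.6 - 1e-12 & eff <= 0.6 + 1e-12))
  expect_true(all(coh@truth$effect[coh@pheno$group == "control"] == 0))
})

test_that("a ROI outside the mask and an invalid lambda are refused", {
  expect_error(simulateCohort(simConfig(
    nPerGroup = 1, gridShape = c(12, 12, 12), nVolumes = 20,
    effectRois = list(list(center = c(2, 2, 2), radius = 2)))),
    "gray-matter mask")
  expect_error(simConfig(synchronyLambda = 1), "synchronyLambda")
  expect_error(simConfig(nVolumes = 10), "nVolumes")
})

test_that("planted synchrony raises in-ROI ReHo monotonically in lambda", {
  lambdas <- c(0, 0.3, 0.6, 0.9)
  means <- sapply(lambdas, function(lam) {
    mean(sapply(1:20, function(s) {
      coh <- simulateCohort(simConfig(nPerGroup = 1, gridShape = c(12, 12, 12),
                                      nVolumes = 40, synchronyLambda = lam,
                                      synchronyJitter = 0, seed = 100 + s))
      m <- rehoMap(coh@subjects[[1]]$bold, coh@gmMask)
      roi <- coh@truth$roiMasks[[1]] & m@computable
      mean(m@kcc[roi])
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("behavioural generator is exactly linear and recovers target correlations", {
  eff <- runif(30, 0.3, 0.9)
  # zero noise, positive slope: perfect correlation
  y <- generateBehavior(eff, slope = 50, noiseSD = 0, intercept = 5)
  expect_equal(unname(cor(eff, y)), 1, tolerance = 1e-12)
  expect_equal(y, 5 + 50 * eff)

  # zero slope: mean |r| below 2/sqrt(n) over 200 seeds
  rs <- sapply(1:200, function(s)
    cor(eff, generateBehavior(eff, 0, 10, seed = s)))
  expect_lt(mean(abs(rs)), 2 / sqrt(30))

  # theoretical r = 0.6: estimated within +-0.15 at n = 30 on average
  sdEff <- sd(eff)
  noise <- 50 * sdEff * sqrt(1 / 0.36 - 1)
  rs <- sapply(1:100, function(s)
    cor(eff, generateBehavior(eff, 50, noise, seed = 1000 + s)))
  expect_lt(abs(mean(rs) - 0.6), 0.15)
})

test_that("cohorts round-trip through disk and the manifest records the seed", {
  coh <- smallCohort(seed = 9, lambda = 0.4, nPerGroup = 2,
                     grid = c(12, 12, 12), nVolumes = 20)
  dir <- file.path(tempdir(), "cohort-roundtrip")
  unlink(dir, recursive = TRUE)
  man <- writeCohort(coh, dir)
  expect_equal(man$seed, 9L)
  # 2 files per subject + 3 masks + truth ROI + phenotype + manifest
  nsub <- length(coh@subjects)
  expect_equal(length(list.files(dir)), 2 * nsub + 3 + 1 + 1 + 1)

  back <- readCohort(dir)
  expect_equal(back@subjects[[1]]$bold, coh@subjects[[1]]$bold,
               tolerance = 1e-6)                    # float32 storage
  expect_identical(back@gmMask, coh@gmMask)
  expect_equal(back@subjects[[2]]$motion, coh@subjects[[2]]$motion,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back@pheno$ndi, coh@pheno$ndi)
  expect_equal(back@truth$effect, coh@truth$effect)
  expect_equal(back@config@seed, coh@config@seed)
})

test_that("deleting a subject's motion file aborts the read naming the subject", {
  coh <- smallCohort(seed = 5, nPerGroup = 2, grid = c(12, 12, 12),
                     nVolumes = 20)
  dir <- file.path(tempdir(), "cohort-broken")
  unlink(dir, recursive = TRUE)
  writeCohort(coh, dir)
  unlink(file.path(dir, "sub-control01_motion.tsv"))
  expect_error(readCohort(dir), "sub-control01")
})
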