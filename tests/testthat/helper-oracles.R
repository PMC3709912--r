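# Independent reference implementations used to cross-check the package.

# Kendall's W via the tie-corrected Friedman statistic: W = chi2_F / (K (n-1))
# with K series (blocks) ranked over n time points (groups).
friedmanW <- function(seriesSet) {
  K <- ncol(seriesSet)
  n <- nrow(seriesSet)
  unname(stats::friedman.test(t(seriesSet))$statistic / (K * (n - 1)))
}

# Connected components by iterative minimum-label propagation (a different
# algorithm from the package's BFS flood fill).
floodFillOracle <- function(bin, connectivity = 26L) {
  d <- dim(bin)
  offs <- rehomvpa:::neighborOffsets(as.integer(connectivity))
  lab <- array(0, d)
  lab[bin] <- which(bin)                 # seed with linear indices
  repeat {
    prev <- lab
    for (r in seq_len(nrow(offs))) {
      sh <- rehomvpa:::shiftArray3d(lab, offs[r, ])
      upd <- bin & sh > 0 & (lab == 0 | sh < lab)
      lab[upd] <- sh[upd]
    }
    if (identical(lab, prev)) break
  }
  # relabel 1..k in order of first appearance
  u <- unique(lab[lab > 0])
  out <- array(0L, d)
  for (i in seq_along(u)) out[lab == u[i]] <- i
  out
}

# Naive triple-loop ReHo reference: for every mask voxel whose full cubic
# neighbourhood is in-mask, Kendall's W of the 27 series via the Friedman
# oracle.
naiveRehoOracle <- function(bold, mask) {
  d <- dim(mask)
  nt <- dim(bold)[4]
  kcc <- array(NA_real_, d)
  comp <- array(FALSE, d)
  for (i in 2:(d[1] - 1)) for (j in 2:(d[2] - 1)) for (k in 2:(d[3] - 1)) {
    if (!mask[i, j, k]) next
    nb <- mask[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
    if (!all(nb)) next
    S <- matrix(0, nt, 27)
    c2 <- 0
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      c2 <- c2 + 1
      S[, c2] <- bold[i + di, j + dj, k + dk, ]
    }
    kcc[i, j, k] <- friedmanW(S)
    comp[i, j, k] <- TRUE
  }
  list(kcc = kcc, computable = comp)
}

# Small planted-effect cohort used by several tests.
smallCohort <- function(seed = 1, lambda = 0.9, nPerGroup = 5,
                        grid = c(12, 12, 12), nVolumes = 60) {
  simulateCohort(simConfig(nPerGroup = nPerGroup, gridShape = grid,
                           nVolumes = nVolumes, synchronyLambda = lambda,
                           seed = seed))
}

# ReHo feature SummarizedExperiment for a cohort, with preprocessing.
cohortFeatures <- function(cohort, config = pipelineConfig(sim = cohort@config)) {
  pp <- preprocessCohort(cohort, config)
  maps <- lapply(pp$bold, rehoMap, gmMask = cohort@gmMask)
  list(se = buildFeatureMatrix(maps, cohort@pheno$label[pp$keep],
                               cohort@pheno[pp$keep, , drop = FALSE]),
       maps = maps, keep = pp$keep)
}
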