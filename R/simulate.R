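#' Create a simulation configuration
#'
#' Defaults emulate the acquisition the pipeline targets: 30 subjects per
#' group, 150 volumes at TR = 2 s, 3 mm isotropic voxels, one spherical
#' planted-synchrony ROI at the grid centre.  The behavioural defaults couple
#' the NDI symptom score to the planted synchrony with a theoretical Pearson
#' correlation of 0.6 (see the methods vignette).
#'
#' @param nPerGroup subjects per group.
#' @param gridShape grid dimensions in voxels.
#' @param voxelSizeMM isotropic voxel size, mm.
#' @param nVolumes time points per subject (must exceed the 10 discarded).
#' @param trS repetition time, seconds.
#' @param effectRois list of \code{list(center=, radius=)} in voxel units;
#'   \code{NULL} places one radius-2 sphere at the grid centre.
#' @param synchronyLambda shared-signal mixing weight in \code{[0, 1)}.
#' @param synchronyJitter per-subject spread of the planted level (see
#'   [SimConfig-class]).
#' @param noiseSD baseline noise SD, BOLD a.u.
#' @param behavSlope NDI units per unit planted synchrony.
#' @param behavNoiseSD behavioural noise SD; the default gives theoretical
#'   r = 0.6 between NDI and the planted level under the default lambda.
#' @param seed RNG seed.
#' @return a validated [SimConfig-class].
#' @export
#' @examples
#' cfg <- simConfig(nPerGroup = 5, gridShape = c(12, 12, 12), nVolumes = 60)
simConfig <- function(nPerGroup = 30, gridShape = c(16, 16, 16),
                      voxelSizeMM = 3, nVolumes = 150, trS = 2,
                      effectRois = NULL, synchronyLambda = 0.6,
                      synchronyJitter = 0.5, noiseSD = 1,
                      behavSlope = 120, behavNoiseSD = NULL, seed = 1) {
  gridShape <- as.integer(gridShape)
  if (is.null(effectRois))
    effectRois <- list(list(center = round(gridShape / 2), radius = 2))
  if (is.null(behavNoiseSD)) {
    # sd of U((1-jitter)*lambda, lambda), then noise for theoretical r = 0.6
    sdEff <- synchronyJitter * synchronyLambda / sqrt(12)
    behavNoiseSD <- if (sdEff > 0) behavSlope * sdEff * sqrt(1 / 0.36 - 1) else 10
  }
  new("SimConfig", nPerGroup = as.integer(nPerGroup), gridShape = gridShape,
      voxelSizeMM = voxelSizeMM, nVolumes = as.integer(nVolumes), trS = trS,
      effectRois = effectRois, synchronyLambda = synchronyLambda,
      synchronyJitter = synchronyJitter, noiseSD = noiseSD,
      behavSlope = behavSlope, behavNoiseSD = behavNoiseSD,
      seed = as.integer(seed))
}

# Tissue masks on the synthetic grid: gray matter is the central box two
# voxels in from every face; white matter and CSF are thin slabs on the
# first/last x-planes, disjoint from gray matter by construction.
cohortMasks <- function(gridShape) {
  d <- gridShape
  gm <- array(FALSE, d)
  gm[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE
  wm <- array(FALSE, d)
  wm[1, 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE
  csf <- array(FALSE, d)
  csf[d[1], 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE
  list(gm = gm, wm = wm, csf = csf)
}

#' Generate behavioural scores linearly coupled to a planted effect
#'
#' \code{score_i = intercept + slope * effect_i + eps_i},
#' \code{eps_i ~ N(0, noiseSD^2)}.  The population Pearson correlation
#' between effect and score is \code{slope * sd(effect) / sd(score)}.
#'
#' @param effect numeric vector of per-subject planted effect levels.
#' @param slope score units per unit effect (finite).
#' @param noiseSD noise SD, score units (>= 0).
#' @param intercept baseline score.
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @return numeric vector of scores.
#' @export
generateBehavior <- function(effect, slope, noiseSD, intercept = 0,
                             seed = NULL) {
  stopifnot(is.finite(slope), noiseSD >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  intercept + slope * effect + rnorm(length(effect), 0, noiseSD)
}

#' Simulate an aligned two-group resting-state cohort
#'
#' Baseline voxel time series are independent Gaussian noise plus a common
#' slow AR(1) drift (rho = 0.3) and a small linear trend.  In each planted
#' ROI, each patient's voxel noise is mixed with one shared regional signal
#' s(t): \code{v'(t) = (1 - lambda_i) v(t) + lambda_i s(t)}, which raises
#' local temporal synchrony monotonically in lambda.  Motion tables are
#' small-amplitude random walks that pass the default 1.5 mm / 1.5 deg QC
#' gate; \code{injectHighMotion} spikes the first patient for QC tests.
#' Behavioural scores are generated by [generateBehavior()] from the
#' per-subject planted level.  Deterministic given \code{config@seed}.
#'
#' @param config a [SimConfig-class].
#' @param injectHighMotion add a 2 mm translation spike to subject 1.
#' @return an [FmriCohort-class] with ground truth.
#' @export
#' @examples
#' coh <- simulateCohort(simConfig(nPerGroup = 2, gridShape = c(12, 12, 12),
#'                                 nVolumes = 20, seed = 7))
#' coh
simulateCohort <- function(config, injectHighMotion = FALSE) {
  validObject(config)
  d <- config@gridShape
  nt <- config@nVolumes
  masks <- cohortMasks(d)

  roiMasks <- lapply(config@effectRois, function(r) {
    m <- roiMaskFromSpec(r$center, r$radius, d)
    shell <- m
    for (off in seq_len(nrow(neighborOffsets(26L))))
      shell <- shell | shiftArray3d(m, neighborOffsets(26L)[off, ])
    if (any(shell & !masks$gm))
      stop("effect ROI (plus its 1-voxel shell) must lie inside the gray-matter mask")
    m
  })

  set.seed(config@seed)
  n <- config@nPerGroup
  groups <- rep(c("patient", "control"), each = n)
  ids <- sprintf("sub-%s%02d", groups, c(seq_len(n), seq_len(n)))
  lam <- config@synchronyLambda
  effect <- c(lam - config@synchronyJitter * lam * runif(n), numeric(n))

  nv <- prod(d)
  subjects <- vector("list", 2L * n)
  for (s in seq_len(2L * n)) {
    noise <- array(rnorm(nv * nt, 0, config@noiseSD), c(d, nt))
    if (effect[s] > 0) {
      for (rm in roiMasks) {
        sh <- rnorm(nt, 0, config@noiseSD)       # shared regional signal s(t)
        vox <- which(rm)
        idx <- rep(vox, nt) + rep((seq_len(nt) - 1L) * nv, each = length(vox))
        noise[idx] <- (1 - effect[s]) * noise[idx] +
          effect[s] * rep(sh, each = length(vox))
      }
    }
    # common slow drift: AR(1) rho 0.3 plus a gentle linear trend
    ar <- as.numeric(stats::filter(rnorm(nt, 0, 0.5 * config@noiseSD),
                                   0.3, method = "recursive"))
    trend <- rnorm(1, 0, 0.005 * config@noiseSD) * seq_len(nt)
    drift <- ar + trend
    noise <- noise + rep(drift, each = nv)

    # mean-reverting random walk (AR(1), rho 0.97, step sd 0.05 mm/deg):
    # drifts like head motion but stays well inside the 1.5 mm/deg QC gate
    motion <- apply(matrix(rnorm(nt * 6, 0, 0.05), nt, 6), 2,
                    function(e) as.numeric(stats::filter(e, 0.97,
                                                         method = "recursive")))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    if (injectHighMotion && s == 1L) motion[max(11L, nt %/% 2L), 1] <- 2.0
    subjects[[s]] <- list(id = ids[s], group = groups[s],
                          bold = noise, motion = motion)
  }

  # behaviour: NDI coupled to the planted level; Zung scales and duration
  # are realistic dressing with no coupling
  meanEff <- lam * (1 - config@synchronyJitter / 2)
  ndiIntercept <- 48.73 - config@behavSlope * meanEff
  ndi <- generateBehavior(effect, config@behavSlope, config@behavNoiseSD,
                          intercept = 0)
  ndi <- ndi + ifelse(groups == "patient", ndiIntercept, 1.37)
  ndi <- pmax(ndi, 0)
  clampRaw <- function(x) pmin(80L, pmax(20L, as.integer(round(x))))
  sdsRaw <- clampRaw(rnorm(2 * n, ifelse(groups == "patient", 43.04, 33.38) / 1.25,
                           ifelse(groups == "patient", 8.2, 5.3)))
  sasRaw <- clampRaw(rnorm(2 * n, ifelse(groups == "patient", 41.79, 33.83) / 1.25,
                           ifelse(groups == "patient", 6.8, 5.0)))
  duration <- ifelse(groups == "patient",
                     round(rlnorm(2 * n, log(24), 0.6), 1), NA_real_)

  pheno <- data.frame(
    id = ids, group = groups,
    label = ifelse(groups == "patient", 1L, -1L),
    ndi = ndi, sds_raw = sdsRaw, sas_raw = sasRaw,
    sds_index = sdsRaw * 1.25, sas_index = sasRaw * 1.25,
    duration_months = duration, stringsAsFactors = FALSE)

  new("FmriCohort", subjects = subjects, gmMask = masks$gm,
      wmMask = masks$wm, csfMask = masks$csf, pheno = pheno,
      truth = list(roiMasks = roiMasks, effect = effect),
      config = config)
}

#' Write a cohort to disk as NIfTI + TSV + JSON manifest
#'
#' One 4D NIfTI per subject, one NIfTI per tissue mask and per truth ROI,
#' one motion TSV per subject, a phenotype TSV and a JSON manifest carrying
#' the seed and configuration.  Volumes are stored as 32-bit floats.
#'
#' @param cohort an [FmriCohort-class].
#' @param dir output directory (created if absent).
#' @return the manifest, invisibly.
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  cfg <- cohort@config
  pix <- rep(cfg@voxelSizeMM, 3)
  wvol <- function(a, path, dt) {
    img <- RNifti::asNifti(a * 1)
    RNifti::pixdim(img) <- if (length(dim(a)) == 4L) c(pix, cfg@trS) else pix
    RNifti::writeNifti(img, path, datatype = dt)
    basename(path)
  }
  files <- list()
  for (s in cohort@subjects) {
    files[[paste0(s$id, "_bold")]] <-
      wvol(s$bold, file.path(dir, paste0(s$id, "_bold.nii.gz")), "float")
    mf <- file.path(dir, paste0(s$id, "_motion.tsv"))
    write.table(s$motion, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[paste0(s$id, "_motion")]] <- basename(mf)
  }
  files$gm_mask <- wvol(cohort@gmMask, file.path(dir, "mask_gm.nii.gz"), "uint8")
  files$wm_mask <- wvol(cohort@wmMask, file.path(dir, "mask_wm.nii.gz"), "uint8")
  files$csf_mask <- wvol(cohort@csfMask, file.path(dir, "mask_csf.nii.gz"), "uint8")
  for (i in seq_along(cohort@truth$roiMasks))
    files[[paste0("truth_roi", i)]] <-
      wvol(cohort@truth$roiMasks[[i]],
           file.path(dir, sprintf("truth_roi%02d.nii.gz", i)), "uint8")
  write.table(cohort@pheno, file.path(dir, "phenotype.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files$phenotype <- "phenotype.tsv"

  manifest <- list(
    seed = cfg@seed,
    config = list(
      nPerGroup = cfg@nPerGroup, gridShape = cfg@gridShape,
      voxelSizeMM = cfg@voxelSizeMM, nVolumes = cfg@nVolumes, trS = cfg@trS,
      effectRois = cfg@effectRois, synchronyLambda = cfg@synchronyLambda,
      synchronyJitter = cfg@synchronyJitter, noiseSD = cfg@noiseSD,
      behavSlope = cfg@behavSlope, behavNoiseSD = cfg@behavNoiseSD),
    truthEffect = cohort@truth$effect,
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing \code{manifest.json}.
#' @return an [FmriCohort-class]; arrays equal the written ones within the
#'   32-bit storage dtype.
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cc <- man$config
  cfg <- simConfig(nPerGroup = cc$nPerGroup, gridShape = cc$gridShape,
                   voxelSizeMM = cc$voxelSizeMM, nVolumes = cc$nVolumes,
                   trS = cc$trS,
                   effectRois = parseEffectRois(cc$effectRois),
                   synchronyLambda = cc$synchronyLambda,
                   synchronyJitter = cc$synchronyJitter, noiseSD = cc$noiseSD,
                   behavSlope = cc$behavSlope, behavNoiseSD = cc$behavNoiseSD,
                   seed = man$seed)
  rvol <- function(name) {
    a <- readVolume(file.path(dir, name))$data
    a
  }
  pheno <- read.table(file.path(dir, "phenotype.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(pheno)), function(i) {
    id <- pheno$id[i]
    mfile <- file.path(dir, paste0(id, "_motion.tsv"))
    bfile <- file.path(dir, paste0(id, "_bold.nii.gz"))
    for (f in c(mfile, bfile))
      if (!file.exists(f))
        stop("missing file for subject ", id, ": ", basename(f))
    motion <- as.matrix(read.table(mfile, sep = "\t", header = TRUE))
    list(id = id, group = pheno$group[i],
         bold = rvol(basename(bfile)), motion = motion)
  })
  roiNames <- grep("^truth_roi", names(man$files), value = TRUE)
  roiMasks <- lapply(roiNames, function(nm) rvol(man$files[[nm]]) > 0.5)
  new("FmriCohort", subjects = subjects,
      gmMask = rvol("mask_gm.nii.gz") > 0.5,
      wmMask = rvol("mask_wm.nii.gz") > 0.5,
      csfMask = rvol("mask_csf.nii.gz") > 0.5,
      pheno = pheno,
      truth = list(roiMasks = roiMasks, effect = man$truthEffect),
      config = cfg)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @return list with \code{data} (plain array), \code{voxelSizeMM} and the
#'   4x4 \code{affine} (world mm via the file's affine).
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path))
  list(data = array(as.numeric(img), dim(img)),
       voxelSizeMM = RNifti::pixdim(img)[1:min(3, length(dim(img)))],
       affine = structure(RNifti::xform(img), class = "matrix"))
}
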