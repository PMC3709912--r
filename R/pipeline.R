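#' Full analysis configuration
#'
#' One place holding every stage's parameters; each default is the
#' pipeline's canonical value (10 discarded volumes, 0.01-0.08 Hz band,
#' 1.5 mm / 1.5 deg motion gate, 27-voxel neighbourhood, C = 1, 5000
#' permutations, voxel level 0.02, minimum cluster 10 voxels, cluster level
#' 0.001, 6 mm ROI spheres, Bonferroni 0.01).  Stage code reads constants
#' from here only.
#'
#' @param sim a [SimConfig-class] describing the cohort to simulate (or the
#'   geometry of a cohort read from disk).
#' @param nDiscard,lowHz,highHz,filterType temporal preprocessing.
#' @param maxTranslationMM,maxRotationDeg motion QC gate.
#' @param neighborhood,edgePolicy ReHo settings.
#' @param C SVM box constraint.
#' @param pcaGlobal leaky global-PCA LOOCV variant.
#' @param nPerm,voxelAlpha,minClusterVoxels,clusterAlpha,connectivity
#'   permutation inference.
#' @param roiRadiusMM,corrAlpha,corrVariables ROI correlation stage.
#' @param seed analysis seed (permutation stream).
#' @return a named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(sim = simConfig(),
                           nDiscard = 10L, lowHz = 0.01, highHz = 0.08,
                           filterType = "ideal",
                           maxTranslationMM = 1.5, maxRotationDeg = 1.5,
                           neighborhood = 27L,
                           edgePolicy = "all_neighbors_required",
                           C = 1, pcaGlobal = FALSE,
                           nPerm = 5000L, voxelAlpha = 0.02,
                           minClusterVoxels = 10L, clusterAlpha = 0.001,
                           connectivity = 26L,
                           roiRadiusMM = 6, corrAlpha = 0.01,
                           corrVariables = c("ndi", "duration_months"),
                           seed = 1L) {
  structure(list(
    sim = sim, nDiscard = as.integer(nDiscard), lowHz = lowHz, highHz = highHz,
    filterType = filterType, maxTranslationMM = maxTranslationMM,
    maxRotationDeg = maxRotationDeg, neighborhood = as.integer(neighborhood),
    edgePolicy = edgePolicy, C = C, pcaGlobal = pcaGlobal,
    nPerm = as.integer(nPerm), voxelAlpha = voxelAlpha,
    minClusterVoxels = as.integer(minClusterVoxels),
    clusterAlpha = clusterAlpha, connectivity = as.integer(connectivity),
    roiRadiusMM = roiRadiusMM, corrAlpha = corrAlpha,
    corrVariables = corrVariables, seed = as.integer(seed)),
    class = "PipelineConfig")
}

#' Write / read a pipeline configuration as JSON
#'
#' The write-read-write round trip is idempotent.
#' @param config a \code{PipelineConfig}.
#' @param path JSON file path.
#' @return \code{readPipelineConfig} returns a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  x <- unclass(config)
  s <- config$sim
  x$sim <- list(nPerGroup = s@nPerGroup, gridShape = s@gridShape,
                voxelSizeMM = s@voxelSizeMM, nVolumes = s@nVolumes,
                trS = s@trS, effectRois = s@effectRois,
                synchronyLambda = s@synchronyLambda,
                synchronyJitter = s@synchronyJitter, noiseSD = s@noiseSD,
                behavSlope = s@behavSlope, behavNoiseSD = s@behavNoiseSD,
                seed = s@seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- x$sim
  rois <- parseEffectRois(sc$effectRois)
  sim <- simConfig(nPerGroup = sc$nPerGroup, gridShape = sc$gridShape,
                   voxelSizeMM = sc$voxelSizeMM, nVolumes = sc$nVolumes,
                   trS = sc$trS, effectRois = rois,
                   synchronyLambda = sc$synchronyLambda,
                   synchronyJitter = sc$synchronyJitter, noiseSD = sc$noiseSD,
                   behavSlope = sc$behavSlope, behavNoiseSD = sc$behavNoiseSD,
                   seed = sc$seed)
  do.call(pipelineConfig, c(list(sim = sim),
                            x[setdiff(names(x), c("sim"))]))
}

#' Preprocess every subject of a cohort
#'
#' Runs motion QC then discard / nuisance regression / band-pass per
#' subject.  Subjects failing QC are excluded and logged.
#'
#' @param cohort an [FmriCohort-class].
#' @param config a \code{PipelineConfig}.
#' @return list: \code{bold} (list of preprocessed 4D arrays, QC passers
#'   only), \code{keep} (indices kept), \code{qc} (per-subject QC results),
#'   \code{stages} (stage order log).
#' @export
preprocessCohort <- function(cohort, config = pipelineConfig()) {
  qc <- lapply(cohort@subjects, function(s)
    qcMotion(s$motion, config$maxTranslationMM, config$maxRotationDeg))
  keep <- which(vapply(qc, `[[`, logical(1), "pass"))
  if (length(keep) == 0L) stop("no subject passes motion QC")
  stages <- NULL
  bold <- lapply(keep, function(i) {
    s <- cohort@subjects[[i]]
    pp <- preprocessSubject(s$bold, s$motion, cohort@gmMask, cohort@wmMask,
                            cohort@csfMask, nDiscard = config$nDiscard,
                            lowHz = config$lowHz, highHz = config$highHz,
                            trS = cohort@config@trS,
                            filterType = config$filterType)
    stages <<- pp$stages
    pp$bold
  })
  list(bold = bold, keep = keep, qc = qc, stages = c(stages, "reho"))
}

#' Run the whole discrimination pipeline on a cohort
#'
#' simulate (optional) -> motion QC / discard / nuisance / band-pass ->
#' ReHo -> LOOCV classification -> full-data weight map + permutation
#' inference -> clusters -> peak ROIs -> patient ReHo-symptom correlations.
#' Deterministic given the cohort seed and \code{config$seed}.
#'
#' @param config a \code{PipelineConfig}; its \code{sim} element defines the
#'   cohort when none is supplied.
#' @param cohort optional pre-built [FmriCohort-class] (e.g. from
#'   [readCohort()]); when absent one is simulated from \code{config$sim}.
#' @param outDir optional directory; when given, intermediate maps and
#'   tables are persisted (NIfTI / TSV / JSON).
#' @return a run report list: \code{stages}, \code{qc}, \code{metrics},
#'   \code{counts}, \code{clusterTable}, \code{correlations}, \code{rois},
#'   plus the intermediate objects (\code{rehoMaps}, \code{features},
#'   \code{weightMap}, \code{pMap}) and \code{seed}, \code{version},
#'   \code{timings}.
#' @export
runPipeline <- function(config = pipelineConfig(), cohort = NULL,
                        outDir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  if (is.null(cohort)) cohort <- simulateCohort(config$sim)
  tick("simulate")

  pp <- preprocessCohort(cohort, config)
  tick("preproc")
  labels <- cohort@pheno$label[pp$keep]
  pheno <- cohort@pheno[pp$keep, , drop = FALSE]

  maps <- lapply(pp$bold, rehoMap, gmMask = cohort@gmMask,
                 neighborhood = config$neighborhood,
                 edgePolicy = config$edgePolicy)
  tick("reho")

  se <- buildFeatureMatrix(maps, labels, pheno)
  cv <- loocv(se, C = config$C, pcaGlobal = config$pcaGlobal)
  tick("loocv")

  wmap <- observedWeightMap(se, C = config$C)
  null <- permutationNull(se, nPerm = config$nPerm,
                          voxelAlpha = config$voxelAlpha,
                          clusterAlpha = config$clusterAlpha,
                          connectivity = config$connectivity,
                          C = config$C, seed = config$seed)
  pMap <- voxelPValues(wmap, null)
  clusters <- extractClusters(pMap, config$voxelAlpha,
                              config$minClusterVoxels, config$connectivity)
  ctab <- clusterPValues(clusters, wmap, null, pMap, config$clusterAlpha,
                         voxelSizeMM = cohort@config@voxelSizeMM)
  tick("permutation")

  sig <- which(ctab$significant)
  rois <- lapply(sig, function(ci)
    peakROI(wmap, clusters[[ci]], radiusMM = config$roiRadiusMM,
            voxelSizeMM = cohort@config@voxelSizeMM))
  correlations <- if (length(rois) > 0)
    roiCorrelations(maps, rois, pheno, config$corrVariables,
                    alpha = config$corrAlpha)
  else data.frame()
  tick("roi_correlation")

  report <- list(
    stages = pp$stages, qc = pp$qc, keep = pp$keep,
    counts = cv$counts, metrics = cv$metrics, predicted = cv$predicted,
    clusterTable = ctab, clusters = clusters, rois = rois,
    correlations = correlations,
    rehoMaps = maps, features = se, weightMap = wmap, pMap = pMap,
    null = list(maxClusterSizes = null$maxClusterSizes, nPerm = null$nPerm),
    seed = config$seed,
    version = as.character(utils::packageVersion("rehomvpa")),
    timings = timings)

  if (!is.null(outDir)) persistReport(report, cohort, config, outDir)
  report
}

# Persist the user-facing outputs of a run: weight map, p-map, cluster and
# correlation tables, and a JSON summary.
persistReport <- function(report, cohort, config, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  pix <- rep(cohort@config@voxelSizeMM, 3)
  wnii <- function(a, name) {
    a[is.na(a)] <- 0
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- pix
    RNifti::writeNifti(img, file.path(outDir, name), datatype = "float")
  }
  wnii(report$weightMap@wVoxel, "weight_map.nii.gz")
  wnii(report$pMap, "voxel_p.nii.gz")
  write.table(report$clusterTable, file.path(outDir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$correlations))
    write.table(report$correlations, file.path(outDir, "correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(metrics = as.list(report$metrics), counts = as.list(report$counts),
         stages = report$stages, seed = report$seed,
         version = report$version, timings = as.list(report$timings)),
    file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(outDir)
}
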