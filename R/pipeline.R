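#' Run configuration for the end-to-end study
#'
#' @param cohort a [cohortSpec()] for a synthetic cohort, or \code{NULL}
#'   when reading images from disk.
#' @param imageDir,metadataCsv image directory plus sidecar CSV, used when
#'   \code{cohort} is NULL.
#' @param trainSource source label selecting the training (reference)
#'   subset; the default trains on postmortem components only, the design
#'   that treats well-functioning components as the gold standard.
#' @param mapRows,mapCols lattice dimensions (default 12 x 10).
#' @param radiusInitial,radiusFinal neighborhood radii (default 4 to 1).
#' @param roughEpochs,fineEpochs two-phase epoch counts.
#' @param mode training mode, \code{"batch"} or \code{"sequential"}.
#' @param kernel neighborhood kernel.
#' @param delineateMethod,delineateQ,delineateTol cluster delineation
#'   settings (see [delineateClusters()]).
#' @param robustnessSeeds number of retraining seeds for the robustness
#'   protocol (default 3).
#' @param masterSeed master seed; every other seed is derived from it.
#' @return a \code{runConfig} list.
#' @export
runConfig <- function(cohort = NULL, imageDir = NULL, metadataCsv = NULL,
                      trainSource = "postmortem",
                      mapRows = 12L, mapCols = 10L,
                      radiusInitial = 4, radiusFinal = 1,
                      roughEpochs = 10L, fineEpochs = 40L,
                      mode = "batch", kernel = "gaussian",
                      delineateMethod = "threshold", delineateQ = 0.5,
                      delineateTol = NULL,
                      robustnessSeeds = 3L, masterSeed = 1L) {
  if (is.null(cohort) && (is.null(imageDir) || is.null(metadataCsv)))
    stop("supply either a cohort spec or imageDir + metadataCsv")
  structure(list(cohort = cohort, imageDir = imageDir,
                 metadataCsv = metadataCsv, trainSource = trainSource,
                 mapRows = as.integer(mapRows), mapCols = as.integer(mapCols),
                 radiusInitial = radiusInitial, radiusFinal = radiusFinal,
                 roughEpochs = as.integer(roughEpochs),
                 fineEpochs = as.integer(fineEpochs),
                 mode = mode, kernel = kernel,
                 delineateMethod = delineateMethod,
                 delineateQ = delineateQ, delineateTol = delineateTol,
                 robustnessSeeds = as.integer(robustnessSeeds),
                 masterSeed = as.integer(masterSeed)),
            class = "runConfig")
}

# Load or simulate the cohort, standardize and right-normalize.
.pipelineCohort <- function(config) {
  if (!is.null(config$cohort)) {
    coh <- sampleCohort(config$cohort)
    images <- coh$images
    tab <- coh$table
  } else {
    images <- readCohortImages(config$imageDir, config$metadataCsv)
    tab <- utils::read.csv(config$metadataCsv, stringsAsFactors = FALSE)
  }
  images <- lapply(images, standardizeImage)
  ref <- Filter(function(im) side(im) == "right", images)
  images <- lapply(images, function(im) {
    if (side(im) == "unknown") im@side <- inferSide(im, ref)
    toRightSide(im)
  })
  list(images = images, table = tab)
}

#' Run the full wear-scar clustering study
#'
#' Simulates (or ingests) a cohort, standardizes and right-normalizes
#' every image, encodes the pixel matrix, trains the map on the reference
#' subset only (no information from held-out components reaches the
#' codebook), delineates clusters on the u-matrix, assigns every
#' component, runs the multi-seed robustness protocol, computes shape
#' descriptors with per-cluster ANOVA and covariate regressions, and the
#' binomial co-clustering probability of the simulator components. All
#' tables, the model, the u-matrix (CSV + PNG) and a manifest are written
#' under \code{outputDir}; an identical config reproduces every numeric
#' output byte for byte.
#'
#' @param config a [runConfig()].
#' @param outputDir output directory (created if needed); \code{NULL}
#'   skips all file output.
#' @param writeImages also write the standardized masks as PBM (default
#'   FALSE).
#' @return list with \code{images, table} (with \code{cluster} column),
#'   \code{model, umatrix, clustermap, composition, robustness,
#'   descriptors, regressions, enrichment, qe}.
#' @export
runPipeline <- function(config, outputDir = NULL, writeImages = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  coh <- .pipelineCohort(config)
  images <- coh$images
  tab <- coh$table

  X <- t(vapply(images, encodeImage, integer(STD_ROWS * STD_COLS)))
  trainIdx <- which(tab$source == config$trainSource)
  if (length(trainIdx) == 0L)
    stop(sprintf("training-subset selection failed: no components with source '%s'",
                 config$trainSource))

  radii <- twoPhaseSchedule(config$radiusInitial, config$radiusFinal,
                            config$roughEpochs, config$fineEpochs)
  seeds <- deriveSeeds(config$masterSeed, config$robustnessSeeds + 1L)
  trainSeed <- seeds[1L]

  model <- sofmInit(config$mapRows, config$mapCols,
                    data = X[trainIdx, , drop = FALSE], mode = "sample",
                    seed = trainSeed, kernel = config$kernel)
  model <- sofmTrain(model, X[trainIdx, , drop = FALSE], radii = radii,
                     mode = config$mode, seed = trainSeed)
  um <- uMatrix(model)
  cmap <- delineateClusters(um, method = config$delineateMethod,
                            q = config$delineateQ, tol = config$delineateTol)
  tab$cluster <- assignCluster(model, cmap, X)
  comp <- compositionTable(tab$cluster, tab$source)

  ensemble <- retrainEnsemble(
    X, config = list(rows = config$mapRows, cols = config$mapCols,
                     radii = radii, mode = config$mode,
                     kernel = config$kernel,
                     delineate = list(method = config$delineateMethod,
                                      q = config$delineateQ,
                                      tol = config$delineateTol)),
    seeds = seeds[-1L], trainIndex = trainIdx)
  robust <- robustnessReport(ensemble)

  desc <- descriptorTable(images)
  stats_ <- merge(tab, desc, by = "component_id", sort = TRUE)
  regs <- list()
  for (dname in c("med_area", "lat_area", "med_perimeter", "lat_perimeter"))
    for (cov in c("time_in_host", "age_at_surgery"))
      regs[[paste(dname, cov, sep = "~")]] <-
        covariateRegression(stats_, dname, cov)
  regTable <- do.call(rbind, regs)
  rownames(regTable) <- NULL

  # chance probability that the observed number of simulator components
  # co-cluster, with success prob = fraction of retrieved components there
  simIdx <- tab$source == "simulator"
  enrich <- NULL
  if (any(simIdx)) {
    simClusters <- tab$cluster[simIdx]
    modal <- as.integer(names(which.max(table(simClusters))))
    k <- sum(simClusters == modal)
    pHit <- comp$frac_retrieved[comp$cluster == modal]
    enrich <- list(cluster = modal, n = sum(simIdx), k = k, p = pHit,
                   tailProbability = binomialEnrichment(sum(simIdx), k, pHit))
  }

  qe <- quantizationError(model, X[trainIdx, , drop = FALSE])
  result <- list(images = images, table = tab, model = model, umatrix = um,
                 clustermap = cmap, composition = comp, robustness = robust,
                 descriptors = stats_, regressions = regTable,
                 enrichment = enrich, qe = qe)

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(outputDir, f)
    data.table::fwrite(tab, fp("assignments.csv"))
    data.table::fwrite(comp, fp("composition.csv"))
    data.table::fwrite(stats_, fp("descriptors.csv"))
    data.table::fwrite(regTable, fp("regressions.csv"))
    data.table::fwrite(data.table::as.data.table(X), fp("encoded_matrix.csv"))
    writeSOFM(model, fp("model.txt"))
    exportUMatrix(um, csvPath = fp("umatrix.csv"), pngPath = fp("umatrix.png"))
    exportClusterMap(cmap, fp("clustermap.csv"))
    robustnessReport(ensemble, csvPath = fp("robustness.csv"),
                     jsonPath = fp("robustness.json"))
    if (writeImages) {
      dir.create(fp("masks"), showWarnings = FALSE)
      for (im in images)
        writeMask(im, file.path(fp("masks"),
                                paste0(componentId(im), ".pbm")), "pbm4")
    }
    manifest <- list(
      config = config[setdiff(names(config), "cohort")],
      cohortMasterSeed = if (!is.null(config$cohort)) config$cohort$masterSeed,
      trainSeed = trainSeed, robustnessSeeds = seeds[-1L],
      nComponents = nrow(tab), nTrain = length(trainIdx),
      qe = qe, nClusters = nClusters(cmap),
      packageVersion = as.character(utils::packageVersion("scarSOM")),
      rVersion = R.version.string)
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  result
}

#' Sensitivity scan over map sizes and radius schedules
#'
#' Trains one map per configuration on the training subset and reports
#' the final quantization error and the number of delineated clusters.
#' The selected configuration is the one with the smallest quantization
#' error among those with at least \code{minClusters} clusters — an
#' automated proxy for requiring a well-defined clustering structure,
#' which is why a large map with a marginally lower error but no visible
#' cluster boundaries can lose to a smaller one.
#'
#' @param data samples x dimension training matrix.
#' @param mapDims list of \code{c(rows, cols)} pairs.
#' @param radiusPairs list of \code{c(initial, final)} pairs; recycled
#'   against \code{mapDims} when of length 1.
#' @param roughEpochs,fineEpochs epochs per phase.
#' @param mode,kernel training mode and kernel.
#' @param delineateQ threshold quantile for cluster counting.
#' @param minClusters minimum cluster count for a configuration to be
#'   selectable (default 2).
#' @param seed training seed shared by all configurations.
#' @return data.frame with one row per configuration (\code{rows, cols,
#'   radius_initial, radius_final, qe, n_clusters, selected}).
#' @export
sensitivityScan <- function(data, mapDims, radiusPairs = list(c(4, 1)),
                            roughEpochs = 10L, fineEpochs = 40L,
                            mode = "batch", kernel = "gaussian",
                            delineateQ = 0.5, minClusters = 2L, seed = 1L) {
  if (length(mapDims) == 0L) stop("empty scan list")
  if (length(radiusPairs) == 1L)
    radiusPairs <- rep(radiusPairs, length(mapDims))
  if (length(radiusPairs) != length(mapDims))
    stop("mapDims and radiusPairs lengths differ")
  X <- as.matrix(data)
  rows <- lapply(seq_along(mapDims), function(i) {
    md <- mapDims[[i]]; rp <- radiusPairs[[i]]
    radii <- twoPhaseSchedule(rp[1L], rp[2L], roughEpochs, fineEpochs)
    model <- sofmInit(md[1L], md[2L], data = X, mode = "sample",
                      seed = seed, kernel = kernel)
    model <- sofmTrain(model, X, radii = radii, mode = mode, seed = seed)
    cmap <- delineateClusters(uMatrix(model), q = delineateQ)
    data.frame(rows = md[1L], cols = md[2L],
               radius_initial = rp[1L], radius_final = rp[2L],
               qe = quantizationError(model, X),
               n_clusters = nClusters(cmap))
  })
  out <- do.call(rbind, rows)
  eligible <- out$n_clusters >= minClusters
  out$selected <- FALSE
  if (any(eligible))
    out$selected[which(eligible)[which.min(out$qe[eligible])]] <- TRUE
  out
}
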