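# Shared fixtures, all generated in code.

# shortened two-phase schedule used by the heavier training tests
radiiShort <- function() twoPhaseSchedule(4, 1, roughEpochs = 5L,
                                          fineEpochs = 15L)

# the study-structure cohort: 21 postmortem / 54 revision / 6 simulator
studyCohortSpec <- function(masterSeed = 11L) {
  cohortSpec(list(list(pop = presetPopulation("postmortem"), n = 21),
                  list(pop = presetPopulation("revision"), n = 54),
                  list(pop = presetPopulation("simulator"), n = 6)),
             masterSeed = masterSeed)
}

# encoded matrix + table of a standardized, right-normalized cohort
encodedCohort <- function(spec) {
  coh <- sampleCohort(spec)
  imgs <- lapply(coh$images, function(i) toRightSide(standardizeImage(i)))
  list(X = t(vapply(imgs, encodeImage, integer(37400L))),
       table = coh$table, images = imgs)
}

# a tight custom population for planted-structure tests
plantedPopulation <- function(name, ap, ml, axAP, axML,
                              source = "revision") {
  populationSpec(
    name = name, source = source,
    medial = list(centerAP = c(ap, 0.4), centerML = c(ml, 0.4),
                  semiAxisAP = c(axAP, 0.2), semiAxisML = c(axML, 0.2),
                  rotation = c(0, 2), squareness = c(2, 0.05),
                  boundaryRoughness = c(0.05, 0.01)),
    lateral = list(centerAP = c(ap, 0.4), centerML = c(-ml, 0.4),
                   semiAxisAP = c(axAP, 0.2), semiAxisML = c(axML, 0.2),
                   rotation = c(0, 2), squareness = c(2, 0.05),
                   boundaryRoughness = c(0.05, 0.01)),
    sideProbLeft = 0, timeInHost = c(50, 20, 1, 120))
}

# three well-separated planted populations (posterior-small, central-large,
# anterior-compact), 15 components each
plantedCohortSpec <- function(masterSeed = 3L) {
  cohortSpec(list(
    list(pop = plantedPopulation("post-small", -14, 4, 5, 4), n = 15),
    list(pop = plantedPopulation("central-large", 2, -3, 14, 11), n = 15),
    list(pop = plantedPopulation("ant-compact", 14, 3, 7, 6), n = 15)),
    masterSeed = masterSeed)
}

# population with near-certain medial dominance: every draw carries the
# asymmetry signal the mirror-distance side rule relies on
unambiguousPopulation <- function() {
  populationSpec(
    name = "unambiguous", source = "postmortem",
    medial = list(centerAP = c(0, 2), centerML = c(4, 1),
                  semiAxisAP = c(12, 1), semiAxisML = c(9.5, 0.8),
                  rotation = c(0, 5), squareness = c(2, 0.2),
                  boundaryRoughness = c(0.1, 0.03)),
    lateral = list(centerAP = c(0, 2), centerML = c(-2, 1),
                   semiAxisAP = c(8, 0.8), semiAxisML = c(6.5, 0.7),
                   rotation = c(0, 5), squareness = c(2, 0.2),
                   boundaryRoughness = c(0.1, 0.03)),
    sideProbLeft = 0.5, timeInHost = c(60, 20, 10, 120))
}

# solid rectangle fixture: 50 x 100 px worn block centered in the medial
# half of a 300 x 600 canvas at 0.1 mm/px
rectangleImage <- function() {
  px <- matrix(1L, 300, 600)
  px[126:175, 401:500] <- 0L
  WearScarImage(px, mmPerPxML = 0.1, mmPerPxAP = 0.1, side = "right")
}

# rasterized disk of the given pixel radius, centered in the medial half
diskImage <- function(radius) {
  n <- 2L * radius + 21L
  px <- matrix(1L, n, 2L * n)
  rc <- (n + 1) / 2
  cc <- n + rc
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq((n + 1L), 2L * n), n, n, byrow = TRUE)
  inside <- (rows - rc)^2 + (cols - cc)^2 <= radius^2
  sub <- px[, (n + 1L):(2L * n)]
  sub[inside] <- 0L
  px[, (n + 1L):(2L * n)] <- sub
  WearScarImage(px, mmPerPxML = 1, mmPerPxAP = 1, side = "right")
}

# hand-made model with explicit codebook
modelWithCodebook <- function(rows, cols, codebook, trained = TRUE) {
  m <- sofmInit(rows, cols, dim = ncol(codebook), mode = "uniform_random",
                seed = 1L)
  m@codebook <- codebook
  m@trained <- trained
  m
}

# study-design fixture with deliberately distinct populations: a posterior
# training population, a larger revision-like population, and the tight
# anterior simulator preset; used for held-out assignment recovery
distinctStudyPopulation <- function(name, source, ap, ml, axAP, axML,
                                    cSd, aSd) {
  populationSpec(
    name = name, source = source,
    medial = list(centerAP = c(ap, cSd), centerML = c(ml + 2, cSd),
                  semiAxisAP = c(axAP, aSd), semiAxisML = c(axML, aSd),
                  rotation = c(0, 8), squareness = c(2, 0.3),
                  boundaryRoughness = c(0.12, 0.04)),
    lateral = list(centerAP = c(ap, cSd), centerML = c(ml - 2, cSd),
                   semiAxisAP = c(axAP * 0.85, aSd),
                   semiAxisML = c(axML * 0.85, aSd),
                   rotation = c(0, 8), squareness = c(2, 0.3),
                   boundaryRoughness = c(0.12, 0.04)),
    sideProbLeft = 0, timeInHost = c(60, 25, 10, 140))
}

distinctStudyCohortSpec <- function(masterSeed = 11L) {
  cohortSpec(list(
    list(pop = distinctStudyPopulation("postmortem-like", "postmortem",
                                       -5, 1, 11, 9, 2.5, 1.8), n = 21),
    list(pop = distinctStudyPopulation("revision-like", "revision",
                                       -3, 1, 14, 11, 3.5, 2.5), n = 20),
    list(pop = presetPopulation("simulator"), n = 6)),
    masterSeed = masterSeed)
}
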