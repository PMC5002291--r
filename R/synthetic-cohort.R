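#' Canvas specification for synthetic wear-scar images
#'
#' Defines the pixel grid and calibration on which scar masks are rendered.
#' The default 170 x 220 px canvas at 0.35 mm/px spans about 60 x 77 mm,
#' a plausible tibial-insert envelope; calibration is configurable because
#' the physical dimensions of any particular insert design vary.
#'
#' @param rows,cols canvas dimensions in pixels (rows = AP, cols = ML).
#' @param mmPerPxML,mmPerPxAP calibration in mm per pixel.
#' @return a \code{canvasSpec} list.
#' @export
canvasSpec <- function(rows = 170L, cols = 220L,
                       mmPerPxML = 0.35, mmPerPxAP = 0.35) {
  stopifnot(rows >= 2, cols >= 2, mmPerPxML > 0, mmPerPxAP > 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 mmPerPxML = mmPerPxML, mmPerPxAP = mmPerPxAP),
            class = "canvasSpec")
}

#' Shape parameters of one synthetic scar blob
#'
#' A wear scar is modelled as a rotated superellipse with an optional
#' low-order radial perturbation of its boundary. Offsets are in mm from
#' the compartment centre, anterior positive for AP and positive toward the
#' medial (right) canvas edge for ML.
#'
#' @param centerAP,centerML centre offsets in mm.
#' @param semiAxisAP,semiAxisML semi-axes in mm (> 0).
#' @param rotation in-plane rotation in degrees.
#' @param squareness superellipse exponent, >= 1 (2 = ellipse, large values
#'   approach a rounded rectangle).
#' @param boundaryRoughness amplitude of the radial boundary perturbation,
#'   in \code{[0, 0.5)}; 0 renders an exact superellipse.
#' @return a \code{scarShapeParams} list.
#' @export
scarShapeParams <- function(centerAP = 0, centerML = 0,
                            semiAxisAP = 10, semiAxisML = 8,
                            rotation = 0, squareness = 2,
                            boundaryRoughness = 0) {
  if (!is.numeric(semiAxisAP) || semiAxisAP <= 0)
    stop("semiAxisAP must be > 0")
  if (!is.numeric(semiAxisML) || semiAxisML <= 0)
    stop("semiAxisML must be > 0")
  if (squareness < 1) stop("squareness must be >= 1")
  if (boundaryRoughness < 0 || boundaryRoughness >= 0.5)
    stop("boundaryRoughness must lie in [0, 0.5)")
  structure(list(centerAP = centerAP, centerML = centerML,
                 semiAxisAP = semiAxisAP, semiAxisML = semiAxisML,
                 rotation = rotation, squareness = squareness,
                 boundaryRoughness = boundaryRoughness),
            class = "scarShapeParams")
}

# Analytic area of a superellipse |x/a|^n + |y/b|^n <= 1.
superellipseArea <- function(a, b, n) {
  4 * a * b * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}

.compartmentCols <- function(canvas, compartment) {
  half <- canvas$cols %/% 2L
  if (compartment == "lateral") c(1L, half) else c(half + 1L, canvas$cols)
}

#' Render one scar blob onto a canvas
#'
#' Rasterizes a (possibly boundary-perturbed) superellipse into the chosen
#' compartment of a blank canvas. Worn pixels are 0, unworn pixels 1.
#' Rendering is deterministic for a fixed seed: the seed drives only the
#' random Fourier coefficients of the boundary perturbation.
#'
#' @param params a [scarShapeParams()] object.
#' @param compartment \code{"medial"} or \code{"lateral"}; on a right-side
#'   canvas the medial compartment is the right half.
#' @param canvas a [canvasSpec()].
#' @param seed integer seed for the boundary perturbation.
#' @return binary integer matrix of canvas dimensions.
#' @examples
#' m <- makeScarMask(scarShapeParams(semiAxisAP = 5, semiAxisML = 10),
#'                   "medial", canvasSpec(), seed = 1)
#' sum(m == 0)  # worn pixel count ~ pi*a*b / pixel area
#' @export
makeScarMask <- function(params, compartment = c("medial", "lateral"),
                         canvas = canvasSpec(), seed = 1L) {
  stopifnot(inherits(params, "scarShapeParams"), inherits(canvas, "canvasSpec"))
  compartment <- match.arg(compartment)
  cc <- .compartmentCols(canvas, compartment)
  # compartment frame, mm
  halfML <- (cc[2L] - cc[1L] + 1L) * canvas$mmPerPxML / 2
  halfAP <- canvas$rows * canvas$mmPerPxAP / 2
  grow <- 1 + params$boundaryRoughness
  extML <- max(params$semiAxisML, params$semiAxisAP) * grow
  extAP <- extML  # rotation can swap axes; use the bounding circle
  if (extML > halfML)
    stop(sprintf("scar too large for compartment: semiAxis%s = %.2f mm exceeds the %.2f mm half-width",
                 if (params$semiAxisML >= params$semiAxisAP) "ML" else "AP",
                 max(params$semiAxisML, params$semiAxisAP), halfML))
  if (abs(params$centerML) + extML > halfML)
    stop(sprintf("scar extends beyond compartment bounds: centerML = %.2f mm", params$centerML))
  if (abs(params$centerAP) + extAP > halfAP)
    stop(sprintf("scar extends beyond compartment bounds: centerAP = %.2f mm", params$centerAP))

  colc <- (cc[1L] + cc[2L]) / 2
  rowc <- (1 + canvas$rows) / 2
  c0 <- colc + params$centerML / canvas$mmPerPxML
  r0 <- rowc - params$centerAP / canvas$mmPerPxAP

  # boundary perturbation rho(theta), |rho| <= boundaryRoughness
  rough <- params$boundaryRoughness
  if (rough > 0) {
    coef <- withSeed(seed, stats::rnorm(8L))
    thGrid <- seq(0, 2 * pi, length.out = 721L)
    basis <- function(th) {
      out <- 0
      for (k in 2:5)
        out <- out + coef[2L * (k - 2L) + 1L] * cos(k * th) +
                     coef[2L * (k - 2L) + 2L] * sin(k * th)
      out
    }
    m0 <- max(abs(basis(thGrid)))
    rho <- function(th) if (m0 > 0) rough * basis(th) / m0 else 0 * th
  } else {
    rho <- function(th) 0 * th
  }

  rows <- seq_len(canvas$rows)
  cols <- seq_len(canvas$cols)
  dx <- outer(rep(1, canvas$rows), (cols - c0) * canvas$mmPerPxML)
  dy <- outer((r0 - rows) * canvas$mmPerPxAP, rep(1, canvas$cols))
  phi <- params$rotation * pi / 180
  xr <- dx * cos(phi) + dy * sin(phi)
  yr <- -dx * sin(phi) + dy * cos(phi)
  n <- params$squareness
  m <- (abs(xr / params$semiAxisML)^n + abs(yr / params$semiAxisAP)^n)^(1 / n)
  inside <- m <= 1 + rho(atan2(yr, xr))
  mask <- matrix(1L, canvas$rows, canvas$cols)
  mask[inside] <- 0L
  mask
}

.popFields <- c("centerAP", "centerML", "semiAxisAP", "semiAxisML",
                "rotation", "squareness", "boundaryRoughness")

#' Population specification for synthetic cohorts
#'
#' Describes the distribution of scar geometry and covariates within one
#' component population. Each entry of \code{medial}/\code{lateral} is a
#' \code{c(mean, sd)} pair for the matching [scarShapeParams()] field.
#'
#' @param name population label.
#' @param source source label attached to generated components
#'   (\code{"postmortem"}, \code{"revision"} or \code{"simulator"}).
#' @param medial,lateral named lists of \code{c(mean, sd)} pairs over the
#'   fields \code{centerAP, centerML, semiAxisAP, semiAxisML, rotation,
#'   squareness, boundaryRoughness}.
#' @param sideProbLeft probability that a drawn component is a left-side
#'   insert (rendered as the mirror image).
#' @param timeInHost \code{c(mean, sd, min, max)} for months in host
#'   (normal, truncated to \code{[min, max]}).
#' @param ageAtSurgery \code{c(mean, sd)} for age at surgery in years, or
#'   \code{NULL} for missing.
#' @param covariateModel optional linear link from time in host to total
#'   scar area: \code{list(intercept, slope, noiseSD)} in mm^2 (and mm^2
#'   per month). When set, the drawn shape is rescaled so its analytic
#'   area follows the line plus noise.
#' @return a \code{populationSpec} list.
#' @seealso [presetPopulation()] for ready-made populations.
#' @export
populationSpec <- function(name, source, medial, lateral,
                           sideProbLeft = 0.5,
                           timeInHost = c(60, 30, 1, 144),
                           ageAtSurgery = c(70, 8),
                           covariateModel = NULL) {
  stopifnot(source %in% .SOURCES,
            all(.popFields %in% names(medial)),
            all(.popFields %in% names(lateral)),
            sideProbLeft >= 0, sideProbLeft <= 1)
  for (side in list(medial, lateral))
    for (f in .popFields)
      if (length(side[[f]]) != 2L || side[[f]][2L] < 0)
        stop(sprintf("field '%s' must be c(mean, sd) with sd >= 0", f))
  if (!is.null(covariateModel))
    stopifnot(all(c("intercept", "slope", "noiseSD") %in% names(covariateModel)),
              covariateModel$noiseSD >= 0)
  structure(list(name = name, source = source, medial = medial,
                 lateral = lateral, sideProbLeft = sideProbLeft,
                 timeInHost = timeInHost, ageAtSurgery = ageAtSurgery,
                 covariateModel = covariateModel),
            class = "populationSpec")
}

#' Ready-made synthetic populations
#'
#' Three presets emulate the structure of a retrieval study cohort:
#' \describe{
#'   \item{postmortem}{well-functioning components with centrally located,
#'     moderately variable scars; the medial scar is slightly larger than
#'     the lateral one (the medial compartment bears more load). Time in
#'     host ~ N(79, 30) truncated to 19-144 months.}
#'   \item{revision}{failed components with larger and more variable scars
#'     and shorter times in host (mean 26, range 1-108 months).}
#'   \item{simulator}{machine-tested components: scars are more anteriorly
#'     located (mean AP offset +6 mm) and far more reproducible — every
#'     spread is at most a quarter of the postmortem value — with medial
#'     and lateral compartments nearly symmetrical. Time in host is the
#'     walking-equivalent of a five-million-cycle test (60 months).}
#' }
#'
#' @param name one of \code{"postmortem"}, \code{"revision"},
#'   \code{"simulator"}.
#' @return a [populationSpec()].
#' @export
presetPopulation <- function(name = c("postmortem", "revision", "simulator")) {
  name <- match.arg(name)
  switch(name,
    postmortem = populationSpec(
      name = "postmortem-like", source = "postmortem",
      medial = list(centerAP = c(0, 4), centerML = c(4, 2),
                    semiAxisAP = c(12, 2.2), semiAxisML = c(9.5, 1.8),
                    rotation = c(0, 10), squareness = c(2, 0.4),
                    boundaryRoughness = c(0.15, 0.05)),
      lateral = list(centerAP = c(0, 4), centerML = c(-2, 2),
                     semiAxisAP = c(8.5, 1.8), semiAxisML = c(7, 1.5),
                     rotation = c(0, 10), squareness = c(2, 0.4),
                     boundaryRoughness = c(0.15, 0.05)),
      sideProbLeft = 0.5,
      timeInHost = c(79, 30, 19, 144),
      ageAtSurgery = c(70, 8)),
    revision = populationSpec(
      name = "revision-like", source = "revision",
      medial = list(centerAP = c(-2, 6), centerML = c(4.5, 2.5),
                    semiAxisAP = c(13, 3), semiAxisML = c(10.5, 2.5),
                    rotation = c(0, 15), squareness = c(2, 0.5),
                    boundaryRoughness = c(0.2, 0.08)),
      lateral = list(centerAP = c(-2, 6), centerML = c(-2.5, 2.5),
                     semiAxisAP = c(9, 2.5), semiAxisML = c(7.5, 2),
                     rotation = c(0, 15), squareness = c(2, 0.5),
                     boundaryRoughness = c(0.2, 0.08)),
      sideProbLeft = 0.5,
      timeInHost = c(26, 25, 1, 108),
      ageAtSurgery = c(68, 9)),
    simulator = populationSpec(
      name = "simulator-like", source = "simulator",
      medial = list(centerAP = c(6, 1), centerML = c(0, 0.5),
                    semiAxisAP = c(9, 0.45), semiAxisML = c(8, 0.35),
                    rotation = c(0, 2.5), squareness = c(2, 0.1),
                    boundaryRoughness = c(0.05, 0.0125)),
      lateral = list(centerAP = c(6, 1), centerML = c(0, 0.5),
                     semiAxisAP = c(9, 0.45), semiAxisML = c(8, 0.35),
                     rotation = c(0, 2.5), squareness = c(2, 0.1),
                     boundaryRoughness = c(0.05, 0.0125)),
      sideProbLeft = 1,  # machine-tested inserts are all left-side fixtures
      timeInHost = c(cyclesToMonths(5), 0, cyclesToMonths(5), cyclesToMonths(5)),
      ageAtSurgery = NULL)
  )
}

#' Cohort specification
#'
#' @param populations list of \code{list(pop = populationSpec, n = count)}
#'   entries; counts must be >= 1.
#' @param canvas a [canvasSpec()].
#' @param masterSeed integer; all per-component randomness is derived
#'   deterministically from this seed.
#' @return a \code{cohortSpec} list.
#' @export
cohortSpec <- function(populations, canvas = canvasSpec(), masterSeed = 1L) {
  if (length(populations) == 0L) stop("cohort spec contains no populations")
  for (p in populations)
    stopifnot(inherits(p$pop, "populationSpec"), p$n >= 1)
  structure(list(populations = populations, canvas = canvas,
                 masterSeed = as.integer(masterSeed)),
            class = "cohortSpec")
}

# Draw one value from N(mean, sd), clamped to [lo, hi].
.drawClamped <- function(ms, lo, hi) {
  min(max(stats::rnorm(1L, ms[1L], ms[2L]), lo), hi)
}

# Draw scar shape parameters for one compartment, clamped so the rendered
# shape always fits the compartment (random cohorts must never abort).
.drawShape <- function(dist, canvas, compartment) {
  cc <- .compartmentCols(canvas, compartment)
  halfML <- (cc[2L] - cc[1L] + 1L) * canvas$mmPerPxML / 2
  halfAP <- canvas$rows * canvas$mmPerPxAP / 2
  rough <- .drawClamped(dist$boundaryRoughness, 0, 0.45)
  grow <- 1 + rough
  maxAxis <- 0.92 * halfML / grow
  aAP <- .drawClamped(dist$semiAxisAP, 1.5, maxAxis)
  aML <- .drawClamped(dist$semiAxisML, 1.5, maxAxis)
  ext <- max(aAP, aML) * grow
  cML <- .drawClamped(dist$centerML, -(halfML - ext - 0.2), halfML - ext - 0.2)
  cAP <- .drawClamped(dist$centerAP, -(halfAP - ext - 0.2), halfAP - ext - 0.2)
  rot <- stats::rnorm(1L, dist$rotation[1L], dist$rotation[2L])
  sq <- .drawClamped(dist$squareness, 1, 8)
  list(params = scarShapeParams(centerAP = cAP, centerML = cML,
                                semiAxisAP = aAP, semiAxisML = aML,
                                rotation = rot, squareness = sq,
                                boundaryRoughness = rough),
       maxAxis = maxAxis)
}

#' Sample one synthetic component
#'
#' Draws scar shapes for both compartments, covariates and an implantation
#' side from a [populationSpec()], renders the image (left-side components
#' are rendered as the mirror image) and returns the image together with
#' its metadata record. Deterministic for a fixed seed.
#'
#' @param pop a [populationSpec()].
#' @param canvas a [canvasSpec()].
#' @param seed integer seed.
#' @param componentId label for the generated component.
#' @return \code{list(image = WearScarImage, record = data.frame)}; the
#'   record carries the source, population, side, covariates and (when a
#'   covariate model is active) the analytic target area in mm^2.
#' @export
sampleComponent <- function(pop, canvas = canvasSpec(), seed = 1L,
                            componentId = "C-1") {
  stopifnot(inherits(pop, "populationSpec"))
  drawn <- withSeed(seed, {
    med <- .drawShape(pop$medial, canvas, "medial")
    lat <- .drawShape(pop$lateral, canvas, "lateral")
    isLeft <- stats::runif(1L) < pop$sideProbLeft
    tih <- .drawClamped(pop$timeInHost, pop$timeInHost[3L], pop$timeInHost[4L])
    age <- if (is.null(pop$ageAtSurgery)) NA_real_
           else stats::rnorm(1L, pop$ageAtSurgery[1L], pop$ageAtSurgery[2L])
    areaNoise <- if (!is.null(pop$covariateModel))
      stats::rnorm(1L, 0, pop$covariateModel$noiseSD) else 0
    list(med = med, lat = lat, isLeft = isLeft, tih = tih, age = age,
         areaNoise = areaNoise)
  })
  med <- drawn$med$params
  lat <- drawn$lat$params
  areaTarget <- NA_real_
  if (!is.null(pop$covariateModel)) {
    cm <- pop$covariateModel
    areaTarget <- cm$intercept + cm$slope * drawn$tih + drawn$areaNoise
    a0 <- superellipseArea(med$semiAxisML, med$semiAxisAP, med$squareness) +
          superellipseArea(lat$semiAxisML, lat$semiAxisAP, lat$squareness)
    if (areaTarget <= 0)
      stop("covariate model produced a non-positive target area")
    sc <- sqrt(areaTarget / a0)
    scaleAxes <- function(p, cap, compartment) {
      p$semiAxisAP <- min(p$semiAxisAP * sc, cap)
      p$semiAxisML <- min(p$semiAxisML * sc, cap)
      # rescaling can push center + extent past the compartment edge
      cc <- .compartmentCols(canvas, compartment)
      halfML <- (cc[2L] - cc[1L] + 1L) * canvas$mmPerPxML / 2
      halfAP <- canvas$rows * canvas$mmPerPxAP / 2
      ext <- max(p$semiAxisAP, p$semiAxisML) * (1 + p$boundaryRoughness)
      p$centerML <- min(max(p$centerML, -(halfML - ext - 0.2)), halfML - ext - 0.2)
      p$centerAP <- min(max(p$centerAP, -(halfAP - ext - 0.2)), halfAP - ext - 0.2)
      p
    }
    med <- scaleAxes(med, drawn$med$maxAxis, "medial")
    lat <- scaleAxes(lat, drawn$lat$maxAxis, "lateral")
  }
  sub <- deriveSeeds(seed, 2L)
  mm <- makeScarMask(med, "medial", canvas, seed = sub[1L])
  ml <- makeScarMask(lat, "lateral", canvas, seed = sub[2L])
  px <- pmin(mm, ml)
  storage.mode(px) <- "integer"
  sideLab <- if (drawn$isLeft) "left" else "right"
  if (drawn$isLeft) px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
  img <- WearScarImage(px, mmPerPxML = canvas$mmPerPxML,
                       mmPerPxAP = canvas$mmPerPxAP, side = sideLab,
                       source = pop$source, componentId = componentId,
                       timeInHost = drawn$tih, ageAtSurgery = drawn$age)
  rec <- data.frame(component_id = componentId, source = pop$source,
                    population = pop$name, side = sideLab,
                    time_in_host = drawn$tih, age_at_surgery = drawn$age,
                    area_target_mm2 = areaTarget, seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  list(image = img, record = rec)
}

#' Sample a full synthetic cohort
#'
#' Generates every component of a [cohortSpec()]; per-component seeds are
#' derived deterministically from the master seed, so an identical spec
#' yields a byte-identical cohort.
#'
#' @param spec a [cohortSpec()].
#' @return \code{list(images = list of WearScarImage, table = data.frame)};
#'   the table has one row per component (columns \code{component_id,
#'   source, population, side, time_in_host, age_at_surgery,
#'   area_target_mm2, seed}).
#' @examples
#' spec <- cohortSpec(list(list(pop = presetPopulation("simulator"), n = 2)),
#'                    masterSeed = 7)
#' coh <- sampleCohort(spec)
#' coh$table$source
#' @export
sampleCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  total <- sum(vapply(spec$populations, function(p) p$n, numeric(1L)))
  seeds <- deriveSeeds(spec$masterSeed, total)
  images <- vector("list", total)
  records <- vector("list", total)
  i <- 0L
  for (p in spec$populations) {
    prefix <- toupper(substr(p$pop$source, 1L, 2L))
    for (j in seq_len(p$n)) {
      i <- i + 1L
      id <- sprintf("%s-%03d", prefix, j)
      res <- sampleComponent(p$pop, spec$canvas, seed = seeds[i],
                             componentId = id)
      images[[i]] <- res$image
      records[[i]] <- res$record
    }
  }
  list(images = images, table = do.call(rbind, records))
}

#' Write a cohort table to CSV
#'
#' @param table cohort metadata table as returned by [sampleCohort()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeCohortTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort specification from a YAML or JSON config file
#'
#' The file holds \code{masterSeed}, an optional \code{canvas} block
#' (\code{rows, cols, mmPerPxML, mmPerPxAP}) and a \code{populations} list
#' whose entries carry \code{preset} (one of the [presetPopulation()]
#' names) and \code{n}.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a [cohortSpec()].
#' @export
readCohortSpec <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = FALSE)
  canvas <- if (is.null(cfg$canvas)) canvasSpec() else
    do.call(canvasSpec, cfg$canvas)
  pops <- lapply(cfg$populations, function(p)
    list(pop = presetPopulation(p$preset), n = p$n))
  cohortSpec(pops, canvas = canvas,
             masterSeed = if (is.null(cfg$masterSeed)) 1L else cfg$masterSeed)
}
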