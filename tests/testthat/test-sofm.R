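test_that("initialization is deterministic and honors its mode", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  m1 <- sofmInit(3, 2, data = X, mode = "sample", seed = 7)
  m2 <- sofmInit(3, 2, data = X, mode = "sample", seed = 7)
  expect_identical(codebook(m1), codebook(m2))
  expect_false(isTrained(m1))
  # one-vector dataset: every neuron equals that vector
  one <- matrix(c(1, 2, 3), 1, 3)
  m3 <- sofmInit(2, 2, data = one, mode = "sample", seed = 1)
  expect_true(all(apply(codebook(m3), 1L, identical, c(1, 2, 3))))
  # a 12 x 10 lattice carries 120 codebook vectors
  m4 <- sofmInit(12, 10, dim = 5, mode = "uniform_random", seed = 1)
  expect_equal(nrow(codebook(m4)), 120L)
  expect_equal(unname(gridSize(m4)), c(12L, 10L))
  expect_error(sofmInit(3, 2, data = X, dim = 7, mode = "sample", seed = 1),
               "does not match")
  expect_error(sofmInit(0, 2, dim = 3), ">= 1")
})

test_that("best-matching unit minimizes distance with row-major tie-breaks", {
  m <- modelWithCodebook(2, 1, matrix(c(0, 10), 2, 1))
  expect_equal(findBMU(m, 4), 1L)    # |4-0| < |4-10|
  expect_equal(findBMU(m, 9), 2L)
  expect_equal(findBMU(m, 5), 1L)    # exact tie -> lowest index
  # x equal to one codebook vector finds that neuron
  set.seed(5)
  W <- matrix(rnorm(12), 6, 2)
  m2 <- modelWithCodebook(2, 3, W)
  expect_equal(findBMU(m2, W[4L, ]), 4L)
  # identical codebooks all tie to neuron 1
  m3 <- modelWithCodebook(2, 2, matrix(1, 4, 3))
  expect_equal(findBMU(m3, c(9, 9, 9)), 1L)
  expect_error(findBMU(m2, c(1, 2, 3)), "dimension")
})

test_that("neighborhood kernels take their closed-form values", {
  m <- sofmInit(1, 5, dim = 1, mode = "uniform_random", seed = 1)
  r <- 2
  h <- neighborhoodWeights(m, bmu = 1L, radius = r)
  expect_equal(h[1L], 1.0)                      # d = 0
  expect_equal(h[3L], exp(-0.5))                # d = radius
  expect_equal(h[2L], exp(-1 / (2 * r^2)))
  expect_true(all(diff(h) <= 0))                # monotone in distance
  hb <- neighborhoodWeights(m, bmu = 1L, radius = 2, kernel = "bubble")
  expect_equal(hb, c(1, 1, 1, 0, 0))            # d > radius -> 0
  expect_error(neighborhoodWeights(m, 1L, radius = 0), "> 0")
})

test_that("one batch epoch equals the brute-force weighted-mean oracle", {
  set.seed(3)
  shapes <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(1, 5), c(5, 1))
  for (sh in shapes) for (n in c(1L, 4L, 10L)) {
    d <- 3L
    X <- matrix(rnorm(n * d), n, d)
    r <- runif(1, 0.5, 3)
    m <- sofmInit(sh[1L], sh[2L], data = X, mode = "sample", seed = n)
    mt <- sofmTrain(m, X, radii = r, mode = "batch")
    # oracle: explicit weighted means over hand-computed grid kernels
    W <- codebook(m)
    nm <- sh[1L] * sh[2L]
    g <- cbind(rep(seq_len(sh[1L]), each = sh[2L]),
               rep(seq_len(sh[2L]), times = sh[1L]))
    bmu <- apply(X, 1L, function(x) which.min(colSums((t(W) - x)^2)))
    Wo <- W
    for (j in seq_len(nm)) {
      h <- vapply(bmu, function(b)
        exp(-sum((g[j, ] - g[b, ])^2) / (2 * r^2)), numeric(1L))
      if (sum(h) > 0) Wo[j, ] <- colSums(h * X) / sum(h)
    }
    expect_equal(codebook(mt), Wo, tolerance = 1e-12)
  }
})

test_that("training converges to known fixed points", {
  # single data vector: every neuron collapses onto it
  x <- matrix(c(2, -1, 3), 1, 3)
  m <- sofmInit(3, 3, data = x, mode = "sample", seed = 1)
  mt <- sofmTrain(m, x, radii = radiusSchedule(3, 1, 5))
  expect_true(all(abs(sweep(codebook(mt), 2L, as.numeric(x))) < 1e-9))
  # 2 x 1 map on bimodal 1-D data: codebook reaches the k-means solution
  X <- matrix(c(0, 0, 0, 10, 10, 10), 6, 1)
  m2 <- modelWithCodebook(2, 1, matrix(c(1, 9), 2, 1), trained = FALSE)
  mt2 <- sofmTrain(m2, X, radii = c(2, 1, 0.5, 0.2, 0.05, 0.01))
  expect_equal(sort(as.numeric(codebook(mt2))), c(0, 10), tolerance = 1e-6)
  expect_true(isTrained(mt2))
  expect_length(trainingLog(mt2), 6L)
  expect_error(sofmTrain(m2, X[0, , drop = FALSE], radii = 1), "empty")
})

test_that("sequential mode trains with a seeded random order", {
  set.seed(8)
  X <- matrix(rnorm(30), 15, 2)
  m <- sofmInit(2, 2, data = X, mode = "sample", seed = 2)
  a <- sofmTrain(m, X, radii = radiusSchedule(2, 1, 4), mode = "sequential",
                 seed = 5)
  b <- sofmTrain(m, X, radii = radiusSchedule(2, 1, 4), mode = "sequential",
                 seed = 5)
  expect_identical(codebook(a), codebook(b))
  c_ <- sofmTrain(m, X, radii = radiusSchedule(2, 1, 4),
                  mode = "sequential", seed = 6)
  expect_false(identical(codebook(a), codebook(c_)))
  expect_error(sofmTrain(m, X, radii = radiusSchedule(2, 1, 4),
                         mode = "sequential",
                         lrSchedule = c(0.5, 0.1)), "match")
})

test_that("quantization error matches hand computations", {
  m <- modelWithCodebook(1, 1, matrix(1, 1, 1))
  expect_equal(quantizationError(m, matrix(c(0, 2), 2, 1)), 1.0)
  # samples sitting on codebook vectors give zero error
  set.seed(4)
  W <- matrix(rnorm(8), 4, 2)
  m2 <- modelWithCodebook(2, 2, W)
  expect_equal(quantizationError(m2, W), 0)
  # duplicating a sample leaves its per-sample contribution unchanged
  X <- matrix(c(0, 3), 2, 1)
  m3 <- modelWithCodebook(1, 1, matrix(1, 1, 1))
  expect_equal(quantizationError(m3, X), mean(c(1, 2)))
  expect_equal(quantizationError(m3, X[c(1, 1, 2, 2), , drop = FALSE]),
               mean(c(1, 1, 2, 2)))
  expect_error(quantizationError(m3, X[0, , drop = FALSE]), "empty")
})

test_that("schedules enforce their invariants", {
  expect_equal(radiusSchedule(4, 1, 4), c(4, 3, 2, 1))
  expect_error(radiusSchedule(1, 4, 3), "initial >= final")
  expect_error(radiusSchedule(4, 0, 3), "initial >= final")
  expect_error(learningRateSchedule(1.5, 0.1, 3), "\\(0, 1\\]")
  expect_equal(length(twoPhaseSchedule(4, 1, 10, 40)), 50L)
  expect_equal(twoPhaseSchedule(4, 1, 2, 3), c(4, 1, 1, 1, 1))
})

test_that("training lowers quantization error relative to initialization", {
  # over >= 10 seeds on small synthetic cohorts; batch SOM is not strictly
  # monotone, so allow one violation
  coh <- encodedCohort(cohortSpec(list(
    list(pop = presetPopulation("postmortem"), n = 12)), masterSeed = 6))
  drops <- vapply(1:10, function(s) {
    m <- sofmInit(4, 4, data = coh$X, mode = "uniform_random", seed = s)
    q0 <- quantizationError(m, coh$X)
    mt <- sofmTrain(m, coh$X, radii = radiusSchedule(3, 1, 8), seed = s)
    quantizationError(mt, coh$X) <= q0
  }, logical(1L))
  expect_gte(sum(drops), 9L)
})

test_that("the trained lattice preserves ring topology", {
  set.seed(10)
  th <- runif(200, 0, 2 * pi)
  X <- cbind(cos(th), sin(th)) + matrix(rnorm(400, sd = 0.05), 200, 2)
  m <- sofmInit(5, 5, data = X, mode = "sample", seed = 3)
  mt <- sofmTrain(m, X, radii = twoPhaseSchedule(3, 1, 10, 20), seed = 3)
  W <- codebook(mt)
  g <- cbind(rep(1:5, each = 5), rep(1:5, times = 5))
  dGrid <- as.matrix(stats::dist(g))
  dCode <- as.matrix(stats::dist(W))
  adj <- dGrid == 1
  far <- dGrid > 1
  expect_lt(mean(dCode[adj]), mean(dCode[far]))
})

test_that("models serialize to text and round-trip exactly", {
  set.seed(11)
  X <- matrix(rnorm(60), 20, 3)
  m <- sofmTrain(sofmInit(3, 2, data = X, mode = "sample", seed = 1), X,
                 radii = radiusSchedule(2, 1, 3))
  path <- tempfile(fileext = ".txt")
  writeSOFM(m, path)
  m2 <- readSOFM(path)
  expect_identical(codebook(m2), codebook(m))
  expect_identical(trainingLog(m2), trainingLog(m))
  expect_equal(unname(gridSize(m2)), unname(gridSize(m)))
  expect_true(isTrained(m2))
  suppressWarnings(expect_error(readSOFM(tempfile()), "cannot open"))
})
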