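test_that("u-matrix equals hand-computed neighbor means", {
  # constant codebook -> all zeros
  m <- modelWithCodebook(3, 3, matrix(2, 9, 4))
  expect_true(all(umValues(uMatrix(m)) == 0))
  # 3 x 1 map with 1-D weights (0, 0, 10) -> u = (0, 5, 10)
  m2 <- modelWithCodebook(3, 1, matrix(c(0, 0, 10), 3, 1))
  expect_equal(as.vector(umValues(uMatrix(m2))), c(0, 5, 10))
  # 2 x 2 corner case: each corner averages over exactly 2 neighbors
  W <- matrix(c(0, 1, 2, 3), 4, 1)  # row-major: (1,1)=0 (1,2)=1 (2,1)=2 (2,2)=3
  m3 <- modelWithCodebook(2, 2, W)
  expect_equal(umValues(uMatrix(m3)),
               matrix(c(1.5, 1.5, 1.5, 1.5), 2, 2))
  # invariance under global translation of the codebook
  set.seed(6)
  W4 <- matrix(rnorm(24), 12, 2)
  m4 <- modelWithCodebook(4, 3, W4)
  m5 <- modelWithCodebook(4, 3, W4 + 100)
  expect_equal(umValues(uMatrix(m4)), umValues(uMatrix(m5)))
  # untrained model warns but still computes
  m6 <- modelWithCodebook(2, 2, matrix(0, 4, 1), trained = FALSE)
  expect_warning(uMatrix(m6), "untrained")
})

test_that("threshold delineation labels valleys and leaves ridges", {
  # flat u-matrix at q = 1 -> one cluster covering the grid
  flat <- new("UMatrix", values = matrix(1, 4, 5))
  cm <- delineateClusters(flat, q = 1.0)
  expect_equal(nClusters(cm), 1L)
  expect_true(all(clusterLabels(cm) == 1L))
  # two low plateaus separated by a one-neuron-wide high ridge
  u <- matrix(1, 5, 5)
  u[, 3] <- 10
  cm2 <- delineateClusters(new("UMatrix", values = u), q = 0.5)
  expect_equal(nClusters(cm2), 2L)
  expect_true(all(clusterLabels(cm2)[, 3] == 0L))
  expect_true(all(clusterLabels(cm2)[, 1:2] == 1L))
  expect_true(all(clusterLabels(cm2)[, 4:5] == 2L))
  # shrinking q never merges clusters
  set.seed(12)
  uR <- matrix(runif(48), 6, 8)
  nAtQ <- vapply(c(1, 0.75, 0.5, 0.25, 0.1),
                 function(q) nClusters(delineateClusters(
                   new("UMatrix", values = uR), q = q)), integer(1L))
  expect_true(all(nAtQ >= nAtQ[1L]))
  expect_error(delineateClusters(flat, q = 0), "\\(0, 1\\]")
  expect_error(delineateClusters(flat, q = 1.2), "\\(0, 1\\]")
})

test_that("watershed delineation floods basins and respects the tolerance", {
  u <- matrix(1, 5, 5)
  u[, 3] <- 10
  cm <- delineateClusters(new("UMatrix", values = u), method = "watershed")
  expect_equal(nClusters(cm), 2L)
  expect_true(all(clusterLabels(cm)[, 3] == 0L))
  # a huge tolerance merges everything into one basin
  cmAll <- delineateClusters(new("UMatrix", values = u),
                             method = "watershed", tol = 100)
  expect_equal(nClusters(cmAll), 1L)
  # determinism
  set.seed(13)
  uR <- new("UMatrix", values = matrix(runif(60), 6, 10))
  a <- delineateClusters(uR, method = "watershed")
  b <- delineateClusters(uR, method = "watershed")
  expect_identical(clusterLabels(a), clusterLabels(b))
})

test_that("cluster ids are contiguous, connected and ordered by neuron index", {
  set.seed(14)
  u <- new("UMatrix", values = matrix(runif(120), 12, 10))
  for (meth in c("threshold", "watershed")) {
    cm <- delineateClusters(u, method = meth)
    lab <- clusterLabels(cm)
    ids <- sort(unique(lab[lab > 0L]))
    expect_identical(ids, seq_len(nClusters(cm)))
    # validity already enforces 4-connectivity; re-check explicitly
    for (id in ids)
      expect_true(scarSOM:::.isConnected4(lab == id))
    # id order follows each cluster's minimum row-major neuron index
    minIdx <- vapply(ids, function(id) min(which(t(lab) == id)), numeric(1L))
    expect_true(all(diff(minIdx) > 0))
  }
})

test_that("assignment returns the BMU's cluster with ridge fallback", {
  W <- matrix(c(0, 1, 2, 10, 11, 12), 6, 1)  # 3 x 2 lattice, row-major
  m <- modelWithCodebook(3, 2, W)
  lab <- matrix(c(1L, 1L, 0L, 0L, 2L, 2L), 3, 2, byrow = TRUE)
  cm <- new("ClusterMap", labels = lab, nClusters = 2L)
  # codebook vector inside cluster 1 maps there
  expect_equal(assignCluster(m, cm, 0), 1L)
  expect_equal(assignCluster(m, cm, 12), 2L)
  # BMU on the ridge row, equidistant to both clusters -> lower id
  expect_equal(assignCluster(m, cm, 2), 1L)
  # assigning the training set reproduces the BMU-implied partition
  X <- matrix(c(0.1, 0.9, 11.5), 3, 1)
  bmus <- findBMU(m, X)
  labVec <- as.vector(t(lab))
  direct <- labVec[bmus]
  assigned <- assignCluster(m, cm, X)
  expect_true(all(assigned[direct > 0] == direct[direct > 0]))
  expect_error(assignCluster(m, cm, c(1, 2)), "dimension")
})

test_that("composition tables count sources and retrieved fractions", {
  # 9 retrieved of 75 in one cluster -> fraction 0.12
  assignments <- c(rep(1L, 10), rep(2L, 71))
  sources <- c(rep("revision", 6), rep("postmortem", 3), "simulator",
               rep("revision", 48), rep("postmortem", 18),
               rep("simulator", 5))
  tab <- compositionTable(assignments, sources)
  expect_equal(tab$frac_retrieved[tab$cluster == 1L], 9 / 75)
  expect_equal(tab$total[tab$cluster == 1L], 10L)
  # column sums conserve the cohort
  expect_equal(sum(tab$total), length(sources))
  expect_equal(sum(tab$revision), sum(sources == "revision"))
  expect_equal(sum(tab$simulator), 6L)
  # only non-empty clusters appear
  expect_identical(tab$cluster, c(1L, 2L))
  expect_error(compositionTable(1L, "martian"), "unknown source")
})

test_that("planted populations are recovered as distinct clusters", {
  # three well-separated populations, clustered on a 7 x 7 map
  coh <- encodedCohort(plantedCohortSpec(masterSeed = 3L))
  truth <- coh$table$population
  for (s in 1:5) {
    m <- sofmTrain(sofmInit(7, 7, data = coh$X, mode = "sample", seed = s),
                   coh$X, radii = radiiShort(), seed = s)
    cm <- delineateClusters(uMatrix(m))
    expect_gte(nClusters(cm), 3L)
    a <- assignCluster(m, cm, coh$X)
    recovery <- vapply(split(a, truth),
                       function(g) max(table(g)) / length(g), numeric(1L))
    expect_true(all(recovery >= 0.9))
  }
})

test_that("u-matrix and cluster maps export to CSV and PNG", {
  set.seed(15)
  u <- new("UMatrix", values = matrix(runif(20), 4, 5))
  csv <- tempfile(fileext = ".csv")
  pngf <- tempfile(fileext = ".png")
  exportUMatrix(u, csvPath = csv, pngPath = pngf)
  back <- as.matrix(utils::read.csv(csv, header = FALSE))
  expect_equal(unname(back), umValues(u), tolerance = 1e-12)
  expect_true(file.size(pngf) > 0)
  cm <- delineateClusters(u)
  cmf <- tempfile(fileext = ".csv")
  exportClusterMap(cm, cmf)
  df <- utils::read.csv(cmf)
  expect_equal(nrow(df), 20L)
  expect_equal(df$cluster_id[1L], clusterLabels(cm)[1L, 1L])
})
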