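test_that("rectangle descriptors are exact analytic values", {
  d <- computeDescriptors(rectangleImage())
  expect_equal(d$med_area, 50)          # 100 x 50 px at 0.1 mm/px
  expect_equal(d$med_ml_stretch, 10)
  expect_equal(d$med_ap_stretch, 5)
  expect_equal(d$med_centroid_ml, 0)    # centered in its compartment
  expect_equal(d$med_centroid_ap, 0)
  expect_equal(d$med_aspect_ratio, 2)
  expect_equal(d$med_solidity, 1)
  # empty compartment flags instead of erroring
  expect_true(d$lat_empty)
  expect_equal(d$lat_area, 0)
  # second moments of a solid a x b rectangle: I = a^3 b / 12 about each
  # centroid axis (discrete sum converges to the integral)
  expect_equal(d$med_i_ap, 10^3 * 5 / 12, tolerance = 0.01)
  expect_equal(d$med_i_ml, 5^3 * 10 / 12, tolerance = 0.01)
})

test_that("disk shape factor approaches 1 with radius", {
  sf <- vapply(c(10, 25, 50), function(r)
    computeDescriptors(diskImage(r))$med_shape_factor, numeric(1L))
  expect_true(all(abs(sf - 1) < 0.05))
  # raster error shrinks (allow a small slack for quantization jitter)
  expect_true(all(diff(abs(sf - 1)) < 0.005))
  # the plain Freeman chain overestimates a smooth perimeter by ~5%,
  # deflating the shape factor by ~10%
  sfF <- computeDescriptors(diskImage(50), weights = "freeman")$med_shape_factor
  expect_lt(sfF, 0.95)
  expect_gt(sfF, 0.85)
})

test_that("area and perimeter are invariant under mirroring and rotation", {
  coh <- sampleCohort(cohortSpec(list(list(
    pop = presetPopulation("postmortem"), n = 2)), masterSeed = 14))
  for (img in coh$images) {
    img <- toRightSide(standardizeImage(img))
    d <- computeDescriptors(img)
    # mirroring swaps compartments, preserving size descriptors
    dm <- computeDescriptors(mirrorImage(img))
    expect_equal(dm$med_area + dm$lat_area, d$med_area + d$lat_area)
    expect_equal(dm$med_perimeter + dm$lat_perimeter,
                 d$med_perimeter + d$lat_perimeter)
    # 180-degree rotation preserves both, compartment-swapped
    rot <- WearScarImage(pixels(img)[nrow(pixels(img)):1,
                                     ncol(pixels(img)):1],
                         mmPerPxML = 0.35, mmPerPxAP = 0.35, side = "right")
    dr <- computeDescriptors(rot)
    expect_equal(dr$med_area, d$lat_area)
    expect_equal(dr$med_perimeter, d$lat_perimeter, tolerance = 1e-9)
  }
  # area is additive over disjoint blobs
  px <- matrix(1L, 100, 200)
  px[10:19, 110:119] <- 0L
  px[60:79, 150:169] <- 0L
  d2 <- computeDescriptors(WearScarImage(px, mmPerPxML = 1, mmPerPxAP = 1,
                                         side = "right"))
  expect_equal(d2$med_area, 100 + 400)
})

test_that("symmetry index is 1 for balanced scars and falls with imbalance", {
  px <- matrix(1L, 170, 220)
  px[80:100, 40:60] <- 0L    # lateral
  px[80:100, 160:180] <- 0L  # medial, same size and AP position
  d <- computeDescriptors(WearScarImage(px, side = "right"))
  expect_equal(d$symmetry_index, 1)
  px2 <- px
  px2[60:140, 150:195] <- 0L  # enlarge and shift medial scar
  d2 <- computeDescriptors(WearScarImage(px2, side = "right"))
  expect_lt(d2$symmetry_index, d$symmetry_index)
  # all-unworn image: undefined
  expect_true(is.na(computeDescriptors(
    WearScarImage(matrix(1L, 170, 220), side = "right"))$symmetry_index))
})

test_that("one-way ANOVA across clusters matches hand computation", {
  tab <- data.frame(y = c(1, 2, 3, 4, 5, 6), cluster = rep(1:2, each = 3))
  r <- anovaByCluster(tab, "y")
  expect_equal(r$F, 13.5)            # SSB 13.5, MSW 1
  # identical groups -> F = 0
  flat <- data.frame(y = rep(2, 6), cluster = rep(1:2, each = 3))
  expect_equal(anovaByCluster(flat, "y")$F, 0)
  # singleton clusters are excluded before fitting
  tab2 <- rbind(tab, data.frame(y = 100, cluster = 3))
  r2 <- anovaByCluster(tab2, "y")
  expect_equal(r2$nGroups, 2L)
  expect_equal(r2$F, 13.5)
  expect_error(anovaByCluster(data.frame(y = 1:3, cluster = c(1, 2, 3)),
                              "y"), "fewer than 2")
  # p is consistent with the F-distribution tail
  expect_equal(r$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
})

test_that("per-cluster regression applies the inclusion and flagging rules", {
  # exact line y = 2x: slope 2, R^2 = 1, flagged
  tab <- data.frame(cluster = 1, x = 1:6, y = 2 * (1:6))
  r <- suppressWarnings(covariateRegression(tab, "y", "x"))
  expect_equal(r$slope, 2)
  expect_equal(r$r2, 1)
  expect_true(r$flagged)
  # clusters with n = 3 are excluded ("more than three" rule)
  tab2 <- rbind(tab, data.frame(cluster = 2, x = 1:3, y = c(5, 1, 9)))
  r2 <- suppressWarnings(covariateRegression(tab2, "y", "x"))
  expect_identical(r2$cluster, 1)
  expect_equal(attr(r2, "skipped"), 2)
  # missing covariates count against inclusion
  tab3 <- data.frame(cluster = 1, x = c(1:3, NA, NA), y = rnorm(5))
  r3 <- covariateRegression(tab3, "y", "x")
  expect_equal(nrow(r3), 0L)
  # closed-form least squares on a hand-set 5-point cluster
  set.seed(20)
  x <- c(1, 3, 4, 7, 9); y <- c(2, 3, 7, 6, 11)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r4 <- covariateRegression(data.frame(cluster = 1, x = x, y = y), "y", "x")
  expect_equal(r4$slope, slope)
  expect_equal(r4$r2, stats::cor(x, y)^2)
})

test_that("flagging requires both significance and meaningful R^2", {
  # construct data straddling both thresholds
  set.seed(22)
  n <- 60
  x <- seq_len(n)
  # strong: significant and high R^2
  yStrong <- x + rnorm(n, sd = 3)
  rs <- covariateRegression(data.frame(cluster = 1, x = x, y = yStrong),
                            "y", "x")
  expect_true(rs$p < 0.05 && rs$r2 > 0.4 && rs$flagged)
  # significant but weak R^2 (large n, shallow trend): not flagged
  yWeak <- 0.35 * x + rnorm(n, sd = 10)
  rw <- covariateRegression(data.frame(cluster = 1, x = x, y = yWeak),
                            "y", "x")
  expect_true(rw$p < 0.05)
  expect_lt(rw$r2, 0.4)
  expect_false(rw$flagged)
  # tiny n with high R^2 but p > 0.05: not flagged
  rt <- covariateRegression(
    data.frame(cluster = 1, x = c(1, 2, 3, 4), y = c(1, 3, 2, 4)), "y", "x")
  expect_gt(rt$p, 0.05)
  expect_false(rt$flagged)
})

test_that("binomial enrichment equals exact tail summation", {
  expect_equal(binomialEnrichment(6, 0, 0.37), 1)
  expect_equal(binomialEnrichment(6, 6, 0.5), 0.5^6)
  expect_equal(binomialEnrichment(6, 5, 9 / 75), 1.3437e-4,
               tolerance = 1e-4)
  # direct pmf summation oracle
  pmf <- function(k, n, p) choose(n, k) * p^k * (1 - p)^(n - k)
  expect_equal(binomialEnrichment(6, 5, 9 / 75),
               pmf(5, 6, 9 / 75) + pmf(6, 6, 9 / 75), tolerance = 1e-12)
  # the whole pmf sums to one
  total <- sum(vapply(0:6, pmf, numeric(1L), n = 6, p = 0.3))
  expect_equal(total, 1, tolerance = 1e-12)
  expect_error(binomialEnrichment(6, 7, 0.5), "<=")
  expect_error(binomialEnrichment(6, 2, 1.5), "\\[0, 1\\]")
})

test_that("simulated durations convert at 12 months per million cycles", {
  expect_equal(cyclesToMonths(5), 60)
  expect_equal(cyclesToMonths(0.5), 6)
  expect_equal(cyclesToMonths(5, monthsPerMc = 10), 50)
  expect_error(cyclesToMonths(-1))
})

test_that("descriptor tables key rows by component id", {
  coh <- sampleCohort(cohortSpec(list(list(
    pop = presetPopulation("simulator"), n = 3)), masterSeed = 2))
  imgs <- lapply(coh$images, function(i) toRightSide(standardizeImage(i)))
  tab <- descriptorTable(imgs)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$component_id, coh$table$component_id)
  expect_true(all(tab$med_area > 0))
  # simulator scars are anterior: positive AP centroid
  expect_true(all(tab$med_centroid_ap > 0))
})
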