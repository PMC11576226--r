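test_that("pairwise correlation matches the direct formula", {
  b <- boldSeries(array(0, c(2, 1, 1, 4)), 2.5)
  b@data[1, 1, 1, ] <- c(1, 2, 3, 4)
  b@data[2, 1, 1, ] <- c(1, 2, 3, 5)
  # direct covariance / (sd * sd) evaluation, independent of stats::cor
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  expected <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pairwiseCorrelation(b, c(1, 1, 1), c(2, 1, 1))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got, pairwiseCorrelation(b, c(2, 1, 1), c(1, 1, 1)))

  ident <- identicalSeriesBold()
  expect_equal(pairwiseCorrelation(ident, c(1, 1, 1), c(3, 3, 3)), 1.0)
  neg <- ident
  neg@data[1, 1, 1, ] <- -neg@data[1, 1, 1, ]
  expect_equal(pairwiseCorrelation(neg, c(1, 1, 1), c(2, 2, 2)), -1.0)

  flat <- ident
  flat@data[1, 1, 1, ] <- 7
  expect_error(pairwiseCorrelation(flat, c(1, 1, 1), c(2, 2, 2)),
               "zero-variance")
})

test_that("fully correlated 3x3x3 grid is a complete, contiguous graph", {
  b <- identicalSeriesBold()
  m <- fullMask(c(3, 3, 3))
  g <- computeGfcd(b, m)
  l <- computeLfcd(b, m)
  expect_true(all(voxelValues(g) == 26))
  expect_true(all(voxelValues(l) == 26))
  lr <- longRangeMap(g, l)
  expect_true(all(voxelValues(lr) == 0))
  expect_identical(fcdKind(lr), "long_range")
})

test_that("a correlated line under 6-adjacency gives lFCD 4 along it", {
  shape <- c(7, 5, 5); nt <- 60
  set.seed(11)
  arr <- array(rnorm(prod(shape) * nt), c(shape, nt))
  s <- as.numeric(scale(rnorm(nt)))
  for (x in 2:6) arr[x, 3, 3, ] <- s
  b <- boldSeries(arr, 2.5)
  l <- computeLfcd(b, fullMask(shape), fcdConfig(neighborhood = 6))
  expect_true(all(voxelValues(l)[2:6, 3, 3] == 4))
})

test_that("the two-block fixture separates local from global centrality", {
  cfg <- twoBlockConfig()
  b <- generateBold(cfg, 1)
  m <- fullMask(b)
  g <- computeGfcd(b, m); l <- computeLfcd(b, m)
  lr <- longRangeMap(g, l)
  blk <- studyGroundTruth(cfg)@plantedLocalDegree > 0
  expect_true(all(voxelValues(g)[blk] == 15))
  expect_true(all(voxelValues(l)[blk] == 7))
  expect_true(all(voxelValues(lr)[blk] == 8))
})

test_that("long-range map rejects mismatched or inconsistent inputs", {
  b <- identicalSeriesBold()
  m <- fullMask(c(3, 3, 3))
  g <- computeGfcd(b, m); l <- computeLfcd(b, m)
  expect_error(longRangeMap(l, l), "expects a gfcd map")
  partial <- array(TRUE, c(3, 3, 3)); partial[1, 1, 1] <- FALSE
  l2 <- computeLfcd(b, brainMask(partial, volumeGrid(c(3, 3, 3))))
  expect_error(longRangeMap(g, l2), "different masks")
})

test_that("noise-only volumes carry almost no supra-threshold edges", {
  # raw white noise, 120 frames: P(r > 0.6) is far below 1e-3 per pair
  b <- makeNoiseBold(c(6, 6, 6), 120, seed = 21)
  g <- oracleGfcd(b, fullMask(c(6, 6, 6)))
  nPairs <- choose(216, 2)
  pNull <- stats::pt(0.6 * sqrt(118) / sqrt(1 - 0.36), df = 118,
                     lower.tail = FALSE)
  bound <- stats::qbinom(0.999, nPairs, pNull)
  expect_lte(sum(g) / 2, bound)
  gImpl <- voxelValues(computeGfcd(b, fullMask(c(6, 6, 6))))
  expect_identical(as.integer(gImpl), as.integer(g))
})

test_that("log transform follows the stated zero conventions", {
  grid <- volumeGrid(c(2, 2, 2))
  counts <- array(c(1, 26, 0, 5, NA, 2, 3, 4), c(2, 2, 2))
  lf <- new("DensityMap", grid = grid, counts = counts, kind = "lfcd")
  out <- logFcd(lf)
  expect_identical(fcdKind(out), "srfcd")
  expect_equal(voxelValues(out)[1, 1, 1], 0)
  expect_equal(voxelValues(out)[2, 1, 1], log(26), tolerance = 1e-12)
  expect_true(is.na(voxelValues(out)[1, 2, 1]))      # count 0 -> missing
  expect_true(is.na(voxelValues(out)[1, 1, 2]))      # NA propagates

  out1 <- logFcd(lf, fcdConfig(zeroHandling = "add_one"))
  expect_equal(voxelValues(out1)[1, 2, 1], 0)        # log1p(0)
  expect_equal(voxelValues(out1)[2, 1, 1], log1p(26))

  gf <- new("DensityMap", grid = grid, counts = counts, kind = "gfcd")
  expect_error(logFcd(gf), "allowGfcd")
  expect_identical(fcdKind(logFcd(gf, allowGfcd = TRUE)), "log_gfcd")
  lrm <- new("DensityMap", grid = grid, counts = counts, kind = "long_range")
  expect_identical(fcdKind(logFcd(lrm)), "lrfcd")
})

test_that("masked smoothing renormalizes over present voxels", {
  grid <- volumeGrid(c(9, 9, 9), 2)
  vals <- array(NA_real_, c(9, 9, 9))
  vals[3:7, 3:7, 3:7] <- 2.5
  m <- new("LogFcdMap", grid = grid, values = vals, kind = "srfcd",
           smoothed = FALSE)
  sm <- smoothLogFcd(m, 8)
  expect_true(sm@smoothed)
  expect_identical(is.na(voxelValues(sm)), is.na(vals))
  expect_lt(max(abs(voxelValues(sm)[3:7, 3:7, 3:7] - 2.5)), 1e-6)

  solo <- array(NA_real_, c(9, 9, 9)); solo[5, 5, 5] <- 1.23
  ms <- smoothLogFcd(new("LogFcdMap", grid = grid, values = solo,
                         kind = "srfcd", smoothed = FALSE), 8)
  expect_equal(voxelValues(ms)[5, 5, 5], 1.23, tolerance = 1e-12)

  expect_error(smoothLogFcd(sm, 8), "already smoothed")
})

test_that("masked smoothing equals the explicit kernel-sum oracle", {
  grid <- volumeGrid(c(9, 9, 9), 2)
  set.seed(9)
  vals <- array(rnorm(729), c(9, 9, 9))
  vals[sample(729, 200)] <- NA
  sm <- smoothLogFcd(new("LogFcdMap", grid = grid, values = vals,
                         kind = "srfcd", smoothed = FALSE), 8)
  sigma <- 8 / (2 * 2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  present <- which(!is.na(vals), arr.ind = TRUE)
  set.seed(10)
  for (row in sample(nrow(present), 20)) {
    p <- present[row, ]
    num <- 0; den <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      q <- p + c(dx, dy, dz)
      if (any(q < 1) || any(q > 9)) next
      v <- vals[q[1], q[2], q[3]]
      if (is.na(v)) next
      w <- k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1]
      num <- num + w * v; den <- den + w
    }
    expect_equal(voxelValues(sm)[p[1], p[2], p[3]], num / den,
                 tolerance = 1e-10)
  }
})

test_that("participant pipeline is deterministic and internally consistent", {
  cfg <- randomOracleConfig(71)
  b <- generateBold(cfg, 1)
  m <- fullMask(b)
  f1 <- participantFcd(b, m)
  f2 <- participantFcd(b, m)
  expect_identical(voxelValues(f1$srfcd), voxelValues(f2$srfcd))
  expect_identical(voxelValues(f1$lrfcd), voxelValues(f2$lrfcd))
  expect_true(all(voxelValues(f1$gfcd) >= voxelValues(f1$lfcd), na.rm = TRUE))
  expect_identical(fcdKind(f1$srfcd), "srfcd")
  expect_identical(fcdKind(f1$lrfcd), "lrfcd")
})

test_that("structural invariants hold on random structured volumes", {
  for (seed in 101:105) {
    cfg <- randomOracleConfig(seed)
    b <- generateBold(cfg, 1)
    m <- fullMask(b)
    V <- 216
    g6 <- computeGfcd(b, m, fcdConfig(neighborhood = 6))
    g26 <- computeGfcd(b, m, fcdConfig(neighborhood = 26))
    expect_identical(voxelValues(g6), voxelValues(g26))  # gFCD ignores adjacency
    l6 <- voxelValues(computeLfcd(b, m, fcdConfig(neighborhood = 6)))
    l18 <- voxelValues(computeLfcd(b, m, fcdConfig(neighborhood = 18)))
    l26 <- voxelValues(computeLfcd(b, m, fcdConfig(neighborhood = 26)))
    expect_true(all(l6 <= l18 & l18 <= l26))             # adjacency monotone
    expect_true(all(l26 <= voxelValues(g26)))
    expect_true(all(voxelValues(g26) <= V - 1))
    # threshold monotonicity
    lLow <- voxelValues(computeLfcd(b, m, fcdConfig(correlationThreshold = 0.5)))
    lHigh <- voxelValues(computeLfcd(b, m, fcdConfig(correlationThreshold = 0.7)))
    expect_true(all(lHigh <= l26 & l26 <= lLow))
    # positive-affine invariance of the time series
    b2 <- b
    b2@data <- b@data * 3.2 + 17
    expect_identical(voxelValues(computeGfcd(b2, m)), voxelValues(g26))
    expect_identical(voxelValues(computeLfcd(b2, m)), l26)
  }
})

test_that("cluster_size convention shifts every count by one", {
  cfg <- randomOracleConfig(301)
  b <- generateBold(cfg, 1)
  m <- fullMask(b)
  edges <- computeLfcd(b, m, fcdConfig(countConvention = "edges"))
  size <- computeLfcd(b, m, fcdConfig(countConvention = "cluster_size"))
  expect_identical(voxelValues(size), voxelValues(edges) + 1)
})

test_that("zero-variance voxels are reported and connect to nothing", {
  b <- makeNoiseBold(c(4, 4, 4), 60, seed = 5)
  b@data[1, 1, 1, ] <- 4
  m <- fullMask(c(4, 4, 4))
  expect_warning(g <- computeGfcd(b, m), "zero-variance")
  expect_identical(voxelValues(g)[1, 1, 1], 0)
})

test_that("mean srFCD ranks voxels by planted local degree", {
  # independent-noise contract (no spatial smoothness), 10 participants
  cfg <- syntheticConfig(gridShape = c(14L, 14L, 14L), nParticipants = 10L,
                         noiseSmoothFwhmVox = 0,
                         hubs = data.frame(cx = c(4, 10), cy = c(4, 10),
                                           cz = c(4, 10), radius = c(1, 2),
                                           rhoWithin = 0.9),
                         pairs = data.frame(a = 1L, b = 2L,
                                            rhoBetween = 0.5),
                         seed = 99L)
  truth <- studyGroundTruth(cfg)
  m <- brainMask(array(TRUE, c(14, 14, 14)), volumeGrid(c(14, 14, 14), 2))
  srSum <- array(0, c(14, 14, 14)); srN <- array(0L, c(14, 14, 14))
  for (p in 1:10) {
    f <- participantFcd(generateBold(cfg, p, truth), m)
    v <- voxelValues(f$srfcd)
    ok <- !is.na(v)
    srSum[ok] <- srSum[ok] + v[ok]; srN <- srN + ok
  }
  meanSr <- srSum / srN
  use <- srN > 0
  rho <- cor(meanSr[use], truth@plantedLocalDegree[use], method = "spearman")
  expect_gt(rho, 0.5)
})
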