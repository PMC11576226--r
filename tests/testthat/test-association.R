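test_that("Spearman rho matches the closed-form rank formula", {
  x <- 1:5; y <- c(3, 1, 2, 5, 4)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d the rank differences
  d <- rank(x) - rank(y)
  expected <- 1 - 6 * sum(d^2) / (5 * (25 - 1))
  st <- spearmanTest(x, y)
  expect_equal(st$rho, expected)
  expect_equal(st$rho, 0.6)

  up <- spearmanTest(1:8, exp(1:8))      # monotone transform
  expect_equal(up$rho, 1)
  expect_equal(up$p, 0)
  down <- spearmanTest(1:8, rev(sort(rnorm(8))))
  expect_equal(down$rho, -1)

  expect_error(spearmanTest(rep(1, 6), 1:6), "constant")
  expect_error(spearmanTest(1:4, 4:1), "at least 5")
  expect_error(spearmanTest(1:6, 1:5), "equal length")
})

test_that("Spearman p agrees with the reference t approximation", {
  set.seed(2)
  for (n in c(10, 30, 100)) {
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    st <- spearmanTest(x, y)
    ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
    expect_equal(st$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(st$p, ref$p.value, tolerance = 1e-10)
  }
  # exact enumeration at small n agrees with cor.test's exact p
  set.seed(3)
  x <- rnorm(6); y <- rnorm(6)
  stE <- spearmanTest(x, y, exact = TRUE)
  refE <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(stE$p, refE$p.value, tolerance = 1e-10)
})

test_that("Fisher z is the odd, invertible atanh with safe clipping", {
  expect_identical(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisherZ(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_true(all(diff(fisherZ(r)) > 0))
  z <- seq(-5, 5, by = 0.25)
  expect_lt(max(abs(atanh(tanh(z)) - z)), 1e-10)
  expect_warning(zc <- fisherZ(1), "clipped")
  expect_equal(zc, atanh(1 - 1e-7))
  expect_error(fisherZ(1.2), "no Fisher")
})

test_that("region means average present voxels only", {
  grid <- volumeGrid(c(4, 4, 4))
  lab <- array(0L, c(4, 4, 4)); lab[1:3, 1, 1] <- 1L; lab[1, 2, 1] <- 2L
  parc <- new("BrainParcellation", grid = grid, labels = lab,
              labelTable = data.frame(label = 1:2, name = c("a", "b"),
                                      group = "g", spinnable = TRUE))
  v <- array(NA_real_, c(4, 4, 4)); v[1:3, 1, 1] <- c(1, 2, 3)
  expect_equal(roiMean(volume3D(v, grid), parc, 1), 2.0)
  v[2, 1, 1] <- NA
  expect_equal(roiMean(volume3D(v, grid), parc, 1), 2.0)  # mean of 1, 3
  expect_error(roiMean(volume3D(v, grid), parc, 2), "no present voxels")
  # network unit aggregates both labels
  v[1, 2, 1] <- 5
  expect_equal(roiMean(volume3D(v, grid), parc, "g", unit = "network"), 3)
})

test_that("whole-map association recovers monotone coupling across regions", {
  grid <- volumeGrid(c(6, 6, 6))
  lab <- array(rep(1:6, each = 36), c(6, 6, 6))
  parc <- new("BrainParcellation", grid = grid, labels = lab,
              labelTable = data.frame(label = 1:6,
                                      name = paste0("r", 1:6),
                                      group = "g", spinnable = TRUE))
  set.seed(6)
  base <- array(rnorm(216, 10, 1), c(6, 6, 6))
  suvr <- volume3D(base, grid)
  fcd <- volume3D(exp(base / 5), grid)         # strictly monotone transform
  out <- wholeMapAssociation(suvr, fcd, parc)
  expect_equal(out$rho, 1)
  expect_identical(out$n, 6L)
  expect_identical(nrow(out$roiMeans), 6L)
})

test_that("whole-map association under the null rejects at its level", {
  grid <- volumeGrid(c(5, 5, 4))
  lab <- array(rep(1:20, each = 5), c(5, 5, 4))
  parc <- new("BrainParcellation", grid = grid, labels = lab,
              labelTable = data.frame(label = 1:20,
                                      name = paste0("r", 1:20),
                                      group = "g", spinnable = TRUE))
  set.seed(41)
  rej <- 0L
  for (r in 1:400) {
    a <- volume3D(array(rnorm(100), c(5, 5, 4)), grid)
    b <- volume3D(array(rnorm(100), c(5, 5, 4)), grid)
    if (wholeMapAssociation(a, b, parc)$p < 0.05) rej <- rej + 1L
  }
  # binomial 95% band around 0.05 with 400 replicates: [0.029, 0.071]
  expect_gte(rej / 400, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 400))
  expect_lte(rej / 400, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400))
})

test_that("pooled within-region association behaves at both extremes", {
  # perfect monotone coupling for every participant
  xs <- replicate(6, rnorm(30), simplify = FALSE)
  ys <- lapply(xs, function(x) exp(x))
  suppressWarnings(res <- pooledSpearmanTest(xs, ys))
  expect_true(all(res$rho == 1))
  expect_true(all(res$z >= atanh(1 - 1e-7) - 1e-9))
  expect_lt(res$pRaw, 1e-10)

  # independent maps: mean of mean z across replicates is centred on 0
  set.seed(12)
  means <- vapply(1:200, function(r) {
    xs <- replicate(6, rnorm(20), simplify = FALSE)
    ys <- replicate(6, rnorm(20), simplify = FALSE)
    pooledSpearmanTest(xs, ys)$meanZ
  }, numeric(1))
  se <- sd(means) / sqrt(200)
  expect_lt(abs(mean(means)), 2 * se + 1e-3)

  xs4 <- replicate(6, rnorm(4), simplify = FALSE)
  expect_error(pooledSpearmanTest(xs4, xs4), "fewer than 5")
})

test_that("within-region association respects the parcellation", {
  grid <- volumeGrid(c(6, 6, 6))
  lab <- array(0L, c(6, 6, 6)); lab[, , 1:3] <- 1L; lab[, , 4:6] <- 2L
  parc <- new("BrainParcellation", grid = grid, labels = lab,
              labelTable = data.frame(label = 1:2, name = c("a", "b"),
                                      group = c("net1", "net1"),
                                      spinnable = TRUE))
  set.seed(8)
  suvrMaps <- lapply(1:5, function(p) volume3D(array(rnorm(216), c(6, 6, 6)),
                                               grid))
  fcdMaps <- lapply(suvrMaps, function(m)
    volume3D(voxelValues(m)^3 + 1, grid))   # monotone per participant
  r <- withinRoiAssociation(suvrMaps, fcdMaps, parc, 1, metric = "srfcd")
  expect_s4_class(r, "AssociationResult")
  expect_true(all(r@rho == 1))
  expect_identical(r@unit, "roi")
  expect_identical(r@nVoxels, rep(108L, 5))
  rn <- withinRoiAssociation(suvrMaps, fcdMaps, parc, "net1",
                             unit = "network")
  expect_identical(rn@nVoxels, rep(216L, 5))
  expect_error(withinRoiAssociation(suvrMaps, fcdMaps, parc, 9), "no voxels")
})

test_that("normality checks have power and hold their level", {
  set.seed(14)
  rejU <- rejN <- 0L
  for (r in 1:200) {
    if (normalityCheck(runif(500), "ks")$p < 0.05) rejU <- rejU + 1L
    if (normalityCheck(rnorm(500), "ks")$p < 0.05) rejN <- rejN + 1L
  }
  expect_gte(rejU / 200, 0.95)
  band <- 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_lte(abs(rejN / 200 - 0.05), band + 0.01)
  sw <- normalityCheck(runif(100), "shapiro_wilk")
  expect_true(sw$p >= 0 && sw$p <= 1)
  expect_error(normalityCheck(rep(2, 50)), "constant")
  expect_error(normalityCheck(rnorm(5), "ks"), "at least 8")
})

test_that("the Bonferroni step uses the strict study-design threshold", {
  mk <- function(p, roi) new("AssociationResult", roi = as.integer(roi),
                             unit = "roi", name = paste0("r", roi),
                             metric = "srfcd", rho = rep(0.5, 3),
                             z = rep(0.55, 3), meanZ = 0.55, meanRho = 0.5,
                             meanRhoBack = 0.5, pRaw = p,
                             bonferroniPassed = NA, pSpin = NA_real_,
                             spinStatus = "pending", nVoxels = rep(10L, 3))
  thr <- bonferroniThreshold(0.05, 90)
  expect_equal(thr, 0.05 / 90)
  res <- bonferroniStep(list(mk(thr * 0.99, 1), mk(thr, 2), mk(0.2, 3)),
                        alpha = 0.05, m = 90)
  expect_true(res[[1]]@bonferroniPassed)
  expect_false(res[[2]]@bonferroniPassed)   # equality does not pass
  expect_false(res[[3]]@bonferroniPassed)
  # m = 1 reduces to the unadjusted test
  res1 <- bonferroniStep(list(mk(0.049, 1)), alpha = 0.05, m = 1)
  expect_true(res1[[1]]@bonferroniPassed)
  expect_error(bonferroniStep(list(mk(0.1, 1), mk(0.1, 2)), m = 1),
               "smaller than the number of results")
})

test_that("second-level association tracks a constructed coupling gradient", {
  mkRes <- function(roi, meanZ, spin = 0.001) new(
    "AssociationResult", roi = as.integer(roi), unit = "roi",
    name = paste0("r", roi), metric = "srfcd", rho = rep(tanh(meanZ), 3),
    z = rep(meanZ, 3), meanZ = meanZ, meanRho = tanh(meanZ),
    meanRhoBack = tanh(meanZ), pRaw = 1e-6, bonferroniPassed = TRUE,
    pSpin = spin, spinStatus = "ok", nVoxels = rep(50L, 3))
  set.seed(15)
  hits <- 0L
  for (r in 1:100) {
    fcdMeans <- stats::setNames(sort(runif(10, 1, 3)), 1:10)
    res <- lapply(1:10, function(i)
      mkRes(i, meanZ = 0.2 + 0.1 * i + rnorm(1, 0, 0.08)))
    if (secondLevelAssociation(res, fcdMeans)$rho > 0) hits <- hits + 1L
  }
  expect_gte(hits, 90L)

  # constant coupling: correlation centred on zero
  set.seed(16)
  rhos <- vapply(1:200, function(r) {
    fcdMeans <- stats::setNames(runif(10, 1, 3), 1:10)
    res <- lapply(1:10, function(i) mkRes(i, meanZ = 0.5 + rnorm(1, 0, 0.1)))
    secondLevelAssociation(res, fcdMeans)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 2 * sd(rhos) / sqrt(200) + 0.02)

  # fewer than 5 surviving regions is an error; non-survivors are dropped
  res <- c(lapply(1:4, function(i) mkRes(i, 0.3 + 0.1 * i)),
           list(mkRes(5, 0.9, spin = 0.9)))
  expect_error(secondLevelAssociation(res, stats::setNames(1:5, 1:5)),
               "at least 5")
  # "not covered" regions still count as survivors (as reported)
  res[[5]]@spinStatus <- "not covered"; res[[5]]@pSpin <- NA_real_
  out <- secondLevelAssociation(res, stats::setNames(c(1, 2, 3, 4, 5), 1:5))
  expect_identical(out$n, 5L)
})
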