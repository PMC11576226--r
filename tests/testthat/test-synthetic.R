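test_that("BOLD generation is deterministic and plants exact structure", {
  cfg <- randomOracleConfig(42)
  b1 <- generateBold(cfg, 1)
  b2 <- generateBold(cfg, 1)
  expect_identical(voxelValues(b1), voxelValues(b2))

  # noiseless fully-correlated hub: identical series within the hub
  cfgFull <- syntheticConfig(
    gridShape = c(6L, 6L, 6L), nTimepoints = 80L, nParticipants = 1L,
    hubs = data.frame(cx = 3, cy = 3, cz = 3, radius = 1, rhoWithin = 1),
    seed = 5L)
  bF <- generateBold(cfgFull, 1)
  expect_lt(abs(pairwiseCorrelation(bF, c(3, 3, 3), c(2, 3, 3)) - 1), 1e-12)
  expect_lt(abs(pairwiseCorrelation(bF, c(4, 3, 3), c(3, 3, 4)) - 1), 1e-12)
})

test_that("with no planted structure supra-threshold pairs are rare", {
  # rhoWithin = 0 hub, spatially independent noise: brute-force pair
  # enumeration on the full 6x6x6 grid
  cfg <- syntheticConfig(
    gridShape = c(6L, 6L, 6L), nTimepoints = 120L, nParticipants = 1L,
    noiseSmoothFwhmVox = 0,
    hubs = data.frame(cx = 3, cy = 3, cz = 3, radius = 1, rhoWithin = 0),
    seed = 8L)
  b <- generateBold(cfg, 1)
  C <- oracleCorrelationMatrix(b, fullMask(c(6, 6, 6)))
  up <- C[upper.tri(C)]
  expect_lt(abs(mean(up)), 0.02)
  expect_lt(mean(up > 0.6), 1e-3)
})

test_that("within-hub mean pairwise correlation converges to rhoWithin", {
  cfg <- syntheticConfig(
    gridShape = c(8L, 8L, 8L), nTimepoints = 1200L, nParticipants = 1L,
    noiseSmoothFwhmVox = 0,
    hubs = data.frame(cx = 4, cy = 4, cz = 4, radius = 2, rhoWithin = 0.7),
    seed = 13L)
  b <- generateBold(cfg, 1)
  vox <- which(studyGroundTruth(cfg)@plantedLocalDegree > 0)
  flat <- matrix(voxelValues(b), 512, 1200)
  C <- stats::cor(t(flat[vox, ]))
  expect_lt(abs(mean(C[upper.tri(C)]) - 0.7), 0.05)
})

test_that("generated series live in the configured passband", {
  cfg <- randomOracleConfig(60)
  b <- generateBold(cfg, 1)
  # bandpassing again is a near no-op: only the one-bin cosine roll-off
  # at the band edges is attenuated twice
  again <- bandpassFilter(b, cfg@bandLowHz, cfg@bandHighHz)
  relErr <- max(abs(voxelValues(again) - voxelValues(b))) /
    max(abs(voxelValues(b)))
  expect_lt(relErr, 0.15)
})

test_that("invalid hub geometries are rejected", {
  expect_error(syntheticConfig(
    gridShape = c(6L, 6L, 6L),
    hubs = data.frame(cx = c(3, 4), cy = c(3, 3), cz = c(3, 3), radius = 1,
                      rhoWithin = 0.9)), "overlap")
  expect_error(syntheticConfig(
    gridShape = c(6L, 6L, 6L),
    hubs = data.frame(cx = 6, cy = 3, cz = 3, radius = 2, rhoWithin = 0.9)),
    "exceeds the grid")
  expect_error(syntheticConfig(
    gridShape = c(8L, 8L, 8L),
    hubs = data.frame(cx = c(2, 6), cy = c(2, 6), cz = c(2, 6), radius = 1,
                      rhoWithin = 0.4),
    pairs = data.frame(a = 1L, b = 2L, rhoBetween = 0.6)),
    "exceeds rhoWithin")
})

test_that("ground truth exposes planted degrees with the stated support", {
  cfg <- syntheticConfig()
  truth <- studyGroundTruth(cfg)
  sizes <- table(truth@plantedLocalDegree[truth@plantedLocalDegree > 0])
  expect_setequal(as.integer(names(sizes)), c(6L, 32L, 122L))
  # long-range degree only inside hubs that belong to a pair
  expect_true(all(truth@plantedLocalDegree[truth@plantedLongDegree > 0] > 0))
  # partner sizes: every paired hub carries the partner's full size
  expect_setequal(unique(truth@plantedLongDegree[truth@plantedLongDegree > 0]),
                  c(7L, 33L, 123L))
  expect_identical(length(truth@participantSeeds), 10L)
})

test_that("molecular volume couples to planted degree as configured", {
  cfg <- syntheticConfig(suvrNoiseSd = 0)
  truth <- studyGroundTruth(cfg)
  v <- generateSuvrVolume(truth, cfg, 1)
  deg <- truth@plantedLocalDegree + truth@plantedLongDegree
  hub <- deg > 0
  expect_equal(cor(voxelValues(v)[hub], deg[hub], method = "spearman"), 1)

  # determinism
  v2 <- generateSuvrVolume(truth, cfg, 1)
  expect_identical(voxelValues(v), voxelValues(v2))
  # different participants differ (through noise) once noise is on
  cfgN <- syntheticConfig()
  truthN <- studyGroundTruth(cfgN)
  a <- generateSuvrVolume(truthN, cfgN, 1)
  b <- generateSuvrVolume(truthN, cfgN, 2)
  expect_gt(max(abs(voxelValues(a) - voxelValues(b))), 0)
})

test_that("under zero coupling the molecular map is unrelated to degree", {
  cfg <- syntheticConfig(beta = 0, nParticipants = 1L)
  passes <- 0L
  for (seed in 1:200) {
    cfgS <- syntheticConfig(beta = 0, nParticipants = 1L, seed = seed)
    truth <- studyGroundTruth(cfgS)
    v <- generateSuvrVolume(truth, cfgS, 1)
    deg <- truth@plantedLocalDegree + truth@plantedLongDegree
    gm <- voxelValues(generateTissueMaps(cfgS)$gm) > 0.1
    rho <- suppressWarnings(cor(voxelValues(v)[gm], deg[gm],
                                method = "spearman"))
    if (abs(rho) < 0.1) passes <- passes + 1L
  }
  expect_gte(passes, 190L)   # >= 95% of 200 seeded replicates
})

test_that("parcellation partitions the shell with hubs intact", {
  cfg <- syntheticConfig()
  parc <- generateParcellation(cfg, 16L)
  gm <- voxelValues(generateTissueMaps(cfg)$gm) > 0.1
  lab <- voxelValues(parc)
  expect_identical(lab > 0L, gm)                     # labels cover the shell
  expect_identical(length(regionLabels(parc)), 16L)  # all regions nonempty
  vox <- fcdcoupling:::hubVoxelIndices(cfg)
  for (i in seq_along(vox)) {
    expect_identical(unique(lab[vox[[i]]]), i)       # hub entirely in one ROI
  }
  expect_identical(sort(unique(labelTable(parc)$group)),
                   sort(c("Visual", "Somatomotor", "DorsalAttention",
                          "Salience", "Limbic", "Frontoparietal", "Default")))
  expect_true(all(labelTable(parc)$spinnable))
  expect_error(generateParcellation(cfg, 1L), ">= 2")

  # small request still yields the requested number of regions
  p4 <- generateParcellation(syntheticConfig(
    gridShape = c(16L, 16L, 16L),
    hubs = data.frame(cx = 13, cy = 8, cz = 8, radius = 1, rhoWithin = 0.9)),
    4L)
  expect_identical(length(regionLabels(p4)), 4L)
})

test_that("parcellation regions grown from hubs are 26-connected", {
  cfg <- syntheticConfig()
  parc <- generateParcellation(cfg, 16L)
  lab <- voxelValues(parc)
  # check connectivity of three regions by flood fill from one member
  for (roi in c(1L, 6L, 12L)) {
    vox <- which(lab == roi, arr.ind = TRUE)
    n <- nrow(vox)
    seen <- logical(n)
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        d <- abs(sweep(vox, 2, vox[f, ], "-"))
        nb <- which(!seen & apply(d <= 1, 1, all))
        seen[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
    expect_true(all(seen))
  }
})

test_that("smooth vertex fields have the configured spatial covariance", {
  mesh <- buildIcosphere(2)
  vL <- mesh@vertices[mesh@hemisphere == "L", ]
  # a close pair and an antipodal pair on the left hemisphere
  d <- acos(pmin(pmax(vL %*% t(vL), -1), 1))
  close <- which(d > 0 & d < 0.35, arr.ind = TRUE)[1, ]
  far <- which.max(d[1, ])
  a <- b <- c <- numeric(500)
  for (s in 1:500) {
    f <- voxelValues(generateSmoothVertexMap(mesh, 0.8, seed = s))
    fL <- f[mesh@hemisphere == "L"]
    a[s] <- fL[close[1]]; b[s] <- fL[close[2]]; c[s] <- fL[far]
  }
  expect_gt(cor(a, b), 0.8)
  expect_lt(abs(cor(a, c)), 0.15)
  f1 <- generateSmoothVertexMap(mesh, 0.8, seed = 77)
  f2 <- generateSmoothVertexMap(mesh, 0.8, seed = 77)
  expect_identical(voxelValues(f1), voxelValues(f2))
})

test_that("a written study can be ingested and matches the generator", {
  dir <- withr::local_tempdir()
  cfg <- syntheticConfig(gridShape = c(16L, 16L, 16L), nParticipants = 2L,
                         nTimepoints = 40L,
                         hubs = data.frame(cx = 13, cy = 8, cz = 8,
                                           radius = 1, rhoWithin = 0.9),
                         seed = 31L)
  mf <- simulateStudy(cfg, dir, nRois = 4L)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  ing <- ingestStudy(dir)
  expect_length(ing$boldList, 2L)
  truth <- studyGroundTruth(cfg)
  b1 <- generateBold(cfg, 1, truth)
  expect_lt(max(abs(voxelValues(ing$boldList[[1]]) - voxelValues(b1))), 1e-6)
  expect_identical(regionLabels(ing$parc), 1:4)
})
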