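# Rank-based association statistics: ROI/network aggregation, Spearman
# correlation with a large-sample t approximation, Fisher z pooling
# across participants, normality checks (reporting only; inference stays
# rank-based throughout), the Bonferroni step, and the second-level
# correlation between FCD magnitude and coupling strength.

#' Spearman rank correlation with a two-sided p-value
#'
#' rho is the Pearson correlation of (average-tie) ranks; the p-value
#' comes from the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#' `exact = TRUE` enumerates all permutations (n <= 8) instead.
#'
#' @param x,y numeric vectors of equal length >= 5, non-constant.
#' @param exact logical(1); exact permutation p for small n.
#' @return list with elements `rho`, `p`, `n`.
#' @export
spearmanTest <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 paired observations, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman correlation undefined")
  rho <- stats::cor(x, y, method = "spearman")
  if (exact) {
    if (n > 8L) stop("exact permutation p only supported for n <= 8")
    rx <- rank(x); ry <- rank(y)
    perms <- permutationsOf(n)
    obs <- abs(rho)
    cnt <- 0L
    for (k in seq_len(nrow(perms))) {
      if (abs(stats::cor(rx, ry[perms[k, ]])) >= obs - 1e-12)
        cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  } else {
    p <- if (abs(rho) >= 1) 0 else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n)
}

permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsOf(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      row <- row + 1L
      out[row, ] <- append(sub[k, ], n, after = pos - 1L)
    }
  }
  out
}

#' Fisher z-transformation of a correlation coefficient
#'
#' `z = atanh(rho)`, variance-stabilizing for pooling correlations.
#' `|rho| = 1` is clipped to `atanh(1 - 1e-7)` with a warning; `|rho| > 1`
#' is an error.
#'
#' @param rho numeric vector of correlations in \[-1, 1\].
#' @return numeric vector of z values.
#' @export
fisherZ <- function(rho) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE))
    stop("|rho| > 1 has no Fisher z-transform")
  clip <- !is.na(rho) & abs(rho) >= 1
  if (any(clip)) {
    warning("|rho| = 1 clipped to +/- atanh(1 - 1e-7)")
    rho[clip] <- sign(rho[clip]) * (1 - 1e-7)
  }
  atanh(rho)
}

#' Mean of a map within one region
#'
#' Arithmetic mean over the region's present (non-missing) voxels.
#'
#' @param map a [Volume3D], [SuvrMap] or [LogFcdMap].
#' @param parc a [BrainParcellation] on the same grid.
#' @param roi integer(1) region label, or (with `unit = "network"`) a
#'   group name from the label table.
#' @param unit "roi" (default) or "network".
#' @return numeric(1).
#' @export
roiMean <- function(map, parc, roi, unit = c("roi", "network")) {
  unit <- match.arg(unit)
  checkGridCompatibility(list(map, parc))
  sel <- regionSelector(parc, roi, unit)
  v <- voxelValues(map)[sel]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("region ", roi, " has no present voxels in this map")
  mean(v)
}

regionSelector <- function(parc, region, unit) {
  if (unit == "roi") {
    labels <- as.integer(region)
  } else {
    labels <- parc@labelTable$label[parc@labelTable$group == region]
    if (length(labels) == 0L) stop("unknown network group: ", region)
  }
  parc@labels %in% labels & parc@labels > 0L
}

#' Across-region association between two mean maps
#'
#' Computes the mean of each map within every region with sufficient
#' coverage in both maps, then the Spearman correlation of those means
#' across regions (>= 5 regions required). `minVoxels` sets the
#' coverage requirement: a region enters the correlation only when both
#' maps have at least that many present voxels in it (a mean over a
#' handful of voxels is not a regional estimate; the study pipeline
#' uses 10).
#'
#' @param meanSuvr,meanFcd group-mean maps on the parcellation grid.
#' @param parc a [BrainParcellation].
#' @param minVoxels minimum present voxels per region and map
#'   (default 1).
#' @return list with `rho`, `p`, `n` (regions used) and `roiMeans`
#'   (data.frame of the per-region means).
#' @export
wholeMapAssociation <- function(meanSuvr, meanFcd, parc, minVoxels = 1L) {
  checkGridCompatibility(list(meanSuvr, meanFcd, parc))
  labs <- regionLabels(parc)
  ms <- mf <- rep(NA_real_, length(labs))
  for (k in seq_along(labs)) {
    sel <- parc@labels == labs[k]
    a <- voxelValues(meanSuvr)[sel]; a <- a[!is.na(a)]
    b <- voxelValues(meanFcd)[sel];  b <- b[!is.na(b)]
    if (length(a) >= minVoxels && length(b) >= minVoxels) {
      ms[k] <- mean(a)
      mf[k] <- mean(b)
    }
  }
  use <- !is.na(ms) & !is.na(mf)
  if (sum(use) < 5L)
    stop("need at least 5 regions with present voxels in both maps, got ",
         sum(use))
  st <- spearmanTest(ms[use], mf[use])
  list(rho = st$rho, p = st$p, n = st$n,
       roiMeans = data.frame(label = labs[use], meanSuvr = ms[use],
                             meanFcd = mf[use]))
}

#' Pooled per-participant Spearman association
#'
#' The group-inference core: per participant, the Spearman correlation
#' between paired values; Fisher z-transform; the group p-value is a
#' one-sample two-sided t test of the z values against zero.
#'
#' @param xs,ys lists (one element per participant) of paired numeric
#'   vectors; each pair must share length >= `minN` after removing
#'   missing pairs.
#' @param minN minimum paired observations per participant (default 5).
#' @return list with `rho`, `z`, `meanZ`, `meanRho`, `meanRhoBack`,
#'   `pRaw`, `nObs` (per-participant counts).
#' @export
pooledSpearmanTest <- function(xs, ys, minN = 5L) {
  stopifnot(is.list(xs), is.list(ys), length(xs) == length(ys),
            length(xs) >= 2L)
  nP <- length(xs)
  rho <- numeric(nP)
  nObs <- integer(nP)
  for (p in seq_len(nP)) {
    ok <- !is.na(xs[[p]]) & !is.na(ys[[p]])
    if (sum(ok) < minN)
      stop("participant ", p, " has fewer than ", minN, " paired values")
    st <- spearmanTest(xs[[p]][ok], ys[[p]][ok])
    rho[p] <- st$rho
    nObs[p] <- st$n
  }
  z <- suppressWarnings(fisherZ(rho))
  meanZ <- mean(z)
  pRaw <- if (stats::sd(z) == 0) {
    if (meanZ == 0) 1 else 0   # degenerate: all participants identical
  } else {
    stats::t.test(z, mu = 0)$p.value
  }
  list(rho = rho, z = z, meanZ = meanZ, meanRho = mean(rho),
       meanRhoBack = tanh(meanZ), pRaw = pRaw, nObs = nObs)
}

#' Within-region voxel-wise association across participants
#'
#' For each participant, the Spearman correlation between SUVR and FCD
#' over the paired present voxels of one region (or network); Fisher z;
#' group p from the one-sample t test of z against zero.
#'
#' @param suvrMaps,fcdMaps lists (per participant) of maps on the
#'   parcellation grid.
#' @param parc a [BrainParcellation].
#' @param region integer label (unit "roi") or group name (unit
#'   "network").
#' @param unit "roi" or "network".
#' @param metric character(1) recorded on the result (e.g. "srfcd").
#' @param minVoxels minimum present paired voxels per participant.
#' @return an [AssociationResult].
#' @export
withinRoiAssociation <- function(suvrMaps, fcdMaps, parc, region,
                                 unit = c("roi", "network"),
                                 metric = "srfcd", minVoxels = 5L) {
  unit <- match.arg(unit)
  stopifnot(is.list(suvrMaps), is.list(fcdMaps),
            length(suvrMaps) == length(fcdMaps))
  sel <- regionSelector(parc, region, unit)
  if (!any(sel)) stop("region ", region, " selects no voxels")
  xs <- lapply(suvrMaps, function(m) voxelValues(m)[sel])
  ys <- lapply(fcdMaps, function(m) voxelValues(m)[sel])
  pooled <- pooledSpearmanTest(xs, ys, minN = minVoxels)
  name <- if (unit == "roi") {
    row <- parc@labelTable[parc@labelTable$label == as.integer(region), ]
    if (nrow(row)) row$name[1L] else as.character(region)
  } else as.character(region)
  new("AssociationResult",
      roi = if (unit == "roi") as.integer(region) else 0L,
      unit = unit, name = name, metric = metric,
      rho = pooled$rho, z = pooled$z, meanZ = pooled$meanZ,
      meanRho = pooled$meanRho, meanRhoBack = pooled$meanRhoBack,
      pRaw = pooled$pRaw, bonferroniPassed = NA, pSpin = NA_real_,
      spinStatus = "pending", nVoxels = pooled$nObs)
}

#' Normality check (reporting only)
#'
#' Kolmogorov-Smirnov test against a fully specified normal distribution,
#' or the Shapiro-Wilk test. The pipeline always proceeds rank-based
#' regardless of the outcome; these statistics are reported so the choice
#' of Spearman correlation can be justified from the data.
#'
#' @param values numeric vector (>= 8 for ks, >= 3 for shapiro_wilk),
#'   non-constant.
#' @param method "ks" or "shapiro_wilk".
#' @param mean,sd reference normal parameters for the KS test.
#' @return list with `statistic` and `p`.
#' @export
normalityCheck <- function(values, method = c("ks", "shapiro_wilk"),
                           mean = 0, sd = 1) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (stats::sd(values) == 0) stop("constant input")
  if (method == "ks") {
    if (length(values) < 8L) stop("ks requires at least 8 values")
    ht <- suppressWarnings(stats::ks.test(values, "pnorm", mean, sd))
  } else {
    if (length(values) < 3L) stop("shapiro_wilk requires at least 3 values")
    ht <- stats::shapiro.test(values)
  }
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Per-test Bonferroni threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests in the family.
#' @return numeric(1), `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  if (m < 1L) stop("m must be >= 1")
  alpha / m
}

#' Bonferroni correction step
#'
#' Marks each association as passed iff `pRaw < alpha / m` (strict).
#' `m` is taken from the study design (number of regions plus number of
#' networks), not from the data, and must be at least the number of
#' results supplied.
#'
#' @param results list of [AssociationResult]s.
#' @param alpha family-wise level (default 0.05).
#' @param m integer(1) number of tests; defaults to `length(results)`.
#' @return the list with `bonferroniPassed` filled in.
#' @export
bonferroniStep <- function(results, alpha = 0.05, m = length(results)) {
  if (m < 1L) stop("m must be >= 1")
  if (m < length(results))
    stop("m (", m, ") is smaller than the number of results (",
         length(results), ")")
  thr <- bonferroniThreshold(alpha, m)
  lapply(results, function(r) {
    r@bonferroniPassed <- !is.na(r@pRaw) && r@pRaw < thr
    r
  })
}

#' Second-level association: FCD magnitude vs coupling strength
#'
#' Spearman correlation, across the regions that survived both
#' correction steps (Bonferroni, and spin where covered), between the
#' region-mean FCD values and the region mean z values of the SUVR-FCD
#' coupling.
#'
#' @param results list of [AssociationResult]s after [bonferroniStep()]
#'   (and spin testing).
#' @param fcdRoiMeans named numeric vector of region-mean FCD values,
#'   names = region labels.
#' @param spinAlpha level for the spin step (default 0.05).
#' @return list with `rho`, `p`, `n` (surviving regions used) and
#'   `survivors` (their labels).
#' @export
secondLevelAssociation <- function(results, fcdRoiMeans, spinAlpha = 0.05) {
  surv <- Filter(function(r) {
    isTRUE(r@bonferroniPassed) &&
      (r@spinStatus == "not covered" ||
         (r@spinStatus == "ok" && !is.na(r@pSpin) && r@pSpin < spinAlpha))
  }, results)
  if (length(surv) < 5L)
    stop("need at least 5 surviving regions, got ", length(surv))
  labs <- vapply(surv, function(r) r@roi, integer(1))
  zz <- vapply(surv, function(r) r@meanZ, numeric(1))
  fv <- fcdRoiMeans[as.character(labs)]
  if (anyNA(fv)) stop("missing FCD mean for a surviving region")
  st <- spearmanTest(as.numeric(fv), zz)
  list(rho = st$rho, p = st$p, n = st$n, survivors = labs)
}
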