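# End-to-end study orchestration: synthetic data (or ingested volumes) ->
# masks and SUVR -> per-participant FCD -> group means -> across-region
# and within-region associations with the two-step correction
# (Bonferroni, then spin permutation on survivors) -> second-level
# association -> report tables.

#' Construct a study configuration
#'
#' @param synthetic a [SyntheticConfig] (see [syntheticConfig()]).
#' @param fcd an [FcdConfig] (see [fcdConfig()]).
#' @param alpha family-wise level (default 0.05).
#' @param mTests Bonferroni divisor; NA (default) means number of
#'   regions + number of networks, taken from the parcellation.
#' @param nPerm spin permutations (default 200 for desk-scale runs; the
#'   full-scale convention is 1000).
#' @param meshOrder icosphere order for the spin projection (default 3;
#'   the full-scale cortical convention is 5).
#' @param smoothingFwhmMm smoothing for SUVR and log-FCD maps (default
#'   8 mm).
#' @param suvrMin SUVR retention threshold (default 1).
#' @param gmThreshold gray-matter probability threshold (default 0.10).
#' @param seed integer(1).
#' @return a [StudyConfig].
#' @export
studyConfig <- function(synthetic = syntheticConfig(), fcd = fcdConfig(),
                        alpha = 0.05, mTests = NA, nPerm = 200L,
                        meshOrder = 3L, smoothingFwhmMm = 8, suvrMin = 1.0,
                        gmThreshold = 0.10, seed = 42L) {
  new("StudyConfig", synthetic = synthetic, fcd = fcd, alpha = alpha,
      mTests = as.integer(mTests), nPerm = as.integer(nPerm),
      meshOrder = as.integer(meshOrder),
      smoothingFwhmMm = as.numeric(smoothingFwhmMm),
      suvrMin = as.numeric(suvrMin), gmThreshold = as.numeric(gmThreshold),
      seed = as.integer(seed))
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

# Missing-aware voxel-wise mean across a list of arrays.
meanArray <- function(arrs) {
  acc <- array(0, dim(arrs[[1L]]))
  cnt <- array(0L, dim(arrs[[1L]]))
  for (a in arrs) {
    ok <- !is.na(a)
    acc[ok] <- acc[ok] + a[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  out
}

#' Ingest a study previously written by [simulateStudy()]
#'
#' Reads the manifest and returns the per-participant volumes, tissue
#' maps and parcellation in the in-memory layout [runStudy()] accepts.
#'
#' @param dir directory containing `manifest.tsv`.
#' @return list with `boldList`, `petList`, `tissue`, `parc`.
#' @export
ingestStudy <- function(dir) {
  mf <- utils::read.delim(file.path(dir, "manifest.tsv"),
                          stringsAsFactors = FALSE)
  pick <- function(kind) mf$file[mf$kind == kind]
  tissue <- list(gm = readVolume(pick("tissue_gm")),
                 wm = readVolume(pick("tissue_wm")),
                 csf = readVolume(pick("tissue_csf")))
  parc <- readParcellation(file.path(dir, "parcellation.nii.gz"),
                           file.path(dir, "parcellation_labels.tsv"))
  boldFiles <- mf[mf$kind == "bold", ]
  petFiles <- mf[mf$kind == "pet", ]
  boldList <- lapply(boldFiles$file[order(boldFiles$participant)], readVolume)
  petList <- lapply(petFiles$file[order(petFiles$participant)], readVolume)
  list(boldList = boldList, petList = petList, tissue = tissue, parc = parc)
}

#' Run a full study
#'
#' Executes, in order: data generation (or ingestion), reference and
#' analysis masks, per-participant SUVR (smooth, then restrict to gray
#' matter and SUVR > threshold) and FCD (gFCD, lFCD, long-range, log,
#' masked smoothing), across-participant mean maps, across-region
#' whole-map associations (with a whole-surface spin test), within-region
#' associations for every region and network, the Bonferroni step with
#' m = regions + networks, spin tests on the Bonferroni survivors
#' (spinnable regions only), the second-level association on survivors,
#' and normality checks. Any stage failure aborts with the stage name.
#'
#' @param config a [StudyConfig].
#' @param data NULL to simulate from `config@synthetic`, or a list as
#'   returned by [ingestStudy()].
#' @param nRois regions for the generated parcellation (simulate mode).
#' @param metrics FCD metrics to analyse (default srfcd and lrfcd).
#' @param keepMaps logical; keep the group-mean maps in the report.
#' @return a [StudyReport].
#' @export
runStudy <- function(config, data = NULL, nRois = 16L,
                     metrics = c("srfcd", "lrfcd"), keepMaps = TRUE) {
  stopifnot(is(config, "StudyConfig"))
  scfg <- config@synthetic
  nP <- if (is.null(data)) scfg@nParticipants else length(data$boldList)
  truth <- NULL
  if (is.null(data)) {
    truth <- withStage("ground-truth", studyGroundTruth(scfg))
    tissue <- withStage("tissue-maps", generateTissueMaps(scfg))
    parc <- withStage("parcellation", generateParcellation(scfg, nRois))
  } else {
    tissue <- data$tissue
    parc <- data$parc
  }
  wmRef <- withStage("wm-reference-mask",
                     whiteMatterReferenceMask(tissue$wm, tissue$gm,
                                              tissue$csf,
                                              config@smoothingFwhmMm))
  gmMask <- withStage("gm-mask", grayMatterMask(tissue$gm, config@gmThreshold))

  suvrMaps <- vector("list", nP)
  srMaps <- vector("list", nP)
  lrMaps <- vector("list", nP)
  rawFcd <- vector("list", nP)
  for (p in seq_len(nP)) {
    pet <- withStage(sprintf("pet participant %d", p),
                     if (is.null(data)) generateSuvrVolume(truth, scfg, p)
                     else data$petList[[p]])
    suvr <- withStage(sprintf("suvr participant %d", p), {
      s <- computeSuvr(pet, wmRef)
      sm <- gaussianSmooth(new("Volume3D", grid = s@grid, values = s@values),
                           config@smoothingFwhmMm)
      thresholdSuvr(new("SuvrMap", grid = s@grid, values = sm@values,
                        referenceMean = s@referenceMean),
                    gmMask, config@suvrMin)
    })
    bold <- withStage(sprintf("bold participant %d", p),
                      if (is.null(data)) generateBold(scfg, p, truth)
                      else data$boldList[[p]])
    fcd <- withStage(sprintf("fcd participant %d", p),
                     participantFcd(bold, gmMask, config@fcd,
                                    config@smoothingFwhmMm))
    suvrMaps[[p]] <- suvr
    srMaps[[p]] <- fcd$srfcd
    lrMaps[[p]] <- fcd$lrfcd
    rawFcd[[p]] <- list(gfcd = fcd$gfcd, lfcd = fcd$lfcd)
  }

  grid <- imageGrid(tissue$gm)
  meanSuvr <- new("Volume3D", grid = grid,
                  values = meanArray(lapply(suvrMaps, voxelValues)))
  meanMaps <- list(suvr = meanSuvr)
  fcdMapsByMetric <- list(srfcd = srMaps, lrfcd = lrMaps)
  for (m in metrics)
    meanMaps[[m]] <- new("LogFcdMap", grid = grid,
                         values = meanArray(lapply(fcdMapsByMetric[[m]],
                                                   voxelValues)),
                         kind = m, smoothed = TRUE)

  # spherical projection for spin testing
  mesh <- withStage("mesh", {
    msh <- buildIcosphere(config@meshOrder)
    center <- grid@origin + (grid@shape - 1) / 2 * grid@voxelSize
    radius <- (scfg@gmInnerRadius + scfg@gmOuterRadius) / 2 *
      mean(grid@voxelSize)
    placeMeshInVolume(msh, center, radius)
  })
  vertexLabels <- withStage("vertex-labels",
                            sampleParcellationAtVertices(parc, mesh))
  vertexMaps <- withStage("vertex-maps", {
    vm <- list(suvr = sampleVolumeAtVertices(meanSuvr, mesh))
    for (m in metrics) vm[[m]] <- sampleVolumeAtVertices(meanMaps[[m]], mesh)
    vm
  })

  wholeRows <- list()
  roiResults <- list()
  labs <- regionLabels(parc)
  groups <- unique(parc@labelTable$group)
  mT <- if (is.na(config@mTests)) length(labs) + length(groups) else
    config@mTests

  for (m in metrics) {
    wm <- withStage(sprintf("whole-map association (%s)", m),
                    wholeMapAssociation(meanSuvr, meanMaps[[m]], parc,
                                        minVoxels = 10L))
    sp <- withStage(sprintf("whole-map spin (%s)", m),
                    spinPvalue(vertexMaps$suvr, vertexMaps[[m]],
                               nPerm = config@nPerm,
                               seed = config@seed + match(m, metrics)))
    wholeRows[[m]] <- data.frame(
      metric = m, rho = wm$rho, p = wm$p, nRegions = wm$n,
      spinObserved = sp@observed, pSpin = sp@p, stringsAsFactors = FALSE)
    attr(wholeRows[[m]], "roiMeans") <- wm$roiMeans

    units <- c(lapply(labs, function(l) list(region = l, unit = "roi")),
               lapply(groups, function(g) list(region = g, unit = "network")))
    res <- lapply(units, function(u) {
      tryCatch(
        withinRoiAssociation(suvrMaps, fcdMapsByMetric[[m]], parc,
                             u$region, unit = u$unit, metric = m),
        error = function(e) NULL)
    })
    skippedUnits <- units[vapply(res, is.null, logical(1))]
    res <- Filter(Negate(is.null), res)
    res <- withStage(sprintf("bonferroni (%s)", m),
                     bonferroniStep(res, config@alpha, m = mT))
    # spin step on Bonferroni survivors only
    res <- lapply(seq_along(res), function(k) {
      r <- res[[k]]
      if (!isTRUE(r@bonferroniPassed)) {
        r@spinStatus <- "skipped"
        return(r)
      }
      spinSeed <- config@seed + 1000L * match(m, metrics) + k
      # regions the projection cannot cover (non-spinnable, or too few
      # vertices on the sphere) keep their Bonferroni status and are
      # flagged "not covered" rather than aborting the run
      sr <- tryCatch({
        if (r@unit == "roi") {
          spinTestRoi(vertexMaps$suvr, vertexMaps[[m]], vertexLabels,
                      r@roi, labelTable = parc@labelTable,
                      nPerm = config@nPerm, seed = spinSeed)
        } else {
          memberLabs <- parc@labelTable$label[parc@labelTable$group == r@name]
          restrict <- which(vertexLabels@labels %in% memberLabs)
          if (length(restrict) < 10L) NULL else
            spinPvalue(vertexMaps$suvr, vertexMaps[[m]],
                       nPerm = config@nPerm, seed = spinSeed,
                       restrict = restrict)
        }
      }, error = function(e) NULL)
      if (is.null(sr)) {
        r@spinStatus <- "not covered"
      } else {
        r@pSpin <- sr@p
        r@spinStatus <- sr@status
      }
      r
    })
    roiResults[[m]] <- res
    attr(roiResults[[m]], "skippedUnits") <- skippedUnits
  }

  wholeMap <- do.call(rbind, unname(wholeRows))
  roiTable <- do.call(rbind, lapply(metrics, function(m) {
    rows <- lapply(roiResults[[m]], function(r) {
      grp <- if (r@unit == "roi")
        parc@labelTable$group[parc@labelTable$label == r@roi][1L] else r@name
      data.frame(unit = r@unit, label = r@roi, name = r@name, group = grp,
                 metric = m, nParticipants = length(r@rho),
                 meanRho = r@meanRho, meanZ = r@meanZ,
                 meanRhoBack = r@meanRhoBack, pRaw = r@pRaw,
                 bonferroniPassed = r@bonferroniPassed, pSpin = r@pSpin,
                 spinStatus = r@spinStatus,
                 significant = isTRUE(r@bonferroniPassed) &&
                   (r@spinStatus == "not covered" ||
                      (r@spinStatus == "ok" && !is.na(r@pSpin) &&
                         r@pSpin < config@alpha)),
                 rhoList = paste(signif(r@rho, 6), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    skipped <- attr(roiResults[[m]], "skippedUnits")
    skRows <- lapply(skipped, function(u) {
      nm <- if (u$unit == "roi")
        parc@labelTable$name[parc@labelTable$label == u$region][1L] else
          u$region
      grp <- if (u$unit == "roi")
        parc@labelTable$group[parc@labelTable$label == u$region][1L] else
          u$region
      data.frame(unit = u$unit,
                 label = if (u$unit == "roi") as.integer(u$region) else 0L,
                 name = nm, group = grp, metric = m, nParticipants = 0L,
                 meanRho = NA_real_, meanZ = NA_real_,
                 meanRhoBack = NA_real_, pRaw = NA_real_,
                 bonferroniPassed = NA, pSpin = NA_real_,
                 spinStatus = "insufficient data", significant = FALSE,
                 rhoList = "", stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, skRows))
  }))

  secondLevel <- do.call(rbind, lapply(metrics, function(m) {
    rm <- attr(wholeRows[[m]], "roiMeans")
    fcdMeans <- stats::setNames(rm$meanFcd, rm$label)
    roiOnly <- Filter(function(r) r@unit == "roi", roiResults[[m]])
    out <- tryCatch(secondLevelAssociation(roiOnly, fcdMeans,
                                           spinAlpha = config@alpha),
                    error = function(e) NULL)
    if (is.null(out))
      data.frame(metric = m, rho = NA_real_, p = NA_real_, n = 0L,
                 status = "not computed", stringsAsFactors = FALSE)
    else
      data.frame(metric = m, rho = out$rho, p = out$p, n = out$n,
                 status = "ok", stringsAsFactors = FALSE)
  }))

  normality <- withStage("normality", {
    rows <- list()
    for (m in c("suvr", metrics)) {
      rmap <- meanMaps[[m]]
      vals <- vapply(labs, function(l)
        tryCatch(roiMean(rmap, parc, l), error = function(e) NA_real_),
        numeric(1))
      vals <- vals[!is.na(vals)]
      if (length(vals) >= 8L && stats::sd(vals) > 0) {
        ks <- normalityCheck(vals, "ks", mean = mean(vals),
                             sd = stats::sd(vals))
        sw <- normalityCheck(vals, "shapiro_wilk")
        rows[[m]] <- data.frame(
          quantity = paste0("region mean ", m), n = length(vals),
          ksStatistic = ks$statistic, ksP = ks$p,
          shapiroStatistic = sw$statistic, shapiroP = sw$p,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, unname(rows))
  })

  manifest <- list(
    seed = config@seed, nParticipants = nP,
    gridShape = scfg@gridShape, nTimepoints = scfg@nTimepoints,
    correlationThreshold = config@fcd@correlationThreshold,
    neighborhood = config@fcd@neighborhood, alpha = config@alpha,
    mTests = mT, nPerm = config@nPerm, meshOrder = config@meshOrder,
    smoothingFwhmMm = config@smoothingFwhmMm,
    packageVersion = as.character(utils::packageVersion("fcdcoupling")))

  new("StudyReport", wholeMap = wholeMap, roiTable = roiTable,
      secondLevel = secondLevel,
      normality = if (is.null(normality)) data.frame() else normality,
      meanMaps = if (keepMaps) meanMaps else list(),
      groundTruth = truth, manifest = manifest)
}

#' Summarize a study report
#'
#' Prints a human-readable summary (per-region table sorted by
#' descending mean z, with correction flags) and, when `dir` is given,
#' writes the report tables as TSV plus a JSON manifest.
#'
#' @param report a [StudyReport].
#' @param dir optional output directory (created if absent).
#' @return invisibly the sorted region table.
#' @export
summarizeStudy <- function(report, dir = NULL) {
  stopifnot(is(report, "StudyReport"))
  cat("Whole-map associations (across regions):\n")
  for (i in seq_len(nrow(report@wholeMap))) {
    r <- report@wholeMap[i, ]
    cat(sprintf("  SUVR vs %-6s rho = %+.3f (p = %.3g), spin p = %.3g over %d regions\n",
                r$metric, r$rho, r$p, r$pSpin, r$nRegions))
  }
  tab <- report@roiTable
  tab <- tab[order(-xtfrm(ifelse(is.na(tab$meanZ), -Inf, tab$meanZ))), ]
  cat(sprintf("\nRegion/network associations (%d rows, sorted by mean z):\n",
              nrow(tab)))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    flag <- if (r$spinStatus == "insufficient data") "insufficient data"
    else if (isTRUE(r$significant)) "survived both steps"
    else if (isTRUE(r$bonferroniPassed) && r$spinStatus == "not covered")
      "survived Bonferroni; spin: not covered"
    else if (isTRUE(r$bonferroniPassed)) "survived Bonferroni only"
    else "not significant"
    cat(sprintf("  %-8s %-12s %-6s mean z %+6.3f  p %.3g  [%s]\n",
                r$unit, r$name, r$metric,
                ifelse(is.na(r$meanZ), NA, r$meanZ), r$pRaw, flag))
  }
  cat("\nSecond-level (FCD magnitude vs coupling strength):\n")
  for (i in seq_len(nrow(report@secondLevel))) {
    r <- report@secondLevel[i, ]
    if (r$status == "ok")
      cat(sprintf("  %-6s rho = %+.3f (p = %.3g) over %d surviving regions\n",
                  r$metric, r$rho, r$p, r$n))
    else
      cat(sprintf("  %-6s not computed (fewer than 5 surviving regions)\n",
                  r$metric))
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeResultTable(report@wholeMap, file.path(dir, "whole_map.tsv"))
    writeResultTable(tab, file.path(dir, "regions.tsv"))
    writeResultTable(report@secondLevel, file.path(dir, "second_level.tsv"))
    if (nrow(report@normality))
      writeResultTable(report@normality, file.path(dir, "normality.tsv"))
    jsonlite::write_json(report@manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(tab)
}
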