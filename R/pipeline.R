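## End-to-end experiment orchestration: phantom (or loaded) cohort ->
## multi-variant tensor fits -> FA maps -> smoothing -> WM mask -> advisory
## Bartlett gate -> ANCOVA eta2p -> post hoc Hedges' g -> partial Spearman
## -> cluster extraction and labeling per fit -> cross-fit consistency ->
## averaged-map analysis. Stage outputs are written to the run directory
## before the next stage begins; with a fixed config and seed every output
## is bit-identical across runs.

#' Configuration of a full experiment run
#'
#' @slot phantom a \linkS4class{PhantomSpec}, or NULL when \code{inputs} is
#'   given. The run seed overrides the phantom's own seed so one config +
#'   seed pins the whole experiment.
#' @slot inputs optional list for real data: \code{images}, \code{bvals},
#'   \code{bvecs} (parallel path vectors), \code{cohortCsv}, and optionally
#'   \code{atlasNifti} + \code{atlasTsv}.
#' @slot fitMethods fit variants to run.
#' @slot analysis an \linkS4class{AnalysisConfig}.
#' @slot contrasts subset of "ANCOVA", "AD vs HC", "AD vs MCI", "HC vs MCI".
#' @slot scores cognitive scores to correlate (subset of MoCA, MMSE, ADAS).
#' @slot outputDir run directory.
#' @slot seed integer seed.
#' @export
setClass("RunConfig",
  representation(phantom = "ANY", inputs = "ANY", fitMethods = "character",
                 analysis = "AnalysisConfig", contrasts = "character",
                 scores = "character", outputDir = "character",
                 seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@fitMethods) < 1) msg <- c(msg, "need at least one fit variant")
    bad <- setdiff(object@fitMethods, c("lls", "wlls", "nlls", "nlls-pos", "restore"))
    if (length(bad)) msg <- c(msg, paste("unknown fit methods:", paste(bad, collapse = ", ")))
    bad_c <- setdiff(object@contrasts,
                     c("ANCOVA", "AD vs HC", "AD vs MCI", "HC vs MCI"))
    if (length(bad_c)) msg <- c(msg, paste("unknown contrasts:", paste(bad_c, collapse = ", ")))
    if (is.null(object@phantom) && is.null(object@inputs))
      msg <- c(msg, "either a phantom spec or real inputs must be given")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a RunConfig
#' @param phantom a \linkS4class{PhantomSpec} (default: \code{phantomSpec()}).
#' @param inputs real-data input list (see \linkS4class{RunConfig}).
#' @param fitMethods fit variants (default: all five).
#' @param analysis an \linkS4class{AnalysisConfig}.
#' @param contrasts contrasts to run.
#' @param scores cognitive scores to correlate.
#' @param outputDir run directory.
#' @param seed integer seed.
#' @return A \linkS4class{RunConfig}.
#' @export
runConfig <- function(phantom = phantomSpec(), inputs = NULL,
                      fitMethods = c("lls", "wlls", "nlls", "nlls-pos", "restore"),
                      analysis = analysisConfig(),
                      contrasts = c("ANCOVA", "AD vs HC", "AD vs MCI", "HC vs MCI"),
                      scores = c("MMSE", "MoCA", "ADAS"),
                      outputDir = tempfile("dtivba_run_"), seed = 42) {
  new("RunConfig", phantom = phantom, inputs = inputs, fitMethods = fitMethods,
      analysis = analysis, contrasts = contrasts, scores = scores,
      outputDir = outputDir, seed = seed)
}

load_real_inputs <- function(inputs) {
  vols <- mapply(readDWI, inputs$images, inputs$bvals, inputs$bvecs,
                 SIMPLIFY = FALSE)
  cohort <- readCohort(inputs$cohortCsv)
  atlas <- if (!is.null(inputs$atlasNifti))
    readLabelAtlas(inputs$atlasNifti, inputs$atlasTsv) else NULL
  list(volumes = vols, cohort = cohort, atlas = atlas, truth = NULL)
}

region_results <- function(clusters, atlas, stat_values) {
  # per-region significant-cluster volume (voxels) and mean |statistic|
  regions <- atlas@regionNames
  out <- data.frame(region = character(), volume = numeric(),
                    effect = numeric(), stringsAsFactors = FALSE)
  if (!length(clusters)) return(out)
  for (rn in regions) {
    lab <- as.integer(names(regions)[regions == rn][1])
    rmask <- atlas@labels == lab
    vol <- 0; acc <- 0
    for (cl in clusters) {
      inr <- rmask[cl@voxels]
      if (any(inr)) {
        vol <- vol + sum(inr)
        acc <- acc + sum(abs(stat_values[cl@voxels[inr, , drop = FALSE]]))
      }
    }
    if (vol > 0)
      out <- rbind(out, data.frame(region = rn, volume = vol,
                                   effect = acc / vol, stringsAsFactors = FALSE))
  }
  out
}

write_stage <- function(dir, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  invisible(dir)
}

#' Run the full experiment described by a config
#'
#' @param config a \linkS4class{RunConfig}.
#' @param verbose print stage progress.
#' @return A run report: list with elements \code{cohort}, \code{wmMasks},
#'   \code{bartlett}, \code{perFit} (per variant: eta2p/g/rho maps and
#'   labeled clusters), \code{consistency} (mean r-ICC, leave-one-out table,
#'   cross-fit r^2 matrices), \code{combined} (averaged-map clusters per
#'   contrast), \code{table3} (region-by-contrast coverage), and
#'   \code{provenance}. Maps, cluster tables and the JSON report are written
#'   under \code{config@outputDir}.
#' @export
runExperiment <- function(config, verbose = interactive()) {
  validObject(config)
  say <- function(...) if (verbose) message(...)
  out_dir <- config@outputDir
  write_stage(out_dir)
  ac <- config@analysis

  ## stage 1: data
  say("stage: data")
  if (!is.null(config@phantom)) {
    spec <- config@phantom
    spec@seed <- config@seed
    data <- generateCohort(spec)
  } else {
    data <- load_real_inputs(config@inputs)
  }
  cohort <- data$cohort
  atlas <- data$atlas
  vs <- data$volumes[[1]]@voxelSize
  dims <- dim(data$volumes[[1]]@signal)[1:3]
  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)

  ## stage 2: fits + FA + smoothing
  say("stage: tensor fits")
  map_dir <- write_stage(file.path(out_dir, "maps"))
  n <- length(data$volumes)
  fa_smooth <- list()   # variant -> 4D array
  for (mth in config@fitMethods) {
    arr <- array(0, c(dims, n))
    for (s in seq_len(n)) {
      vol <- data$volumes[[s]]
      field <- fitTensor(vol, method = mth)
      fam <- computeFA(field)
      sm <- smoothMap(fam@values, ac@smoothingSigmaMM, vs, mask = field@mask)
      arr[, , , s] <- sm
    }
    fa_smooth[[mth]] <- arr
    writeMap(arr[, , , 1], data$volumes[[1]],
             file.path(map_dir, paste0("fa_smooth_", mth, "_subj1.nii.gz")))
  }

  ## stage 3: WM masks (per fit) + advisory Bartlett gate
  say("stage: masks and variance gate")
  wm <- lapply(fa_smooth, wmMask, threshold = ac@faMaskThreshold)
  bart <- lapply(names(wm), function(mth) {
    m <- wm[[mth]]
    subj_mean <- vapply(seq_len(n), function(s) {
      v <- fa_smooth[[mth]][, , , s]
      mean(v[m])
    }, numeric(1))
    by_group <- split(subj_mean, droplevels(cohort$group))
    res <- tryCatch(bartlettGate(by_group),
                    error = function(e) list(statistic = NA_real_,
                                             p.value = NA_real_, df = NA_real_,
                                             error = conditionMessage(e)))
    res
  })
  names(bart) <- names(wm)

  ## stage 4: per-fit voxel-based statistics
  say("stage: voxel-based statistics")
  clus_dir <- write_stage(file.path(out_dir, "clusters"))
  per_fit <- list()
  pair_of <- list("AD vs HC" = c("AD", "HC"), "AD vs MCI" = c("AD", "MCI"),
                  "HC vs MCI" = c("HC", "MCI"))
  for (mth in config@fitMethods) {
    m <- wm[[mth]]
    res <- list(wmVoxels = sum(m))
    if ("ANCOVA" %in% config@contrasts) {
      eta <- ancovaEta2p(fa_smooth[[mth]], cohort, mask = m, voxel_size = vs)
      cl <- extractClusters(eta, ac@eta2pThreshold, ac@minClusterVoxels,
                            two_sided = FALSE, connectivity = ac@connectivity)
      if (!is.null(atlas)) cl <- labelClusters(cl, atlas, dims)
      res$eta2p <- list(map = eta, clusters = cl)
      writeMap(eta@values, data$volumes[[1]],
               file.path(map_dir, paste0("eta2p_", mth, ".nii.gz")))
      write.table(clusterTable(cl),
                  file.path(clus_dir, paste0("eta2p_", mth, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (cn in intersect(config@contrasts, names(pair_of))) {
      gmap <- hedgesG(fa_smooth[[mth]], cohort, groups = pair_of[[cn]],
                      mask = m, voxel_size = vs)
      cl <- extractClusters(gmap, ac@gThreshold, ac@minClusterVoxels,
                            two_sided = TRUE, connectivity = ac@connectivity)
      if (!is.null(atlas)) cl <- labelClusters(cl, atlas, dims)
      key <- gsub(" ", "_", cn)
      res[[paste0("g_", key)]] <- list(map = gmap, clusters = cl)
      write.table(clusterTable(cl),
                  file.path(clus_dir, paste0("g_", key, "_", mth, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    for (sc in config@scores) {
      if (all(is.na(cohort[[sc]]))) next
      rmap <- partialSpearman(fa_smooth[[mth]], cohort[[sc]], cohort,
                              mask = m, voxel_size = vs)
      cl <- extractClusters(rmap, ac@rhoThreshold, ac@minClusterVoxels,
                            two_sided = TRUE, connectivity = ac@connectivity)
      if (!is.null(atlas)) cl <- labelClusters(cl, atlas, dims)
      res[[paste0("rho_", sc)]] <- list(map = rmap, clusters = cl)
    }
    per_fit[[mth]] <- res
  }

  ## stage 5: cross-fit consistency
  say("stage: consistency")
  consist <- NULL
  if (length(config@fitMethods) >= 2) {
    cons_dir <- write_stage(file.path(out_dir, "consistency"))
    stack <- fitStack(fa_smooth, voxelSize = vs)
    pooled_mask <- wmMask(array(unlist(fa_smooth),
                                c(dims, n * length(fa_smooth))),
                          threshold = ac@faMaskThreshold)
    vi <- voxelwiseICC(stack, pooled_mask)
    loo <- if (length(config@fitMethods) >= 3)
      leaveOneOut(stack, pooled_mask) else NULL
    xmat <- NULL
    if (!is.null(atlas) && "ANCOVA" %in% config@contrasts) {
      prr <- lapply(config@fitMethods, function(mth)
        region_results(per_fit[[mth]]$eta2p$clusters, atlas,
                       per_fit[[mth]]$eta2p$map@values))
      names(prr) <- config@fitMethods
      xmat <- crossfitMatrices(prr)
      write.table(xmat$volume, file.path(cons_dir, "r2_cluster_volume.tsv"),
                  sep = "\t", quote = FALSE)
      write.table(xmat$effect, file.path(cons_dir, "r2_effect_size.tsv"),
                  sep = "\t", quote = FALSE)
    }
    writeMap(vi$iccMap@values, data$volumes[[1]],
             file.path(map_dir, "icc.nii.gz"))
    if (!is.null(loo))
      write.table(loo, file.path(cons_dir, "leave_one_out.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    consist <- list(iccMap = vi$iccMap, meanICC = vi$meanICC,
                    leaveOneOut = loo, crossfit = xmat,
                    mask = pooled_mask)
  }

  ## stage 6: averaged-map analysis
  say("stage: averaged maps")
  combined <- list()
  if ("ANCOVA" %in% config@contrasts) {
    avg <- averageMaps(lapply(per_fit, function(r) r$eta2p$map))
    cl <- extractClusters(avg, ac@eta2pThreshold, ac@minClusterVoxels,
                          two_sided = FALSE, connectivity = ac@connectivity)
    if (!is.null(atlas)) cl <- labelClusters(cl, atlas, dims)
    combined$ANCOVA <- list(map = avg, clusters = cl)
  }
  for (cn in intersect(config@contrasts, names(pair_of))) {
    key <- paste0("g_", gsub(" ", "_", cn))
    avg <- averageMaps(lapply(per_fit, function(r) r[[key]]$map))
    cl <- extractClusters(avg, ac@gThreshold, ac@minClusterVoxels,
                          two_sided = TRUE, connectivity = ac@connectivity)
    if (!is.null(atlas)) cl <- labelClusters(cl, atlas, dims)
    combined[[cn]] <- list(map = avg, clusters = cl)
  }

  report <- list(cohort = cohort, faSmooth = fa_smooth,
                 wmMasks = wm, bartlett = bart,
                 perFit = per_fit, consistency = consist, combined = combined,
                 atlas = atlas, truth = data$truth,
                 provenance = list(
                   seed = config@seed, fitMethods = config@fitMethods,
                   thresholds = list(eta2p = ac@eta2pThreshold,
                                     g = ac@gThreshold, rho = ac@rhoThreshold,
                                     minClusterVoxels = ac@minClusterVoxels,
                                     faMask = ac@faMaskThreshold,
                                     smoothingSigmaMM = ac@smoothingSigmaMM,
                                     connectivity = ac@connectivity),
                   configHash = config_hash(config)))
  if (!is.null(atlas)) {
    report$table3 <- summarizeTable3(report, atlas)
    write.table(report$table3, file.path(out_dir, "table3.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  json <- list(provenance = report$provenance,
               bartlett = lapply(bart, function(b)
                 b[c("statistic", "p.value")]),
               meanICC = if (!is.null(consist)) consist$meanICC else NULL,
               leaveOneOut = if (!is.null(consist)) consist$leaveOneOut else NULL,
               combinedClusterCounts = lapply(combined, function(cc)
                 length(cc$clusters)))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}

config_hash <- function(config) {
  config@outputDir <- ""   # hash the scientific configuration, not the path
  s <- paste(capture.output(str(config, give.attr = FALSE)), collapse = "\n")
  # small stable polynomial hash over the printed config
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Region-by-contrast coverage of the averaged-map clusters
#'
#' Rows are atlas regions, columns the run's contrasts; each cell is the
#' percentage of the region's volume covered by significant clusters of the
#' averaged (cross-fit) statistic maps. Negative and positive g components
#' are reported in separate columns (e.g. "AD < HC" and "AD > HC"). Regions
#' with no coverage anywhere are retained as zero rows.
#'
#' @param report a report from \code{\link{runExperiment}}.
#' @param atlas a \linkS4class{LabelAtlas}.
#' @return data.frame.
#' @export
summarizeTable3 <- function(report, atlas) {
  regions <- atlas@regionNames
  region_masks <- lapply(names(regions), function(lb)
    atlas@labels == as.integer(lb))
  names(region_masks) <- regions

  cover <- function(clusters, sgn = NULL) {
    vapply(regions, function(rn) {
      rmask <- region_masks[[rn]]
      tot <- sum(rmask)
      hit <- 0
      for (cl in clusters) {
        if (!is.null(sgn) && cl@sign != sgn) next
        hit <- hit + sum(rmask[cl@voxels])
      }
      round(100 * hit / tot, 2)
    }, numeric(1))
  }

  out <- data.frame(region = unname(regions), stringsAsFactors = FALSE)
  for (cn in names(report$combined)) {
    cl <- report$combined[[cn]]$clusters
    if (cn == "ANCOVA") {
      out[["ANCOVA"]] <- cover(cl)
    } else {
      a <- sub(" vs.*", "", cn); b <- sub(".*vs ", "", cn)
      out[[paste(a, "<", b)]] <- cover(cl, sgn = -1)
      out[[paste(a, ">", b)]] <- cover(cl, sgn = 1)
    }
  }
  out
}
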