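#' @useDynLib dtivba, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats bartlett.test coef cor lm median na.omit
#'   quantile rbinom rnorm runif sd setNames var contr.sum
#' @importFrom utils read.csv read.delim write.csv write.table capture.output str
NULL

#' Gradient scheme of a diffusion acquisition
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions. Directions of
#' diffusion-weighted volumes must be unit vectors (they are re-normalized at
#' construction when the deviation is below 1e-3); b = 0 volumes may carry
#' zero vectors. A scheme must contain at least one b = 0 volume and at least
#' seven diffusion-weighted volumes, the minimum for the 7-parameter tensor
#' model to be identifiable.
#'
#' @slot bvals numeric vector of b-values, one per volume.
#' @slot bvecs numeric matrix (volumes x 3) of gradient directions.
#' @export
setClass("GradientScheme",
  representation(bvals = "numeric", bvecs = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- length(object@bvals)
    if (!is.numeric(object@bvecs) || nrow(object@bvecs) != n || ncol(object@bvecs) != 3)
      msg <- c(msg, sprintf("bvecs must be a %d x 3 numeric matrix", n))
    if (any(object@bvals < 0))
      msg <- c(msg, "negative b-values are not allowed")
    if (length(msg) == 0) {
      dwi <- object@bvals > 0
      if (sum(!dwi) < 1) msg <- c(msg, "scheme needs at least one b = 0 volume")
      if (sum(dwi) < 7)
        msg <- c(msg, "scheme needs at least 7 diffusion-weighted volumes")
      if (any(dwi)) {
        norms <- sqrt(rowSums(object@bvecs[dwi, , drop = FALSE]^2))
        if (any(abs(norms - 1) >= 1e-3))
          msg <- c(msg, "diffusion-weighted b-vectors must have unit norm (within 1e-3)")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a GradientScheme
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs numeric matrix (volumes x 3) of gradient directions. Vectors
#'   on diffusion-weighted volumes whose norm deviates from 1 by less than
#'   1e-3 are re-normalized; larger deviations are an error.
#' @return A \linkS4class{GradientScheme}.
#' @export
gradientScheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  storage.mode(bvecs) <- "double"
  if (nrow(bvecs) == 3 && length(bvals) != 3 && ncol(bvecs) == length(bvals))
    bvecs <- t(bvecs)
  dwi <- which(bvals > 0)
  if (length(dwi)) {
    norms <- sqrt(rowSums(bvecs[dwi, , drop = FALSE]^2))
    fix <- abs(norms - 1) < 1e-3 & norms > 0
    if (any(fix))
      bvecs[dwi[fix], ] <- bvecs[dwi[fix], , drop = FALSE] / norms[fix]
  }
  new("GradientScheme", bvals = bvals, bvecs = bvecs)
}

#' One subject's 4D diffusion-weighted acquisition
#'
#' @slot signal 4D non-negative array (nx, ny, nz, nvol) in scanner units.
#' @slot voxelSize numeric length-3, voxel dimensions in mm.
#' @slot scheme the \linkS4class{GradientScheme} describing the volumes.
#' @slot subjectID subject identifier.
#' @slot refHeader optional NIfTI header template (from \code{RNifti}) used to
#'   preserve the affine when maps derived from this volume are written out.
#' @export
setClass("DWIVolume",
  representation(signal = "array", voxelSize = "numeric",
                 scheme = "GradientScheme", subjectID = "character",
                 refHeader = "ANY"),
  prototype(refHeader = NULL),
  validity = function(object) {
    msg <- character()
    d <- dim(object@signal)
    if (length(d) != 4) msg <- c(msg, "signal must be a 4D array")
    else if (d[4] != length(object@scheme@bvals))
      msg <- c(msg, sprintf("volume count mismatch %d vs %d",
                            d[4], length(object@scheme@bvals)))
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive values (mm)")
    if (any(object@signal < 0, na.rm = TRUE))
      msg <- c(msg, "signal values must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Per-voxel diffusion tensors from a fit
#'
#' Tensor elements are stored internally in the order Dxx, Dyy, Dzz, Dxy,
#' Dxz, Dyz (mm^2/s), matching the regression parameter order. Diagnostic
#' flags are a bitmask: 1 = all-zero voxel, 2 = clamped non-positive signals,
#' 4 = non-convergence (LLS estimate returned), 8 = RESTORE reverted to WLLS.
#'
#' @slot tensors 4D array (nx, ny, nz, 6).
#' @slot lnS0 3D array of fitted log reference signals.
#' @slot mask 3D logical array of fitted voxels.
#' @slot method fit variant tag ("lls", "wlls", "nlls", "nlls-pos", "restore").
#' @slot flags 3D integer array of diagnostic bits.
#' @slot outlierCount 3D integer array; RESTORE's excluded measurements per voxel.
#' @slot voxelSize numeric length-3 (mm).
#' @export
setClass("TensorField",
  representation(tensors = "array", lnS0 = "array", mask = "array",
                 method = "character", flags = "array",
                 outlierCount = "array", voxelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@tensors)
    msg <- character()
    if (length(d) != 4 || d[4] != 6)
      msg <- c(msg, "tensors must be (nx, ny, nz, 6)")
    else {
      if (!identical(dim(object@lnS0), d[1:3])) msg <- c(msg, "lnS0 grid mismatch")
      if (!identical(dim(object@mask), d[1:3])) msg <- c(msg, "mask grid mismatch")
      inmask <- which(object@mask)
      if (length(inmask)) {
        tm <- matrix(object@tensors, prod(d[1:3]), 6)[inmask, , drop = FALSE]
        if (!all(is.finite(tm)))
          msg <- c(msg, "non-finite tensor elements inside the fitted mask")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' A voxelwise scalar statistic map
#'
#' @slot values 3D array of the statistic (NA outside the analysis domain).
#' @slot kind one of "eta2p", "g", "rho", "fa", "icc".
#' @slot contrast free-text description (e.g. "AD vs HC").
#' @slot voxelSize numeric length-3 (mm).
#' @slot thresholds named list of thresholds used to produce or intended for
#'   the map (may be empty).
#' @export
setClass("StatMap",
  representation(values = "array", kind = "character", contrast = "character",
                 voxelSize = "numeric", thresholds = "list"),
  prototype(contrast = "", thresholds = list()),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3) msg <- c(msg, "values must be 3D")
    if (!object@kind %in% c("eta2p", "g", "rho", "fa", "icc"))
      msg <- c(msg, "kind must be one of eta2p, g, rho, fa, icc")
    v <- object@values[is.finite(object@values)]
    if (length(v)) {
      if (object@kind == "eta2p" && (min(v) < 0 || max(v) > 1))
        msg <- c(msg, "eta2p values must lie in [0, 1]")
      if (object@kind %in% c("rho", "icc") && (min(v) < -1 || max(v) > 1))
        msg <- c(msg, sprintf("%s values must lie in [-1, 1]", object@kind))
      if (object@kind == "fa" && (min(v) < 0 || max(v) > 1))
        msg <- c(msg, "fa values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a StatMap
#' @param values 3D array.
#' @param kind statistic kind ("eta2p", "g", "rho", "fa", "icc").
#' @param voxelSize numeric length-3 (mm).
#' @param contrast description string.
#' @param thresholds named list.
#' @return A \linkS4class{StatMap}.
#' @export
statMap <- function(values, kind, voxelSize, contrast = "", thresholds = list()) {
  new("StatMap", values = values, kind = kind, voxelSize = as.numeric(voxelSize),
      contrast = contrast, thresholds = thresholds)
}

#' A fractional anisotropy map with its eigenvalue spectrum
#'
#' FA is computed from eigenvalues with negatives clamped to zero and is
#' clipped to [0, 1]; the \code{eigenvalues} slot keeps the unclamped sorted
#' spectrum as a diagnostic.
#'
#' @slot eigenvalues 4D array (nx, ny, nz, 3), descending per voxel.
#' @slot mask 3D logical array of fitted voxels.
#' @export
setClass("FAMap", contains = "StatMap",
  representation(eigenvalues = "array", mask = "array"))

#' Integer-labeled region atlas on the cohort grid
#'
#' @slot labels 3D integer array; 0 is background.
#' @slot regionNames named character vector mapping label (as character) to
#'   region name.
#' @export
setClass("LabelAtlas",
  representation(labels = "array", regionNames = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3) msg <- c(msg, "labels must be 3D")
    used <- setdiff(unique(as.integer(object@labels)), 0L)
    missing <- setdiff(as.character(used), names(object@regionNames))
    if (length(missing))
      msg <- c(msg, paste("labels without names:", paste(missing, collapse = ", ")))
    if (length(msg)) msg else TRUE
  }
)

#' Construct a LabelAtlas
#' @param labels 3D integer array (0 = background).
#' @param regionNames named character vector, names are label integers as
#'   character strings.
#' @return A \linkS4class{LabelAtlas}.
#' @export
labelAtlas <- function(labels, regionNames) {
  storage.mode(labels) <- "integer"
  new("LabelAtlas", labels = labels, regionNames = regionNames)
}

#' A supra-threshold cluster
#'
#' @slot voxels integer matrix (n x 3) of 1-based voxel indices.
#' @slot size number of voxels.
#' @slot peak peak statistic value (signed).
#' @slot centroid numeric length-3 voxel-coordinate centroid.
#' @slot sign +1 for positive components, -1 for negative ones.
#' @slot overlaps data.frame with columns region, pctRegionCovered,
#'   pctClusterInRegion (filled by \code{\link{labelClusters}}).
#' @export
setClass("Cluster",
  representation(voxels = "matrix", size = "numeric", peak = "numeric",
                 centroid = "numeric", sign = "numeric", overlaps = "data.frame"),
  prototype(overlaps = data.frame(region = character(),
                                  pctRegionCovered = numeric(),
                                  pctClusterInRegion = numeric(),
                                  stringsAsFactors = FALSE)),
  validity = function(object) {
    if (nrow(object@voxels) != object@size)
      "size must equal the number of voxels" else TRUE
  }
)

#' Analysis thresholds and settings for voxel-based group statistics
#'
#' Defaults mirror a conventional effect-size-thresholded FA study: large
#' partial eta-squared (> 0.15), large |Hedges' g| (> 0.85), |Spearman rho| >
#' 0.50, cluster size strictly greater than 100 voxels, white-matter mask at
#' mean FA > 0.20, isotropic Gaussian smoothing with sigma 3 mm, and
#' 26-connectivity for cluster extraction.
#'
#' @slot eta2pThreshold,gThreshold,rhoThreshold statistic thresholds.
#' @slot minClusterVoxels cluster-size minimum (strict: size must exceed it).
#' @slot faMaskThreshold white-matter mask FA threshold.
#' @slot smoothingSigmaMM Gaussian kernel sigma in mm.
#' @slot connectivity 6, 18 or 26.
#' @export
setClass("AnalysisConfig",
  representation(eta2pThreshold = "numeric", gThreshold = "numeric",
                 rhoThreshold = "numeric", minClusterVoxels = "numeric",
                 faMaskThreshold = "numeric", smoothingSigmaMM = "numeric",
                 connectivity = "numeric"),
  prototype(eta2pThreshold = 0.15, gThreshold = 0.85, rhoThreshold = 0.50,
            minClusterVoxels = 100, faMaskThreshold = 0.20,
            smoothingSigmaMM = 3.0, connectivity = 26),
  validity = function(object) {
    msg <- character()
    pos <- c(eta2p = object@eta2pThreshold, g = object@gThreshold,
             rho = object@rhoThreshold, minVox = object@minClusterVoxels,
             faMask = object@faMaskThreshold)
    if (any(pos <= 0)) msg <- c(msg, "all thresholds must be positive")
    if (object@smoothingSigmaMM < 0) msg <- c(msg, "smoothing sigma must be >= 0")
    if (!object@connectivity %in% c(6, 18, 26))
      msg <- c(msg, "connectivity must be 6, 18 or 26")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an AnalysisConfig
#' @param eta2pThreshold partial eta-squared threshold (default 0.15).
#' @param gThreshold |Hedges' g| threshold (default 0.85).
#' @param rhoThreshold |Spearman rho| threshold (default 0.50).
#' @param minClusterVoxels strict cluster-size minimum (default 100).
#' @param faMaskThreshold WM mask mean-FA threshold (default 0.20).
#' @param smoothingSigmaMM Gaussian smoothing sigma in mm (default 3).
#' @param connectivity cluster connectivity, 6, 18 or 26 (default 26).
#' @return An \linkS4class{AnalysisConfig}.
#' @export
analysisConfig <- function(eta2pThreshold = 0.15, gThreshold = 0.85,
                           rhoThreshold = 0.50, minClusterVoxels = 100,
                           faMaskThreshold = 0.20, smoothingSigmaMM = 3.0,
                           connectivity = 26) {
  new("AnalysisConfig", eta2pThreshold = eta2pThreshold, gThreshold = gThreshold,
      rhoThreshold = rhoThreshold, minClusterVoxels = minClusterVoxels,
      faMaskThreshold = faMaskThreshold, smoothingSigmaMM = smoothingSigmaMM,
      connectivity = connectivity)
}

#' A stack of per-variant, per-subject FA maps on a common grid
#'
#' @slot variants character vector of fit-variant names.
#' @slot data named list; each element a 4D array (nx, ny, nz, nsubjects).
#' @slot voxelSize numeric length-3 (mm).
#' @export
setClass("FitStack",
  representation(variants = "character", data = "list", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@variants) < 2) msg <- c(msg, "need at least 2 fit variants")
    if (!identical(names(object@data), object@variants))
      msg <- c(msg, "data names must match variants")
    dims <- lapply(object@data, dim)
    if (length(unique(lapply(dims, identity))) > 1)
      msg <- c(msg, "all variants must share grid and subject count")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a FitStack from per-variant FA maps
#' @param data named list; each element either a 4D array
#'   (nx, ny, nz, nsubjects) or a list of per-subject \linkS4class{FAMap} /
#'   \linkS4class{StatMap} objects or 3D arrays.
#' @param voxelSize numeric length-3 (mm); taken from the first map when
#'   available.
#' @return A \linkS4class{FitStack}.
#' @export
fitStack <- function(data, voxelSize = NULL) {
  stopifnot(is.list(data), length(names(data)) == length(data))
  arrs <- lapply(data, function(el) {
    if (is.array(el) && length(dim(el)) == 4) return(el)
    if (is.list(el)) {
      mats <- lapply(el, function(m) {
        if (is(m, "StatMap")) {
          if (is.null(voxelSize)) voxelSize <<- m@voxelSize
          m@values
        } else m
      })
      return(array(unlist(mats), dim = c(dim(mats[[1]]), length(mats))))
    }
    stop("each variant must be a 4D array or a list of maps")
  })
  if (is.null(voxelSize)) voxelSize <- c(1, 1, 1)
  new("FitStack", variants = names(arrs), data = arrs,
      voxelSize = as.numeric(voxelSize))
}
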