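#' @name accessors
#' @title Accessors for dtivba classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots.
#' @param object an object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setMethod("bValues", "GradientScheme", function(object) object@bvals)
#' @rdname accessors
#' @export
setMethod("bValues", "DWIVolume", function(object) object@scheme@bvals)

#' @rdname accessors
#' @export
setGeneric("bVectors", function(object) standardGeneric("bVectors"))
#' @rdname accessors
#' @export
setMethod("bVectors", "GradientScheme", function(object) object@bvecs)
#' @rdname accessors
#' @export
setMethod("bVectors", "DWIVolume", function(object) object@scheme@bvecs)

#' @rdname accessors
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))
#' @rdname accessors
#' @export
setMethod("nVolumes", "GradientScheme", function(object) length(object@bvals))
#' @rdname accessors
#' @export
setMethod("nVolumes", "DWIVolume", function(object) dim(object@signal)[4])

#' @rdname accessors
#' @export
setGeneric("signalArray", function(object) standardGeneric("signalArray"))
#' @rdname accessors
#' @export
setMethod("signalArray", "DWIVolume", function(object) object@signal)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "DWIVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "TensorField", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "StatMap", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))
#' @rdname accessors
#' @export
setMethod("subjectID", "DWIVolume", function(object) object@subjectID)

#' @rdname accessors
#' @export
setGeneric("gradientSchemeOf", function(object) standardGeneric("gradientSchemeOf"))
#' @rdname accessors
#' @export
setMethod("gradientSchemeOf", "DWIVolume", function(object) object@scheme)

#' @rdname accessors
#' @export
setGeneric("tensorArray", function(object) standardGeneric("tensorArray"))
#' @rdname accessors
#' @export
setMethod("tensorArray", "TensorField", function(object) object@tensors)

#' @rdname accessors
#' @export
setGeneric("lnS0Array", function(object) standardGeneric("lnS0Array"))
#' @rdname accessors
#' @export
setMethod("lnS0Array", "TensorField", function(object) object@lnS0)

#' @rdname accessors
#' @export
setGeneric("fitMethod", function(object) standardGeneric("fitMethod"))
#' @rdname accessors
#' @export
setMethod("fitMethod", "TensorField", function(object) object@method)

#' @rdname accessors
#' @export
setGeneric("fitFlags", function(object) standardGeneric("fitFlags"))
#' @rdname accessors
#' @export
setMethod("fitFlags", "TensorField", function(object) object@flags)

#' @rdname accessors
#' @export
setGeneric("outlierCount", function(object) standardGeneric("outlierCount"))
#' @rdname accessors
#' @export
setMethod("outlierCount", "TensorField", function(object) object@outlierCount)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setMethod("mapValues", "StatMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("mapKind", function(object) standardGeneric("mapKind"))
#' @rdname accessors
#' @export
setMethod("mapKind", "StatMap", function(object) object@kind)

#' @rdname accessors
#' @export
setGeneric("mapContrast", function(object) standardGeneric("mapContrast"))
#' @rdname accessors
#' @export
setMethod("mapContrast", "StatMap", function(object) object@contrast)

#' @rdname accessors
#' @export
setGeneric("eigenvalueArray", function(object) standardGeneric("eigenvalueArray"))
#' @rdname accessors
#' @export
setMethod("eigenvalueArray", "FAMap", function(object) object@eigenvalues)

#' @rdname accessors
#' @export
setGeneric("atlasLabels", function(object) standardGeneric("atlasLabels"))
#' @rdname accessors
#' @export
setMethod("atlasLabels", "LabelAtlas", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("regionNames", function(object) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setMethod("regionNames", "LabelAtlas", function(object) object@regionNames)

#' @rdname accessors
#' @export
setGeneric("clusterSize", function(object) standardGeneric("clusterSize"))
#' @rdname accessors
#' @export
setMethod("clusterSize", "Cluster", function(object) object@size)

#' @rdname accessors
#' @export
setGeneric("clusterVoxels", function(object) standardGeneric("clusterVoxels"))
#' @rdname accessors
#' @export
setMethod("clusterVoxels", "Cluster", function(object) object@voxels)

#' @rdname accessors
#' @export
setGeneric("clusterPeak", function(object) standardGeneric("clusterPeak"))
#' @rdname accessors
#' @export
setMethod("clusterPeak", "Cluster", function(object) object@peak)

#' @rdname accessors
#' @export
setGeneric("clusterOverlaps", function(object) standardGeneric("clusterOverlaps"))
#' @rdname accessors
#' @export
setMethod("clusterOverlaps", "Cluster", function(object) object@overlaps)

#' @rdname accessors
#' @export
setGeneric("variantNames", function(object) standardGeneric("variantNames"))
#' @rdname accessors
#' @export
setMethod("variantNames", "FitStack", function(object) object@variants)

setMethod("show", "GradientScheme", function(object) {
  b <- object@bvals
  cat(sprintf("GradientScheme: %d volumes (%d b=0, %d diffusion-weighted, b = %s)\n",
              length(b), sum(b == 0), sum(b > 0),
              paste(unique(b[b > 0]), collapse = "/")))
})

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@signal)
  cat(sprintf("DWIVolume '%s': %d x %d x %d voxels x %d volumes, voxel %.3g x %.3g x %.3g mm\n",
              object@subjectID, d[1], d[2], d[3], d[4],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "TensorField", function(object) {
  d <- dim(object@tensors)
  cat(sprintf("TensorField (%s): %d x %d x %d grid, %d fitted voxels\n",
              object@method, d[1], d[2], d[3], sum(object@mask)))
  nf <- sum(object@flags[object@mask] != 0)
  if (nf) cat(sprintf("  %d voxels carry diagnostic flags\n", nf))
})

setMethod("show", "StatMap", function(object) {
  d <- dim(object@values)
  v <- object@values[is.finite(object@values)]
  cat(sprintf("StatMap [%s]%s: %d x %d x %d grid, %d finite voxels, range [%.4g, %.4g]\n",
              object@kind,
              if (nzchar(object@contrast)) paste0(" ", object@contrast) else "",
              d[1], d[2], d[3], length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "LabelAtlas", function(object) {
  cat(sprintf("LabelAtlas: %s grid, %d regions\n",
              paste(dim(object@labels), collapse = " x "),
              length(object@regionNames)))
})

setMethod("show", "Cluster", function(object) {
  cat(sprintf("Cluster: %d voxels, peak %.4g, centroid (%.1f, %.1f, %.1f)\n",
              object@size, object@peak, object@centroid[1],
              object@centroid[2], object@centroid[3]))
  if (nrow(object@overlaps)) {
    top <- object@overlaps[1, ]
    cat(sprintf("  top region: %s (%.1f%% of region covered)\n",
                top$region, top$pctRegionCovered))
  }
})

setMethod("show", "FitStack", function(object) {
  d <- dim(object@data[[1]])
  cat(sprintf("FitStack: %d variants (%s), %d subjects on %d x %d x %d grid\n",
              length(object@variants), paste(object@variants, collapse = ", "),
              d[4], d[1], d[2], d[3]))
})
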