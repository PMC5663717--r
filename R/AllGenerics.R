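#' @include AllClasses.R
NULL

#' Accessors for fitted mixtures, panels, connectivity arrays and components
#'
#' Small accessor generics so downstream code never touches slots.
#'
#' @param object An object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cutoff", function(object) standardGeneric("cutoff"))
#' @rdname accessors
#' @export
setMethod("cutoff", "MixtureFit", function(object) object@cutoff)

#' @rdname accessors
#' @export
setGeneric("mixtureParams", function(object) standardGeneric("mixtureParams"))
#' @rdname accessors
#' @export
setMethod("mixtureParams", "MixtureFit", function(object) {
  list(weights = object@weights, means = object@means, sds = object@sds,
       loglik = object@loglik, nIter = object@nIter,
       converged = object@converged, n = object@n)
})

#' @rdname accessors
#' @export
setGeneric("suvrBaseline", function(object) standardGeneric("suvrBaseline"))
#' @rdname accessors
#' @export
setMethod("suvrBaseline", "RoiSuvrPanel", function(object)
  SummarizedExperiment::assay(object, "suvr_baseline"))

#' @rdname accessors
#' @export
setGeneric("suvrFollowup", function(object) standardGeneric("suvrFollowup"))
#' @rdname accessors
#' @export
setMethod("suvrFollowup", "RoiSuvrPanel", function(object)
  SummarizedExperiment::assay(object, "suvr_followup"))

#' @rdname accessors
#' @export
setGeneric("scanInterval", function(object) standardGeneric("scanInterval"))
#' @rdname accessors
#' @export
setMethod("scanInterval", "RoiSuvrPanel", function(object)
  SummarizedExperiment::colData(object)$interval_years)

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))
#' @rdname accessors
#' @export
setMethod("nodeLabels", "ConnectivityArray", function(object) object@nodeLabels)
#' @rdname accessors
#' @export
setMethod("nodeLabels", "NetworkComponent", function(object) object@nodeLabels)

#' @rdname accessors
#' @export
setGeneric("connValues", function(object) standardGeneric("connValues"))
#' @rdname accessors
#' @export
setMethod("connValues", "ConnectivityArray", function(object) object@z)

#' @rdname accessors
#' @export
setGeneric("componentLinks", function(object) standardGeneric("componentLinks"))
#' @rdname accessors
#' @export
setMethod("componentLinks", "NetworkComponent", function(object) object@links)

#' @rdname accessors
#' @export
setGeneric("componentStat", function(object) standardGeneric("componentStat"))
#' @rdname accessors
#' @export
setMethod("componentStat", "NetworkComponent", function(object) object@S)

#' @rdname accessors
#' @export
setGeneric("permPvalue", function(object) standardGeneric("permPvalue"))
#' @rdname accessors
#' @export
setMethod("permPvalue", "NetworkComponent", function(object) object@p)

#' @rdname accessors
#' @export
setGeneric("nullSizes", function(object) standardGeneric("nullSizes"))
#' @rdname accessors
#' @export
setMethod("nullSizes", "NetworkComponent", function(object) object@nullSizes)

#' @rdname accessors
#' @export
setGeneric("tMap", function(object) standardGeneric("tMap"))
#' @rdname accessors
#' @export
setMethod("tMap", "StatMap", function(object) object@t)

#' @rdname accessors
#' @export
setGeneric("pMap", function(object) standardGeneric("pMap"))
#' @rdname accessors
#' @export
setMethod("pMap", "StatMap", function(object) object@p)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setMethod("maskArray", "StatMap", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("clusterVoxels", function(object) standardGeneric("clusterVoxels"))
#' @rdname accessors
#' @export
setMethod("clusterVoxels", "VoxelCluster", function(object) object@voxels)

#' @rdname accessors
#' @export
setGeneric("clusterSize", function(object) standardGeneric("clusterSize"))
#' @rdname accessors
#' @export
setMethod("clusterSize", "VoxelCluster", function(object) object@size)

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit (2-component univariate Gaussian)\n")
  cat(sprintf("  weights: %.3f / %.3f\n", object@weights[1], object@weights[2]))
  cat(sprintf("  means:   %.4g / %.4g   sds: %.4g / %.4g\n",
              object@means[1], object@means[2], object@sds[1], object@sds[2]))
  cat(sprintf("  cutoff (posterior 0.5 crossing): %.4g\n", object@cutoff))
  cat(sprintf("  loglik %.2f after %d EM iterations (converged: %s), n = %d\n",
              object@loglik, object@nIter, object@converged, object@n))
})

setMethod("show", "ConnectivityArray", function(object) {
  d <- dim(object@z)
  cat(sprintf("ConnectivityArray: %d nodes x %d subjects (%d links)\n",
              d[1], d[3], d[1] * (d[1] - 1L) %/% 2L))
  cat("  networks:", paste(names(table(object@nodeLabels)), collapse = " "),
      "\n")
})

setMethod("show", "StatMap", function(object) {
  d <- dim(object@t)
  cat(sprintf("StatMap: %d x %d x %d grid, %d voxels in mask, df = %g\n",
              d[1], d[2], d[3], sum(object@mask), object@df))
})

setMethod("show", "VoxelCluster", function(object) {
  cat(sprintf("VoxelCluster: %d voxels, peak t = %.2f at (%d, %d, %d)\n",
              object@size, object@peakT,
              object@peakIjk[1], object@peakIjk[2], object@peakIjk[3]))
})

setMethod("show", "NetworkComponent", function(object) {
  cat(sprintf("NetworkComponent (%s direction): %d links\n",
              object@direction, nrow(object@links)))
  cat(sprintf("  S = %.3f, summed-z partial Spearman r = %.3f\n",
              object@S, object@spearmanR))
  cat(sprintf("  permutation p = %.4g (n_perm = %d, r0 = %.3f)\n",
              object@p, object@nPerm, object@r0))
})
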