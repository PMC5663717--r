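#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats dnorm qnorm qt pt rnorm runif rbinom cor sd var
#'   complete.cases lm uniroot p.adjust wilcox.test kruskal.test setNames
#'   quantile rbeta
NULL

## Canonical CSF/PET stage labels. Order matters: it is the factor level
## order used everywhere (non-accumulators, early, late, discordant).
STAGE_LABELS <- c("CSF-/PET-", "CSF+/PET-", "CSF+/PET+", "CSF-/PET+")

## The nine node groupings used for connectivity break-ups: seven
## resting-state networks plus basal ganglia and hippocampus/amygdala.
NETWORK_LABELS <- c("DM", "FP", "DA", "VA", "SM", "VI", "FT", "BG", "HI")

#' Two-component Gaussian mixture fit with derived abnormality cut-off
#'
#' Holds the EM-fitted univariate two-component Gaussian mixture used to
#' derive a biomarker abnormality threshold, together with the cut-off
#' itself: the unique point between the two component means at which the
#' posterior probability of membership in either component equals 0.5.
#'
#' @slot weights Numeric(2), mixing proportions (sum to 1), ordered by
#'   increasing component mean.
#' @slot means Numeric(2), component means in biomarker units.
#' @slot sds Numeric(2), positive component standard deviations.
#' @slot cutoff Numeric(1), the posterior-0.5 crossing, strictly between
#'   the component means.
#' @slot loglik Numeric(1), maximised log-likelihood.
#' @slot nIter Integer(1), EM iterations used by the winning restart.
#' @slot converged Logical(1).
#' @slot n Integer(1), number of observations fitted.
#'
#' @seealso [fitMixtureCutoff()]
#' @export
setClass("MixtureFit",
  representation(
    weights = "numeric", means = "numeric", sds = "numeric",
    cutoff = "numeric", loglik = "numeric", nIter = "integer",
    converged = "logical", n = "integer"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (length(object@weights) != 2L || abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must be two proportions summing to 1")
  if (length(object@means) != 2L || is.unsorted(object@means))
    msg <- c(msg, "means must be two values in increasing order")
  if (length(object@sds) != 2L || any(object@sds <= 0))
    msg <- c(msg, "sds must be two positive values")
  if (length(object@cutoff) == 1L && length(object@means) == 2L &&
      !(object@cutoff > object@means[1] && object@cutoff < object@means[2]))
    msg <- c(msg, "cutoff must lie strictly between the component means")
  if (length(msg)) msg else TRUE
})

#' Longitudinal regional SUVR panel
#'
#' A \linkS4class{SummarizedExperiment} with ROIs as rows and subjects as
#' columns, carrying two assays, \code{suvr_baseline} and
#' \code{suvr_followup} (both in SUVR units), and per-subject metadata in
#' \code{colData} including the inter-scan interval in years
#' (\code{interval_years}). Optional \code{rowData} column \code{roi_class}
#' marks ROIs as \code{"early"}, \code{"late"} or \code{"other"} when the
#' panel was simulated.
#'
#' @seealso [roiSuvrPanel()], [annualChange()], [roiContrast()]
#' @export
setClass("RoiSuvrPanel", contains = "SummarizedExperiment")

setValidity("RoiSuvrPanel", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("suvr_baseline", "suvr_followup") %in% an))
    return("assays 'suvr_baseline' and 'suvr_followup' are required")
  b <- SummarizedExperiment::assay(object, "suvr_baseline")
  f <- SummarizedExperiment::assay(object, "suvr_followup")
  if (any(!is.finite(b)) || any(b <= 0) || any(!is.finite(f)) || any(f <= 0))
    msg <- c(msg, "all SUVR values must be finite and > 0")
  cd <- SummarizedExperiment::colData(object)
  if (!"interval_years" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'interval_years'")
  else if (any(!is.finite(cd$interval_years)) || any(cd$interval_years <= 0))
    msg <- c(msg, "interval_years must be finite and > 0")
  if (length(msg)) msg else TRUE
})

#' Per-subject functional-connectivity array
#'
#' Stores one symmetric Fisher-z connectivity matrix per subject as a
#' 3-D array (node x node x subject) with zero diagonals, together with
#' the atlas network label of every node (one of DM, FP, DA, VA, SM, VI,
#' FT, BG, HI) and subject identifiers.
#'
#' @slot z Numeric 3-D array, node x node x subject; symmetric slices,
#'   zero diagonal, finite entries.
#' @slot nodeLabels Character vector, one network label per node.
#' @slot subjectIds Character vector, one id per subject.
#'
#' @seealso [connectivityArray()], [fisherZMatrix()], [permutationTest()]
#' @export
setClass("ConnectivityArray",
  representation(z = "array", nodeLabels = "character",
                 subjectIds = "character")
)

setValidity("ConnectivityArray", function(object) {
  d <- dim(object@z)
  msg <- character()
  if (length(d) != 3L || d[1] != d[2])
    return("z must be a node x node x subject array")
  if (length(object@nodeLabels) != d[1])
    msg <- c(msg, "need one node label per node")
  if (length(object@subjectIds) != d[3])
    msg <- c(msg, "need one subject id per subject")
  if (any(!is.finite(object@z)))
    msg <- c(msg, "z entries must be finite (clip correlations before atanh)")
  ## spot-check symmetry/diagonal on up to 3 slices to keep validity cheap
  idx <- unique(c(1L, d[3] %/% 2L + 1L, d[3]))
  for (s in idx) {
    zi <- object@z[, , s]
    if (max(abs(zi - t(zi))) > 1e-8) {
      msg <- c(msg, "z slices must be symmetric"); break
    }
    if (max(abs(diag(zi))) > 1e-12) {
      msg <- c(msg, "z diagonals must be zero"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Voxelwise statistical map
#'
#' The result of a voxelwise covariate-adjusted two-sample contrast:
#' t statistics and two-sided p values on a 3-D grid, defined inside a
#' boolean mask and NA outside it.
#'
#' @slot t Numeric 3-D array of t statistics (NA outside the mask).
#' @slot p Numeric 3-D array of two-sided p values in [0,1].
#' @slot mask Logical 3-D array.
#' @slot df Numeric(1), residual degrees of freedom.
#'
#' @seealso [adjustedTtestMap()], [extractClusters()]
#' @export
setClass("StatMap",
  representation(t = "array", p = "array", mask = "array", df = "numeric")
)

setValidity("StatMap", function(object) {
  if (!identical(dim(object@t), dim(object@mask)) ||
      !identical(dim(object@p), dim(object@mask)))
    return("t, p and mask must share the same 3-D dimensions")
  inm <- object@mask
  pv <- object@p[inm]
  if (any(!is.finite(object@t[inm])))
    return("t must be finite inside the mask")
  if (any(pv < 0 | pv > 1))
    return("p must lie in [0, 1] inside the mask")
  TRUE
})

#' A supra-threshold voxel cluster
#'
#' A connected set of supra-threshold voxels under the configured
#' neighbourhood. Voxel coordinates are 0-based integer grid indices.
#'
#' @slot voxels Integer matrix, one row per voxel, columns i, j, k
#'   (0-based).
#' @slot size Integer(1), number of voxels.
#' @slot peakT Numeric(1), maximum t statistic within the cluster.
#' @slot peakIjk Integer(3), 0-based location of the peak.
#'
#' @seealso [extractClusters()]
#' @export
setClass("VoxelCluster",
  representation(voxels = "matrix", size = "integer", peakT = "numeric",
                 peakIjk = "integer")
)

setValidity("VoxelCluster", function(object) {
  if (ncol(object@voxels) != 3L) return("voxels must have 3 columns (i,j,k)")
  if (object@size != nrow(object@voxels)) return("size must equal nrow(voxels)")
  if (any(object@voxels < 0L)) return("voxel indices are 0-based, >= 0")
  TRUE
})

#' Connectivity network component with permutation significance
#'
#' A connected set of links (links are adjacent when they share a node)
#' whose link-wise partial Spearman correlations with CSF A-beta-42 all
#' exceed the threshold r0, scored with the composite size statistic
#' S = (sum of link correlations) x (partial Spearman correlation between
#' the per-subject summed component connectivity and CSF), and assigned a
#' family-wise-error-controlling permutation p value.
#'
#' @slot links Data frame with columns \code{i}, \code{j} (node indices,
#'   i < j) and \code{r} (link-wise partial Spearman correlation).
#' @slot direction Character(1), \code{"positive"} or \code{"negative"}.
#' @slot S Numeric(1), composite size statistic.
#' @slot spearmanR Numeric(1), partial Spearman correlation of summed
#'   component connectivity with CSF.
#' @slot p Numeric(1), permutation p value (plus-one estimator).
#' @slot r0 Numeric(1), link-level correlation threshold used.
#' @slot nPerm Integer(1), number of permutations.
#' @slot nullSizes Numeric vector of null |S| draws (one per permutation).
#' @slot nodeLabels Character vector, network label per node of the
#'   parent connectivity array.
#' @slot seed Integer(1), RNG seed used for the permutations.
#'
#' @seealso [permutationTest()], [networkBreakdown()]
#' @export
setClass("NetworkComponent",
  representation(links = "data.frame", direction = "character",
                 S = "numeric", spearmanR = "numeric", p = "numeric",
                 r0 = "numeric", nPerm = "integer", nullSizes = "numeric",
                 nodeLabels = "character", seed = "integer")
)

setValidity("NetworkComponent", function(object) {
  msg <- character()
  if (!all(c("i", "j", "r") %in% colnames(object@links)))
    msg <- c(msg, "links must have columns i, j, r")
  if (!object@direction %in% c("positive", "negative"))
    msg <- c(msg, "direction must be 'positive' or 'negative'")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
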