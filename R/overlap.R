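#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Jaccard coefficient of two element sets
#'
#' Similarity between two sets over a common element space:
#' \code{|intersection| / (|a| + |b| - |intersection|)}. Used to
#' quantify how much a significant accumulation cluster resembles a
#' functional-network mask.
#'
#' @param a,b Vectors of element identifiers (e.g. linear voxel
#'   indices); duplicates are ignored.
#' @return Proportion in [0, 1].
#'
#' @examples
#' jaccard(1:100, 51:150)   # 50 / 150
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L)
    stop("jaccard is undefined for two empty sets", call. = FALSE)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Distribution of a cluster's overlap across atlas networks
#'
#' Intersects a cluster (element set) with every network mask of an
#' atlas labelling and reports, per network: the overlap element count,
#' the percentage of the total labelled overlap (the percentages sum to
#' 100), and the Jaccard coefficient between the cluster and the full
#' network mask. Elements falling outside every network label are
#' excluded from the percentage denominator and reported via the
#' \code{"excluded"} attribute.
#'
#' @param cluster Vector of element identifiers, or a
#'   \linkS4class{VoxelCluster} (converted to linear indices via
#'   \code{atlasDim}).
#' @param labels Integer/character vector or 3-D array assigning each
#'   element of the atlas space a network label (0 or NA = unlabelled).
#' @param legend Named character vector mapping label values to network
#'   names; by default labels are used verbatim.
#' @param atlasDim Grid dimensions, required when \code{cluster} is a
#'   \linkS4class{VoxelCluster}.
#' @return Data frame (network, count, percent, jaccard) sorted by
#'   decreasing count, with attribute \code{"excluded"}.
#'
#' @export
overlapDistribution <- function(cluster, labels, legend = NULL,
                                atlasDim = NULL) {
  if (is(cluster, "VoxelCluster")) {
    if (is.null(atlasDim)) atlasDim <- dim(labels)
    if (is.null(atlasDim))
      stop("'atlasDim' is required to convert voxel coordinates",
           call. = FALSE)
    vox <- clusterVoxels(cluster) + 1L
    cluster <- vox[, 1] + atlasDim[1] * (vox[, 2] - 1L) +
      atlasDim[1] * atlasDim[2] * (vox[, 3] - 1L)
  }
  labVec <- as.vector(labels)
  cluster <- unique(cluster)
  if (any(cluster < 1L | cluster > length(labVec)))
    stop("cluster elements fall outside the atlas space", call. = FALSE)

  lab <- labVec
  lab[lab %in% c(0, "0")] <- NA
  if (!is.null(legend)) {
    lab <- unname(legend[as.character(lab)])
  } else {
    lab <- as.character(lab)
  }
  networks <- sort(unique(lab[!is.na(lab)]))
  if (!length(networks))
    stop("the atlas labelling contains no networks", call. = FALSE)

  clLab <- lab[cluster]
  excluded <- sum(is.na(clLab))
  inside <- cluster[!is.na(clLab)]
  if (!length(inside))
    stop("cluster lies entirely outside all network labels", call. = FALSE)

  counts <- vapply(networks, function(nw) sum(lab[inside] == nw), numeric(1))
  jc <- vapply(networks, function(nw)
    jaccard(cluster, which(!is.na(lab) & lab == nw)), numeric(1))
  out <- data.frame(network = networks, count = as.integer(counts),
                    percent = 100 * counts / sum(counts), jaccard = jc,
                    row.names = NULL)
  out <- out[order(-out$count, out$network), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- as.integer(excluded)
  out
}
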