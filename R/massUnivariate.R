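#' @include AllClasses.R AllGenerics.R utils.R
NULL

## normalize grids input to an x*y*z*subject array
.gridsToArray <- function(grids) {
  if (is.list(grids)) {
    dims <- unique(lapply(grids, dim))
    if (length(dims) != 1L || length(dims[[1]]) != 3L)
      stop("all grids must be 3-D arrays with a common shape", call. = FALSE)
    arr <- array(unlist(grids, use.names = FALSE),
                 dim = c(dims[[1]], length(grids)))
  } else {
    if (length(dim(grids)) != 4L)
      stop("'grids' must be a 4-D array (x, y, z, subject) or a list of ",
           "3-D arrays", call. = FALSE)
    arr <- grids
  }
  arr
}

#' Voxelwise covariate-adjusted two-sample t-map
#'
#' At every voxel inside the mask, fits the ordinary least-squares model
#' \code{value ~ group + covariates} across subjects and returns the t
#' statistic and two-sided p value on the group coefficient (the
#' contrast \code{group2 - group1}). With no covariates this reduces to
#' the pooled-variance two-sample t-test.
#'
#' @param grids 4-D array (x, y, z, subject) or list of per-subject 3-D
#'   arrays with a common shape.
#' @param groups Two-level factor or vector, one entry per subject.
#' @param covariates Optional data frame of per-subject covariates.
#' @param mask Logical 3-D array; defaults to all voxels.
#' @return A \linkS4class{StatMap}.
#'
#' @export
adjustedTtestMap <- function(grids, groups, covariates = NULL, mask = NULL) {
  arr <- .gridsToArray(grids)
  d <- dim(arr)[1:3]
  nSubj <- dim(arr)[4]
  groups <- as.factor(groups)
  if (length(groups) != nSubj)
    stop("'groups' must have one entry per subject", call. = FALSE)
  if (nlevels(droplevels(groups)) != 2L)
    stop("'groups' must have exactly two levels", call. = FALSE)
  groups <- droplevels(groups)
  if (min(table(groups)) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  if (!identical(dim(mask), d))
    stop("shape mismatch between 'mask' and the grids", call. = FALSE)

  g <- as.numeric(groups == levels(groups)[2])
  X <- cbind(1, g, .covarMatrix(covariates, nSubj))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design (collinear covariates)", call. = FALSE)
  df <- nSubj - ncol(X)

  V <- matrix(arr, nrow = prod(d), ncol = nSubj)[as.vector(mask), ,
                                                 drop = FALSE]
  Y <- t(V)                                    # subject x voxel
  beta <- qr.coef(qrX, Y)[2L, ]
  res <- qr.resid(qrX, Y)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  tval <- beta / sqrt(sigma2 * XtXinv[2L, 2L])
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)

  tArr <- array(NA_real_, dim = d)
  pArr <- array(NA_real_, dim = d)
  tArr[mask] <- tval
  pArr[mask] <- pval
  new("StatMap", t = tArr, p = pArr, mask = mask, df = as.numeric(df))
}

## 3-D neighbourhood offsets for 6 / 18 / 26 connectivity
.neighborOffsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1L,
                 "18" = nz >= 1L & nz <= 2L,
                 "26" = nz >= 1L)
  off[keep, , drop = FALSE]
}

## label connected components of a logical 3-D array; returns integer
## array (0 = background) using breadth-first search over the offsets
.labelComponents <- function(supra, connectivity) {
  d <- dim(supra)
  off <- .neighborOffsets(connectivity)
  labels <- array(0L, dim = d)
  idx <- which(supra, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(labels)
  nextLab <- 0L
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    nextLab <- nextLab + 1L
    queue <- matrix(v, ncol = 3L)
    labels[v[1], v[2], v[3]] <- nextLab
    while (nrow(queue)) {
      cur <- queue[1L, ]
      queue <- queue[-1L, , drop = FALSE]
      nb <- sweep(off, 2L, cur, "+")
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
            nb[, 2] >= 1L & nb[, 2] <= d[2] &
            nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      take <- supra[lin] & labels[lin] == 0L
      if (any(take)) {
        labels[lin[take]] <- nextLab
        queue <- rbind(queue, nb[take, , drop = FALSE])
      }
    }
  }
  labels
}

#' Extract supra-threshold clusters from a statistical map
#'
#' Thresholds the map at an uncorrected voxel-level height
#' (\code{p < pHeight} in the requested contrast direction), labels
#' connected components under the chosen 3-D neighbourhood, and keeps
#' components strictly larger than \code{kMin} voxels. Clusters are
#' returned in a deterministic order: decreasing size, ties broken by
#' decreasing peak t.
#'
#' @param map A \linkS4class{StatMap}.
#' @param pHeight Voxel-level height threshold in (0, 1), default 0.001.
#' @param kMin Cluster-extent threshold: components must have more than
#'   \code{kMin} voxels (strict), default 100.
#' @param connectivity Neighbourhood: 6, 18 or 26 (default 26).
#' @param direction \code{"positive"} (t > 0), \code{"negative"}
#'   (t < 0) or \code{"both"}.
#' @return List of \linkS4class{VoxelCluster} objects (possibly empty).
#'   Voxel coordinates are 0-based.
#'
#' @export
extractClusters <- function(map, pHeight = 0.001, kMin = 100L,
                            connectivity = 26L,
                            direction = c("positive", "negative", "both")) {
  stopifnot(is(map, "StatMap"))
  .assertNumber(pHeight, "pHeight", lower = 0, upper = 1, strict = TRUE)
  kMin <- .assertCount(kMin, "kMin")
  direction <- match.arg(direction)

  tArr <- tMap(map)
  supra <- maskArray(map) & !is.na(pMap(map)) & pMap(map) < pHeight
  supra[is.na(supra)] <- FALSE
  if (direction != "both") {
    dirOk <- if (direction == "positive") tArr > 0 else tArr < 0
    dirOk[is.na(dirOk)] <- FALSE
    supra <- supra & dirOk
  }

  labels <- .labelComponents(supra, as.integer(connectivity))
  nLab <- max(labels)
  if (nLab == 0L) return(list())
  out <- list()
  for (lab in seq_len(nLab)) {
    vox <- which(labels == lab, arr.ind = TRUE)
    if (nrow(vox) <= kMin) next
    tv <- tArr[vox]
    pk <- which.max(abs(tv))
    out[[length(out) + 1L]] <- new("VoxelCluster",
      voxels = unname(vox) - 1L, size = nrow(vox), peakT = tv[pk],
      peakIjk = as.integer(vox[pk, ] - 1L))
  }
  if (!length(out)) return(list())
  ord <- order(-vapply(out, clusterSize, integer(1)),
               -vapply(out, function(cl) abs(cl@peakT), numeric(1)))
  out[ord]
}

#' Integer label map from a cluster list
#'
#' @param clusters List of \linkS4class{VoxelCluster} objects.
#' @param dim Integer(3) grid dimensions.
#' @return Integer 3-D array, 0 background, cluster id elsewhere
#'   (ids follow the list order).
#' @export
clusterLabelArray <- function(clusters, dim) {
  lab <- array(0L, dim = dim)
  for (k in seq_along(clusters)) {
    vox <- clusterVoxels(clusters[[k]]) + 1L
    lab[vox] <- k
  }
  lab
}

#' Cluster summary table
#'
#' @param clusters List of \linkS4class{VoxelCluster} objects.
#' @return Data frame with id, size, peak t and 0-based peak coordinates.
#' @export
clusterTable <- function(clusters) {
  data.frame(
    id = seq_along(clusters),
    size = vapply(clusters, clusterSize, integer(1)),
    peak_t = vapply(clusters, function(cl) cl@peakT, numeric(1)),
    peak_i = vapply(clusters, function(cl) cl@peakIjk[1], integer(1)),
    peak_j = vapply(clusters, function(cl) cl@peakIjk[2], integer(1)),
    peak_k = vapply(clusters, function(cl) cl@peakIjk[3], integer(1))
  )
}
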