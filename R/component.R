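#' @include AllClasses.R AllGenerics.R utils.R
NULL

## upper-triangle link index (i < j), fixed column-major order shared by
## every function that flattens a connectivity matrix into a link vector
.linkIndex <- function(nNodes) {
  which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
}

## subjects x links matrix of z values
.subjectLinkMatrix <- function(z) {
  n <- dim(z)[1]
  ut <- which(upper.tri(matrix(0, n, n)))
  t(matrix(z, n * n, dim(z)[3])[ut, , drop = FALSE])
}

#' Construct a per-subject connectivity array
#'
#' @param z List of symmetric node x node Fisher-z matrices (one per
#'   subject) or a node x node x subject array.
#' @param nodeLabels Character vector of network labels, one per node
#'   (levels among DM, FP, DA, VA, SM, VI, FT, BG, HI).
#' @param subjectIds Optional subject identifiers.
#' @return A \linkS4class{ConnectivityArray}.
#' @export
connectivityArray <- function(z, nodeLabels, subjectIds = NULL) {
  if (is.list(z)) {
    d <- unique(lapply(z, dim))
    if (length(d) != 1L)
      stop("all connectivity matrices must share dimensions", call. = FALSE)
    z <- array(unlist(z, use.names = FALSE), dim = c(d[[1]], length(z)))
  }
  if (is.null(subjectIds)) subjectIds <- paste0("S", seq_len(dim(z)[3]))
  new("ConnectivityArray", z = z, nodeLabels = as.character(nodeLabels),
      subjectIds = as.character(subjectIds))
}

#' Fisher-z connectivity matrix from node time series
#'
#' Pairwise Pearson correlation between node time series, clipped to
#' \code{|r| <= 1 - 1e-7} so the Fisher transform stays finite, then
#' z = atanh(r). The diagonal is zero.
#'
#' @param timeseries Numeric node x time matrix (>= 2 nodes, >= 3
#'   timepoints).
#' @return Symmetric node x node matrix of Fisher-z values.
#'
#' @export
fisherZMatrix <- function(timeseries) {
  if (!is.matrix(timeseries) || nrow(timeseries) < 2L ||
      ncol(timeseries) < 3L)
    stop("'timeseries' must be a node x time matrix with >= 2 nodes and ",
         ">= 3 timepoints", call. = FALSE)
  sds <- apply(timeseries, 1L, sd)
  if (any(sds == 0))
    stop("constant time series at node(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  r <- cor(t(timeseries))
  clip <- 1 - 1e-7
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Partial Spearman correlation
#'
#' Rank-transforms \code{x} and \code{y} (average ranks for ties),
#' residualises both rank vectors on the covariates (plus an intercept)
#' by least squares, and returns the Pearson correlation of the
#' residuals. With no covariates this is the ordinary Spearman rho.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covars Optional data frame / matrix of covariates.
#' @return Correlation in [-1, 1].
#'
#' @export
partialSpearman <- function(x, y, covars = NULL) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length",
                           call. = FALSE)
  covMat <- .covarMatrix(covars, n)
  if (n < ncol(covMat) + 3L)
    stop("too few observations for the requested adjustment", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero variance after ranking (all values tied)", call. = FALSE)
  qrX <- qr(cbind(1, covMat))
  ex <- qr.resid(qrX, rx)
  ey <- qr.resid(qrX, ry)
  if (sum(ex^2) == 0 || sum(ey^2) == 0)
    stop("zero residual variance after adjustment", call. = FALSE)
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

#' Link-level correlation threshold from a significance level
#'
#' Inverts the t approximation of the null correlation distribution,
#' \code{t = r sqrt(df / (1 - r^2))} with \code{df = n - 2 -
#' nCovariates}, at the two-sided \code{alpha} quantile: the |r| a link
#' must exceed for its subject-wise correlation with CSF to be
#' significant at \code{alpha}.
#'
#' @param n Number of subjects (>= 5).
#' @param alpha Two-sided significance level in (0, 1), default 0.001.
#' @param nCovariates Number of covariates partialled out (reduces the
#'   degrees of freedom), default 0.
#' @return Threshold r0 in (0, 1).
#'
#' @export
r0FromAlpha <- function(n, alpha = 0.001, nCovariates = 0L) {
  n <- .assertCount(n, "n", min = 5L)
  .assertNumber(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  nCovariates <- .assertCount(nCovariates, "nCovariates", min = 0L)
  df <- n - 2L - nCovariates
  if (df < 3L)
    stop(sprintf("n = %d is too small for alpha = %g with %d covariates",
                 n, alpha, nCovariates), call. = FALSE)
  tcrit <- qt(1 - alpha / 2, df)
  tcrit / sqrt(df + tcrit^2)
}

#' Link-wise partial Spearman correlation field
#'
#' For every link (i, j), i < j, computes the partial Spearman
#' correlation across subjects between CSF A-beta-42 and the link's
#' Fisher-z connectivity, adjusted for the covariates. Links with
#' constant connectivity across subjects get r = 0.
#'
#' @param conn A \linkS4class{ConnectivityArray}.
#' @param csf Per-subject CSF values.
#' @param covars Optional per-subject covariate data frame.
#' @return Data frame (i, j, r) over the upper triangle, with
#'   attributes \code{"n"} and \code{"nCovariates"}.
#'
#' @export
linkCorrelations <- function(conn, csf, covars = NULL) {
  stopifnot(is(conn, "ConnectivityArray"))
  z <- connValues(conn)
  n <- dim(z)[3]
  if (length(csf) != n)
    stop("'csf' must have one value per subject", call. = FALSE)
  covMat <- .covarMatrix(covars, n)
  qrX <- qr(cbind(1, covMat))
  Z <- .subjectLinkMatrix(z)
  Rz <- .residUnit(.rankColumns(Z), qrX)
  u <- .residUnit(matrix(rank(csf), ncol = 1L), qrX)[, 1L]
  r <- as.vector(crossprod(Rz, u))
  r[!is.finite(r)] <- 0
  idx <- .linkIndex(dim(z)[1])
  out <- data.frame(i = idx[, 1], j = idx[, 2], r = r)
  attr(out, "n") <- n
  attr(out, "nCovariates") <- ncol(covMat)
  out
}

## connected components of a link set via union-find over nodes; links
## are rows of a data.frame with i, j (and r). Returns list of
## data.frames ordered by link count desc, then sum |r| desc.
.linkComponents <- function(links) {
  if (!nrow(links)) return(list())
  nodes <- sort(unique(c(links$i, links$j)))
  pairs <- cbind(match(links$i, nodes), match(links$j, nodes))
  root <- .unionFind(length(nodes), pairs)
  comp <- root[pairs[, 1L]]
  groups <- split(seq_len(nrow(links)), comp)
  out <- lapply(groups, function(ix) links[ix, , drop = FALSE])
  cnt <- vapply(out, nrow, integer(1))
  sar <- vapply(out, function(d) sum(abs(d$r)), numeric(1))
  out[order(-cnt, -sar)]
}

#' Extract connected link components above a correlation threshold
#'
#' Keeps links whose correlation exceeds the threshold in the requested
#' direction (\code{r > r0} for positive, \code{r < -r0} for negative)
#' and partitions them into connected components: links belong to the
#' same component when they can be joined through shared nodes.
#' Components are ordered by decreasing link count, ties broken by
#' decreasing sum of |r|.
#'
#' @param field Link correlation field from [linkCorrelations()] (data
#'   frame with columns i, j, r).
#' @param r0 Positive correlation threshold.
#' @param direction \code{"positive"} or \code{"negative"}.
#' @return List of data frames (i, j, r), possibly empty.
#'
#' @export
extractComponents <- function(field, r0,
                              direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  .assertNumber(r0, "r0", lower = 0, strict = TRUE, upper = 1)
  keep <- if (direction == "positive") field$r > r0 else field$r < -r0
  .linkComponents(field[keep, , drop = FALSE])
}

#' Composite size statistic of a link component
#'
#' \code{S = (sum of link correlations r_ij over the component) x
#' (partial Spearman correlation between the per-subject sum of the
#' component's z values and CSF)}. An empty component has S = 0 by
#' convention.
#'
#' @param C Component: data frame with columns i, j and r (as returned
#'   by [extractComponents()]).
#' @param conn The parent \linkS4class{ConnectivityArray}.
#' @param csf Per-subject CSF values.
#' @param covars Optional covariates, as in [partialSpearman()].
#' @return The statistic S (dimensionless).
#'
#' @export
componentSize <- function(C, conn, csf, covars = NULL) {
  if (is.null(C) || nrow(C) == 0L) return(0)
  stopifnot(is(conn, "ConnectivityArray"))
  z <- connValues(conn)
  nn <- dim(z)[1]
  if (any(C$i < 1L | C$i > nn | C$j < 1L | C$j > nn))
    stop("component link references a node absent from the connectivity ",
         "array", call. = FALSE)
  sumz <- vapply(seq_len(dim(z)[3]), function(s)
    sum(z[cbind(C$i, C$j, s)]), numeric(1))
  sum(C$r) * partialSpearman(sumz, csf, covars)
}

## S of every component in a list under a fixed residualising design;
## sumz is computed on raw z, its ranks residualised through qrX and
## correlated with the (already residualised, unit-norm) csf vector
.componentStats <- function(comps, Z, idxMap, uCsf, qrX) {
  vapply(comps, function(C) {
    lk <- idxMap[cbind(C$i, C$j)]
    sumz <- if (length(lk) == 1L) Z[, lk] else rowSums(Z[, lk, drop = FALSE])
    ez <- qr.resid(qrX, rank(sumz))
    nz <- sqrt(sum(ez^2))
    if (nz == 0) return(0)
    sum(C$r) * sum(ez * uCsf) / nz
  }, numeric(1))
}

#' Permutation test for CSF-connectivity network components
#'
#' The full network-component pipeline with family-wise error control in
#' the weak sense: compute the link-wise partial Spearman correlation
#' field between connectivity and CSF A-beta-42, threshold it at the r0
#' corresponding to a link-level two-sided \code{alphaLink} (default
#' 0.001), extract connected link components, take the largest, and
#' score it with the composite size statistic S. The observed |S| is
#' compared against a null distribution built by randomly permuting the
#' subject-to-CSF assignment (connectivity and covariates stay with
#' their subjects) and re-running the identical pipeline, recording the
#' maximal |S| per permutation (0 when no supra-threshold component
#' exists). The p value uses the plus-one estimator
#' \code{(1 + #(null >= observed)) / (1 + nPerm)}.
#'
#' Positive and negative link directions are searched in separate runs;
#' the null is built within the chosen direction.
#'
#' @param conn A \linkS4class{ConnectivityArray} (>= 10 subjects).
#' @param csf Per-subject CSF A-beta-42 values.
#' @param covars Optional per-subject covariates (e.g. age, sex, APOE),
#'   partialled out of both sides of every correlation and held fixed
#'   under permutation.
#' @param alphaLink Link-level two-sided significance level defining r0
#'   (default 0.001).
#' @param nPerm Number of permutations (>= 100; default 1000).
#' @param seed RNG seed (required).
#' @param direction \code{"positive"} or \code{"negative"}.
#' @param permMode Null-construction scheme: \code{"simple"} permutes
#'   the raw CSF ranks (exact under the complete null);
#'   \code{"freedman_lane"} permutes the covariate-adjusted residuals
#'   of the CSF ranks instead, which is preferable when covariates are
#'   strongly associated with CSF.
#' @return A \linkS4class{NetworkComponent}; empty component with p = 1
#'   when no supra-threshold link exists.
#'
#' @export
permutationTest <- function(conn, csf, covars = NULL, alphaLink = 0.001,
                            nPerm = 1000L, seed = 1L,
                            direction = c("positive", "negative"),
                            permMode = c("simple", "freedman_lane")) {
  stopifnot(is(conn, "ConnectivityArray"))
  direction <- match.arg(direction)
  permMode <- match.arg(permMode)
  z <- connValues(conn)
  n <- dim(z)[3]
  if (n < 10L) stop("need at least 10 subjects", call. = FALSE)
  nPerm <- .assertCount(nPerm, "nPerm", min = 100L)
  seed <- .assertSeed(seed)
  if (length(csf) != n)
    stop("'csf' must have one value per subject", call. = FALSE)

  covMat <- .covarMatrix(covars, n)
  qrX <- qr(cbind(1, covMat))
  r0 <- r0FromAlpha(n, alphaLink, ncol(covMat))

  Z <- .subjectLinkMatrix(z)
  Rz <- .residUnit(.rankColumns(Z), qrX)
  badLink <- !is.finite(colSums(Rz))
  Rz[, badLink] <- 0
  idx <- .linkIndex(dim(z)[1])
  idxMap <- matrix(NA_integer_, dim(z)[1], dim(z)[1])
  idxMap[idx] <- seq_len(nrow(idx))

  rcsf <- rank(csf)
  fieldFrom <- function(u) {
    r <- as.vector(crossprod(Rz, u))
    r[!is.finite(r)] <- 0
    data.frame(i = idx[, 1], j = idx[, 2], r = r)
  }
  largestAbsS <- function(u) {
    field <- fieldFrom(u)
    keep <- if (direction == "positive") field$r > r0 else field$r < -r0
    comps <- .linkComponents(field[keep, , drop = FALSE])
    if (!length(comps))
      return(list(comps = comps, S = numeric(0), maxAbs = 0))
    S <- .componentStats(comps, Z, idxMap, u, qrX)
    list(comps = comps, S = S, maxAbs = max(abs(S)))
  }

  uObs <- .residUnit(matrix(rcsf, ncol = 1L), qrX)[, 1L]
  obs <- largestAbsS(uObs)

  if (!length(obs$comps)) {
    return(new("NetworkComponent",
               links = data.frame(i = integer(0), j = integer(0),
                                  r = numeric(0)),
               direction = direction, S = 0, spearmanR = NA_real_, p = 1,
               r0 = r0, nPerm = nPerm, nullSizes = numeric(0),
               nodeLabels = nodeLabels(conn), seed = seed))
  }
  largest <- obs$comps[[1L]]
  Sobs <- obs$S[1L]
  spearmanR <- Sobs / sum(largest$r)

  set.seed(seed)
  eObs <- qr.resid(qrX, rcsf)
  nullSizes <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    perm <- sample.int(n)
    base <- if (permMode == "simple") rcsf[perm] else eObs[perm]
    ub <- qr.resid(qrX, base)
    ub <- ub / sqrt(sum(ub^2))
    nullSizes[b] <- largestAbsS(ub)$maxAbs
  }
  p <- (1 + sum(nullSizes >= abs(Sobs))) / (1 + nPerm)

  new("NetworkComponent", links = largest, direction = direction,
      S = Sobs, spearmanR = spearmanR, p = p, r0 = r0, nPerm = nPerm,
      nullSizes = nullSizes, nodeLabels = nodeLabels(conn),
      seed = seed)
}

#' Break a link component down by network pair
#'
#' Counts a component's links per unordered pair of atlas networks
#' (intra-network pairs included); the counts sum to the component's
#' link count.
#'
#' @param x A \linkS4class{NetworkComponent}, or a data frame of links
#'   (columns i, j) combined with \code{labels}.
#' @param labels Character vector of node network labels (taken from the
#'   component when \code{x} is a \linkS4class{NetworkComponent}).
#' @return Data frame (network_a, network_b, count) sorted by
#'   decreasing count.
#'
#' @export
networkBreakdown <- function(x, labels = NULL) {
  if (is(x, "NetworkComponent")) {
    if (is.null(labels)) labels <- nodeLabels(x)
    links <- componentLinks(x)
  } else {
    links <- x
  }
  if (is.null(labels))
    stop("node 'labels' are required", call. = FALSE)
  if (!nrow(links))
    return(data.frame(network_a = character(0), network_b = character(0),
                      count = integer(0)))
  nodes <- c(links$i, links$j)
  if (any(nodes < 1L | nodes > length(labels)) ||
      any(is.na(labels[nodes])))
    stop("unlabelled node in component", call. = FALSE)
  la <- labels[links$i]
  lb <- labels[links$j]
  pair <- ifelse(la <= lb, paste(la, lb, sep = "-"),
                 paste(lb, la, sep = "-"))
  tab <- sort(table(pair), decreasing = TRUE)
  parts <- strsplit(names(tab), "-", fixed = TRUE)
  data.frame(network_a = vapply(parts, `[`, "", 1L),
             network_b = vapply(parts, `[`, "", 2L),
             count = as.integer(tab), row.names = NULL)
}
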