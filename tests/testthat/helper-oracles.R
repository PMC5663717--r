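# Independent oracles used to cross-check the package's own algorithms.
# Each is deliberately implemented with a different algorithm (or a
# different library) than the code path it checks.

# Connected-component labelling of a logical 3-D field by iterative
# minimum-label propagation (vs the package's breadth-first search).
floodFillOracle <- function(supra, connectivity = 26L) {
  d <- dim(supra)
  lab <- array(0, dim = d)
  lab[supra] <- seq_len(sum(supra))
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = nz == 1, "18" = nz >= 1 & nz <= 2, nz >= 1), ,
             drop = FALSE]
  shift <- function(a, o, fill) {
    src <- lapply(1:3, function(ax) {
      ix <- seq_len(d[ax]) - o[ax]
      ix[ix < 1L | ix > d[ax]] <- NA
      ix
    })
    out <- a[src[[1]], src[[2]], src[[3]], drop = FALSE]
    out[is.na(out)] <- fill
    array(out, dim = d)
  }
  repeat {
    nxt <- lab
    for (r in seq_len(nrow(off))) {
      sh <- shift(lab, off[r, ], Inf)
      sh[sh == 0] <- Inf
      upd <- supra & sh < nxt
      nxt[upd] <- sh[upd]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab[!supra] <- 0
  lab
}

# Canonical signature of a voxel-set partition: sorted list of sorted
# linear indices, for order-independent comparison.
partitionSignature <- function(groups) {
  sig <- unname(lapply(groups, function(g) unname(sort(g))))
  sig[order(sapply(sig, `[`, 1L))]
}

# Link-graph connected components via igraph (vs the package union-find).
igraphLinkComponents <- function(links, nNodes) {
  g <- igraph::graph_from_edgelist(as.matrix(links[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nNodes - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  split(seq_len(nrow(links)), memb[links$i])
}

# Link-graph connected components by recursive depth-first search over
# the link adjacency relation (links adjacent iff they share a node).
dfsLinkComponents <- function(links) {
  m <- nrow(links)
  if (!m) return(list())
  adj <- outer(seq_len(m), seq_len(m), function(a, b)
    links$i[a] == links$i[b] | links$i[a] == links$j[b] |
      links$j[a] == links$i[b] | links$j[a] == links$j[b])
  seen <- rep(FALSE, m)
  out <- list()
  for (s in seq_len(m)) {
    if (seen[s]) next
    stack <- s
    comp <- integer(0)
    while (length(stack)) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, which(adj[v, ] & !seen))
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

# Textbook Spearman rho for untied data: 1 - 6 sum(d^2) / (n (n^2 - 1)).
spearmanRankFormula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exact one-sided Mann-Whitney p by full enumeration of group
# assignments (no ties): P(W <= observed) under the null.
mwEnumPvalue <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  wStat <- function(xi, yi) sum(outer(xi, yi, ">"))
  obs <- wStat(x, y)
  sets <- utils::combn(length(pooled), n1)
  ws <- apply(sets, 2L, function(ix) wStat(pooled[ix], pooled[-ix]))
  mean(ws <= obs)
}

# Hand-executed Benjamini-Hochberg step-up (vs stats::p.adjust wrapper).
bhStepUpOracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  flags <- rep(FALSE, m)
  if (length(k)) flags[o[seq_len(max(k))]] <- TRUE
  flags
}

# A tiny 2-node connectivity array whose single link has the given
# per-subject z values.
oneLinkConn <- function(z12) {
  n <- length(z12)
  z <- array(0, dim = c(2, 2, n))
  z[1, 2, ] <- z12
  z[2, 1, ] <- z12
  connectivityArray(z, c("DM", "FP"))
}
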