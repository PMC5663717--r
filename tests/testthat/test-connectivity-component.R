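test_that("Fisher-z matrices are symmetric, clipped and sign-correct", {
  set.seed(51)
  ts <- matrix(rnorm(5 * 60), 5, 60)
  ts[2, ] <- ts[1, ]          # identical pair
  ts[3, ] <- -ts[1, ]         # perfectly anti-correlated pair
  z <- fisherZMatrix(ts)
  expect_true(isSymmetric(z))
  expect_equal(diag(z), rep(0, 5))
  expect_true(all(is.finite(z)))
  expect_gt(z[1, 2], 8)
  expect_lt(z[1, 3], -8)

  tsc <- ts; tsc[4, ] <- 2
  expect_error(fisherZMatrix(tsc), "node\\(s\\): 4")
  expect_error(fisherZMatrix(matrix(1:4, 2, 2)), "3 timepoints")
})

test_that("independent time series give near-zero links", {
  set.seed(52)
  z <- fisherZMatrix(matrix(rnorm(20 * 500), 20, 500))
  offdiag <- z[upper.tri(z)]
  expect_gte(mean(abs(offdiag) < 0.2), 0.95)
})

test_that("partial Spearman reduces to the textbook formula", {
  expect_equal(partialSpearman(1:10, (1:10)^3), 1.0)
  set.seed(53)
  for (r in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    expect_equal(partialSpearman(x, y), spearmanRankFormula(x, y),
                 tolerance = 1e-12)
    expect_equal(partialSpearman(x, y),
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  expect_error(partialSpearman(rep(1, 10), 1:10), "tied")
})

test_that("partialling out a shared covariate removes induced correlation", {
  set.seed(54)
  hits <- replicate(20, {
    c0 <- rnorm(100)
    x <- c0 + rnorm(100, 0, 0.4)
    y <- c0 + rnorm(100, 0, 0.4)
    abs(partialSpearman(x, y, covars = data.frame(c = c0))) < 0.3
  })
  expect_gte(mean(hits), 0.9)
  # unadjusted correlation is, by construction, strong
  c0 <- rnorm(100)
  expect_gt(partialSpearman(c0 + rnorm(100, 0, 0.3),
                            c0 + rnorm(100, 0, 0.3)), 0.5)
})

test_that("the r0 threshold behaves like the t-approximation quantile", {
  expect_lt(r0FromAlpha(100, 0.9999), 0.01)
  expect_gt(r0FromAlpha(50, 0.001), r0FromAlpha(500, 0.001))
  expect_gt(r0FromAlpha(60, 0.001, nCovariates = 3),
            r0FromAlpha(60, 0.001))
  expect_error(r0FromAlpha(6, 0.001, nCovariates = 3), "too small")
  # closed form round-trip: t = r sqrt(df / (1 - r^2)) hits the quantile
  r0 <- r0FromAlpha(103, 0.001)
  tt <- r0 * sqrt(101 / (1 - r0^2))
  expect_equal(2 * pt(tt, 101, lower.tail = FALSE), 0.001,
               tolerance = 1e-10)
})

test_that("r0 matches the Monte-Carlo null Spearman quantile at n = 103", {
  n <- 103L
  set.seed(64)
  x <- seq_len(n)
  xc <- scale(x)[, 1]
  nulls <- replicate(20000, {
    yc <- scale(sample(n))[, 1]
    sum(xc * yc) / (n - 1)
  })
  mcQuantile <- quantile(abs(nulls), 0.999, names = FALSE)
  expect_lt(abs(r0FromAlpha(n, 0.001) - mcQuantile), 0.02)
})

test_that("link components match shared-node intuition and igraph", {
  field <- data.frame(i = c(1L, 2L, 4L), j = c(2L, 3L, 5L),
                      r = c(0.6, 0.7, 0.8))
  comps <- extractComponents(field, r0 = 0.5)
  expect_length(comps, 2L)
  expect_equal(nrow(comps[[1]]), 2L)     # (1-2, 2-3) share node 2
  expect_equal(nrow(comps[[2]]), 1L)

  set.seed(55)
  for (trial in 1:30) {
    n <- 30L
    idx <- t(combn(n, 2))
    r <- runif(nrow(idx), -1, 1)
    field <- data.frame(i = idx[, 1], j = idx[, 2], r = r)
    r0 <- runif(1, 0.5, 0.95)
    for (dir in c("positive", "negative")) {
      comps <- extractComponents(field, r0, dir)
      kept <- field[if (dir == "positive") field$r > r0 else field$r < -r0, ]
      if (!nrow(kept)) {
        expect_length(comps, 0L)
        next
      }
      mine <- partitionSignature(lapply(comps, function(cc)
        paste(cc$i, cc$j)))
      oracle <- partitionSignature(lapply(
        igraphLinkComponents(kept, n),
        function(ix) paste(kept$i[ix], kept$j[ix])))
      expect_identical(mine, oracle)
    }
  }
})

test_that("component ordering is by link count then summed |r|", {
  field <- data.frame(i = c(1L, 2L, 5L, 6L, 8L, 9L),
                      j = c(2L, 3L, 6L, 7L, 9L, 10L),
                      r = c(0.6, 0.6, 0.9, 0.9, 0.7, 0.7))
  comps <- extractComponents(field, r0 = 0.5)
  expect_length(comps, 3L)
  expect_equal(sum(comps[[1]]$r), 1.8)   # size tie broken by sum |r|
  expect_equal(sum(comps[[3]]$r), 1.2)
})

test_that("the composite size statistic multiplies its two factors", {
  # single link whose z ranks correlate with csf at exactly rho = 0.5
  z12 <- c(2, 4, 1, 3, 5) / 10
  conn <- oneLinkConn(z12)
  csf <- c(10, 20, 30, 40, 50)
  field <- linkCorrelations(conn, csf)
  expect_equal(field$r, 0.5, tolerance = 1e-12)
  comps <- extractComponents(field, r0 = 0.3)
  S <- componentSize(comps[[1]], conn, csf)
  expect_equal(S, 0.25, tolerance = 1e-12)

  expect_equal(componentSize(data.frame(i = integer(0), j = integer(0),
                                        r = numeric(0)),
                             conn, csf), 0)
  bad <- data.frame(i = 1L, j = 7L, r = 0.5)
  expect_error(componentSize(bad, conn, csf), "absent")
})

test_that("a three-link component matches the step-by-step hand formula", {
  set.seed(56)
  n <- 8L
  z <- array(0, dim = c(4, 4, n))
  links <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  for (s in seq_len(n)) {
    m <- matrix(0, 4, 4)
    m[links] <- rnorm(3, 0.5, 0.3)
    z[, , s] <- m + t(m)
  }
  conn <- connectivityArray(z, c("DM", "DM", "FP", "FP"))
  csf <- rnorm(n, 500, 100)
  field <- linkCorrelations(conn, csf)
  C <- data.frame(i = links[, 1], j = links[, 2],
                  r = field$r[match(paste(links[, 1], links[, 2]),
                                    paste(field$i, field$j))])
  # hand execution: per-link Spearman, summed; then Spearman of summed z
  rHand <- vapply(seq_len(3), function(k)
    cor(z[links[k, 1], links[k, 2], ], csf, method = "spearman"),
    numeric(1))
  expect_equal(C$r, rHand, tolerance = 1e-12)
  sumz <- vapply(seq_len(n), function(s) sum(z[cbind(links, s)]), numeric(1))
  SHand <- sum(rHand) * cor(sumz, csf, method = "spearman")
  expect_equal(componentSize(C, conn, csf), SHand, tolerance = 1e-12)
})

test_that("link-wise field equals per-link partial Spearman calls", {
  set.seed(57)
  sim <- simulateConnectivity(connectivitySpec(
    nSubjects = 25, nNodes = 8L,
    plantedLinks = rbind(c(1L, 2L), c(2L, 3L)), seed = 57))
  covars <- sim$subjects
  field <- linkCorrelations(sim$conn, sim$csf, covars)
  z <- connValues(sim$conn)
  for (row in c(1, 7, 15, 28)) {
    expect_equal(field$r[row],
                 partialSpearman(z[field$i[row], field$j[row], ], sim$csf,
                                 covars),
                 tolerance = 1e-10)
  }
})

test_that("permutation test recovers a planted component", {
  sim <- simulateConnectivity(connectivitySpec(nSubjects = 100,
                                               effectSize = 0.8,
                                               seed = 58))
  comp <- permutationTest(sim$conn, sim$csf, nPerm = 500, seed = 58)
  expect_lt(permPvalue(comp), 0.01)
  links <- componentLinks(comp)
  planted <- paste(sim$plantedLinks[, 1], sim$plantedLinks[, 2])
  recovered <- mean(planted %in% paste(links$i, links$j))
  expect_gte(recovered, 0.7)
  expect_equal(length(nullSizes(comp)), 500L)
})

test_that("permutation test is deterministic and covariate-stable", {
  sim <- simulateConnectivity(connectivitySpec(nSubjects = 40,
                                               effectSize = 0.7,
                                               seed = 59))
  a <- permutationTest(sim$conn, sim$csf, covars = sim$subjects,
                       nPerm = 200, seed = 7)
  b <- permutationTest(sim$conn, sim$csf, covars = sim$subjects,
                       nPerm = 200, seed = 7)
  expect_identical(componentStat(a), componentStat(b))
  expect_identical(permPvalue(a), permPvalue(b))
  expect_identical(nullSizes(a), nullSizes(b))

  # Freedman-Lane residual permutation: same observed component, valid
  # and reproducible null
  fl <- permutationTest(sim$conn, sim$csf, covars = sim$subjects,
                        nPerm = 200, seed = 7,
                        permMode = "freedman_lane")
  expect_identical(componentLinks(fl), componentLinks(a))
  expect_identical(componentStat(fl), componentStat(a))
  expect_true(permPvalue(fl) > 0 && permPvalue(fl) <= 1)
})

test_that("negating CSF mirrors the component into the other direction", {
  sim <- simulateConnectivity(connectivitySpec(nSubjects = 60,
                                               effectSize = 0.8,
                                               seed = 60))
  pos <- permutationTest(sim$conn, sim$csf, nPerm = 200, seed = 9,
                         direction = "positive")
  neg <- permutationTest(sim$conn, -sim$csf, nPerm = 200, seed = 9,
                         direction = "negative")
  expect_equal(componentLinks(pos)[, c("i", "j")],
               componentLinks(neg)[, c("i", "j")])
  expect_equal(abs(componentStat(pos)), abs(componentStat(neg)),
               tolerance = 1e-10)
})

test_that("S is invariant under monotone transforms of CSF", {
  sim <- simulateConnectivity(connectivitySpec(nSubjects = 50,
                                               effectSize = 0.8,
                                               seed = 61))
  f1 <- linkCorrelations(sim$conn, sim$csf)
  f2 <- linkCorrelations(sim$conn, exp(sim$csf / 200))
  expect_equal(f1$r, f2$r, tolerance = 1e-12)
})

test_that("no supra-threshold component yields an empty result with p = 1", {
  sim <- simulateConnectivity(connectivitySpec(nSubjects = 80, nNodes = 10L,
                                               effectSize = 0,
                                               plantedLinks =
                                                 matrix(integer(0), 0, 2),
                                               seed = 62))
  comp <- permutationTest(sim$conn, sim$csf, alphaLink = 1e-9,
                          nPerm = 100, seed = 3)
  expect_equal(nrow(componentLinks(comp)), 0L)
  expect_equal(permPvalue(comp), 1)
  expect_equal(componentStat(comp), 0)
})

test_that("network breakdown counts links per network pair", {
  labels <- c("DM", "DM", "DM", "DM", "FP", "FP")
  links <- data.frame(i = c(1L, 1L, 2L, 1L, 2L),
                      j = c(2L, 3L, 3L, 5L, 6L),
                      r = rep(0.5, 5))
  bd <- networkBreakdown(links, labels)
  expect_equal(bd$count[bd$network_a == "DM" & bd$network_b == "DM"], 3L)
  expect_equal(bd$count[bd$network_a == "DM" & bd$network_b == "FP"], 2L)
  expect_equal(sum(bd$count), nrow(links))
  expect_error(networkBreakdown(links, labels[1:4]), "nlabelled")

  set.seed(63)
  sim <- simulateConnectivity(connectivitySpec(seed = 63))
  comp <- permutationTest(sim$conn, sim$csf, nPerm = 100, seed = 2)
  bd <- networkBreakdown(comp)
  expect_equal(sum(bd$count), nrow(componentLinks(comp)))
})
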