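test_that("cohort generation is deterministic and respects its spec", {
  spec <- cohortSpec(nSubjects = 120, seed = 77)
  p1 <- simulateCohort(spec)
  p2 <- simulateCohort(spec)
  expect_identical(suvrBaseline(p1), suvrBaseline(p2))
  expect_identical(suvrFollowup(p1), suvrFollowup(p2))
  expect_identical(as.data.frame(SummarizedExperiment::colData(p1)),
                   as.data.frame(SummarizedExperiment::colData(p2)))

  expect_true(all(suvrBaseline(p1) > 0))
  expect_true(all(suvrFollowup(p1) > 0))
  iv <- scanInterval(p1)
  expect_true(all(iv >= 0.9 & iv <= 4.1))
})

test_that("zero noise and zero rates reproduce baseline exactly", {
  rm0 <- matrix(0, 4, 3)
  spec <- cohortSpec(nSubjects = 40, rateMeans = rm0, rateSd = 0,
                     roiBaselineSd = 0, followupNoiseSd = 0, seed = 78)
  p <- simulateCohort(spec)
  expect_identical(suvrBaseline(p), suvrFollowup(p))
})

test_that("generated rates match the stage-by-ROI-class means", {
  rm <- rbind("CSF-/PET-" = c(0.4, 0.4, 0.4),
              "CSF+/PET-" = c(2.5, 0.4, 0.4),
              "CSF+/PET+" = c(2.5, 2.4, 1.5),
              "CSF-/PET+" = c(1.5, 1.5, 1.0))
  colnames(rm) <- c("early", "late", "other")
  p <- simulateCohort(cohortSpec(nSubjects = 300, rateMeans = rm,
                                 seed = 79))
  cd <- SummarizedExperiment::colData(p)
  pct <- percentRate(panelAnnualChange(p), suvrBaseline(p))
  early <- SummarizedExperiment::rowData(p)$roi_class == "early"

  for (stage in c("CSF-/PET-", "CSF+/PET-")) {
    sel <- cd$stage_true == stage
    vals <- pct[early, sel]
    mu <- mean(vals)
    sem <- sd(vals) / sqrt(length(vals))
    target <- rm[stage, "early"]
    expect_lt(abs(mu - target), 3 * sem + 0.05)
  }
})

test_that("stage cell proportions follow the generative mixture", {
  spec <- cohortSpec(nSubjects = 5000, seed = 80)
  p <- simulateCohort(spec)
  obs <- table(SummarizedExperiment::colData(p)$stage_true)
  wAbn <- spec@csfMixture["abnormal", "weight"]
  pPet <- spec@petGivenCsf
  probs <- c("CSF-/PET-" = (1 - wAbn) * (1 - pPet[1]),
             "CSF+/PET-" = wAbn * (1 - pPet[2]),
             "CSF+/PET+" = wAbn * pPet[2],
             "CSF-/PET+" = (1 - wAbn) * pPet[1])
  chi <- chisq.test(as.vector(obs), p = probs[names(obs)])
  expect_gt(chi$p.value, 0.001)
})

test_that("invalid cohort specs fail with the offending field named", {
  expect_error(cohortSpec(nSubjects = 0), "nSubjects")
  expect_error(cohortSpec(csfMixture = rbind(c(0.7, 234, 27),
                                             c(0.5, 150, 30))),
               "weights must sum to 1")
  expect_error(cohortSpec(petMixture = rbind(c(0.6, 0.74, 0),
                                             c(0.4, 1.0, 0.12))),
               "sds must be > 0")
  expect_error(cohortSpec(earlyRois = "lh_precuneus",
                          lateRois = "lh_precuneus"), "disjoint")
  expect_error(cohortSpec(earlyRois = "not_a_roi"), "subsets of roiNames")
  expect_error(cohortSpec(seed = NULL), "seed")
})

test_that("planted connectivity effects land at the requested strength", {
  simStrong <- simulateConnectivity(connectivitySpec(nSubjects = 100,
                                                     effectSize = 0.8,
                                                     seed = 81))
  pl <- simStrong$plantedLinks
  sumz <- apply(connValues(simStrong$conn), 3, function(m) sum(m[pl]))
  rho <- cor(sumz, simStrong$csf, method = "spearman")
  expect_gt(rho, 0.6)
  expect_lt(rho, 0.95)

  simNull <- simulateConnectivity(connectivitySpec(nSubjects = 100,
                                                   effectSize = 0,
                                                   seed = 82))
  sumz0 <- apply(connValues(simNull$conn), 3,
                 function(m) sum(m[simNull$plantedLinks]))
  expect_lt(abs(cor(sumz0, simNull$csf, method = "spearman")), 0.3)
})

test_that("tiny connectivity graphs have the right structure", {
  sim <- simulateConnectivity(connectivitySpec(
    nSubjects = 12, nNodes = 2L, nodeLabels = c("DM", "FP"),
    plantedLinks = matrix(c(1L, 2L), 1), seed = 83))
  z <- connValues(sim$conn)
  expect_equal(dim(z), c(2L, 2L, 12L))
  expect_equal(z[1, 2, ], z[2, 1, ])
  expect_equal(z[1, 1, ], rep(0, 12))

  expect_error(connectivitySpec(nNodes = 5L,
                                nodeLabels = rep("DM", 5),
                                plantedLinks = matrix(c(1L, 9L), 1)),
               "node range")
})

test_that("grid generator plants detectable clusters and validates masks", {
  spec <- gridSpec(effectSizes = 1.0, noiseSd = 0.1, seed = 84)
  sim <- simulateGrids(spec)
  map <- adjustedTtestMap(sim$grids, sim$groups, mask = sim$mask)
  cube <- spec@clusterVoxels[[1]] + 1L
  tvals <- tMap(map)[cube]
  expect_gte(mean(tvals > 3), 0.9)

  # zero effect: the planted voxels look like any other null voxel
  sim0 <- simulateGrids(gridSpec(effectSizes = 0, seed = 85))
  map0 <- adjustedTtestMap(sim0$grids, sim0$groups, mask = sim0$mask)
  expect_lt(max(abs(tMap(map0)), na.rm = TRUE), 6)

  mask <- array(TRUE, dim = c(20, 20, 20))
  mask[1:12, , ] <- FALSE      # removes the default cube at 5..9
  expect_error(gridSpec(mask = mask), "outside the mask")
  expect_error(gridSpec(mask = array(FALSE, dim = c(20, 20, 20))),
               "empty|outside")
})
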