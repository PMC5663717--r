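test_that("annual change and percent rate follow the linear formulas", {
  expect_equal(annualChange(0.80, 0.84, 2.0), 0.02)
  expect_equal(annualChange(0.9, 0.9, 3.1), 0)
  expect_error(annualChange(0.8, 0.9, 0), "> 0")
  expect_error(annualChange(0.8, 0.9, -1), "> 0")

  expect_equal(percentRate(0.02, 0.80), 2.5)
  expect_equal(percentRate(0, 1.23), 0)
  expect_equal(percentRate(0.018, 0.90), 2.0)
  expect_error(percentRate(0.02, 0), "> 0")

  # shift invariance: adding a constant to both scans leaves change fixed
  set.seed(21)
  a <- runif(50, 0.5, 1.2); b <- a + rnorm(50, 0.02, 0.01)
  expect_equal(annualChange(a, b, 2), annualChange(a + 0.3, b + 0.3, 2))

  # matrix form with per-subject intervals
  base <- matrix(1, 3, 2)
  fu <- matrix(c(1.1, 1.1, 1.1, 1.2, 1.2, 1.2), 3, 2)
  ch <- annualChange(base, fu, c(1, 2))
  expect_equal(ch[1, ], c(0.1, 0.1), tolerance = 1e-12)
})

test_that("BH flags match a hand-executed step-up procedure", {
  expect_equal(sum(bhFdr(c(0.001, 0.01, 0.02, 0.04, 0.9), 0.05)), 4L)
  expect_false(any(bhFdr(rep(1, 10), 0.05)))
  expect_true(bhFdr(0.04, 0.05))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(22)
  for (r in 1:20) {
    p <- runif(68)^runif(1, 0.5, 3)
    q <- runif(1, 0.01, 0.2)
    expect_equal(bhFdr(p, q), bhStepUpOracle(p, q))
  }
})

test_that("unadjusted ROI contrast equals the pooled two-sample t-test", {
  panel <- simulateCohort(cohortSpec(nSubjects = 80, seed = 23))
  cd <- SummarizedExperiment::colData(panel)
  res <- roiContrast(panel, "stage_true", c("CSF-/PET-", "CSF+/PET+"),
                     covariates = character(0))
  rate <- panelAnnualChange(panel)
  g1 <- cd$stage_true == "CSF-/PET-"
  g2 <- cd$stage_true == "CSF+/PET+"
  for (roi in res$roi[1:5]) {
    tt <- t.test(rate[roi, g2], rate[roi, g1], var.equal = TRUE)
    row <- res[res$roi == roi, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
    expect_equal(row$estimate, unname(diff(rev(tt$estimate))),
                 tolerance = 1e-10)
  }
})

test_that("covariates orthogonal to group leave the contrast unchanged", {
  panel <- simulateCohort(cohortSpec(nSubjects = 150, seed = 24))
  cd <- SummarizedExperiment::colData(panel)
  # balanced synthetic covariate, orthogonal to every group indicator
  SummarizedExperiment::colData(panel)$block <-
    rep(c(-1, 1), length.out = ncol(panel))
  un <- roiContrast(panel, "stage_true", c("CSF-/PET-", "CSF+/PET+"),
                    covariates = character(0))
  ad <- roiContrast(panel, "stage_true", c("CSF-/PET-", "CSF+/PET+"),
                    covariates = "block")
  m <- match(un$roi, ad$roi)
  expect_equal(un$estimate, ad$estimate[m], tolerance = 0.02)
})

test_that("planted early-ROI rate differences are found and survive BH", {
  rm <- rbind("CSF-/PET-" = c(0.4, 0.4, 0.4),
              "CSF+/PET-" = c(2.5, 0.4, 0.4),
              "CSF+/PET+" = c(2.5, 2.4, 1.5),
              "CSF-/PET+" = c(1.5, 1.5, 1.0))
  panel <- simulateCohort(cohortSpec(nSubjects = 473, rateMeans = rm,
                                     seed = 25))
  res <- roiContrast(panel, "stage_true", c("CSF-/PET-", "CSF+/PET-"))
  early <- rownames(panel)[
    SummarizedExperiment::rowData(panel)$roi_class == "early"]
  sig <- res$roi[res$bh_significant]
  # the discovered set is dominated by the planted ROIs
  expect_gte(sum(early %in% sig), 12)
  expect_lte(sum(!sig %in% early), 2)
  # planted ROIs concentrate at the top of the significance ordering
  expect_gte(sum(res$roi[seq_along(early)] %in% early), 12)
  # estimated group rates bracket the generating values
  rowsE <- res[res$roi %in% early, ]
  expect_gt(mean(rowsE[["meanPct_CSF+/PET-"]]), 2.0)
  expect_lt(mean(rowsE[["meanPct_CSF-/PET-"]]), 1.0)
})

test_that("degenerate contrast designs are rejected with clear errors", {
  panel <- simulateCohort(cohortSpec(nSubjects = 60, seed = 26))
  expect_error(roiContrast(panel, "stage_true",
                           c("CSF-/PET-", "CSF-/PET-")), "identical")
  expect_error(roiContrast(panel, "stage_true",
                           c("CSF-/PET-", "CSF-/PET+")), "2 subjects")
  SummarizedExperiment::colData(panel)$dup <-
    SummarizedExperiment::colData(panel)$age
  expect_error(roiContrast(panel, "stage_true", c("CSF-/PET-", "CSF+/PET+"),
                           covariates = c("age", "dup")), "collinear")
})

test_that("Mann-Whitney exact p matches full enumeration", {
  r <- rankTests(c(1, 2), c(3, 4), kind = "mann_whitney",
                 alternative = "less")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1 / 6)
  set.seed(27)
  for (k in 1:8) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    v <- sample(1000, n1 + n2) / 7   # untied
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    r <- rankTests(x, y, kind = "mann_whitney", alternative = "less")
    expect_equal(r$p.value, mwEnumPvalue(x, y), tolerance = 1e-12)
  }
})

test_that("rank tests: signed-rank guards and Kruskal-Wallis consistency", {
  expect_error(rankTests(rep(0, 5), kind = "wilcoxon_signed"), "zero")
  d <- c(1.2, -0.5, 2.1, 0.8, 1.4, -0.2, 0.9)
  expect_lt(rankTests(d, kind = "wilcoxon_signed")$p.value, 0.2)
  set.seed(28)
  x <- rnorm(40); y <- rnorm(40, 0.9)
  pkw <- rankTests(list(x, y), kind = "kruskal_wallis")$p.value
  pmw <- rankTests(x, y, kind = "mann_whitney")$p.value
  expect_equal(pkw, pmw, tolerance = 0.02)
})

test_that("null two-group labels give uniform Mann-Whitney p-values", {
  set.seed(29)
  ps <- replicate(300, {
    v <- rnorm(40)
    rankTests(v[1:20], v[21:40], kind = "mann_whitney")$p.value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
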