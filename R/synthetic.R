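#' @include AllClasses.R AllGenerics.R utils.R staging.R
NULL

## 34 Desikan-Killiany-style cortical parcels x two hemispheres = 68 ROIs
.DK_PARCELS <- c(
  "bankssts", "caudal_anterior_cingulate", "caudal_middle_frontal",
  "cuneus", "entorhinal", "frontal_pole", "fusiform", "inferior_parietal",
  "inferior_temporal", "insula", "isthmus_cingulate", "lateral_occipital",
  "lateral_orbitofrontal", "lingual", "medial_orbitofrontal",
  "middle_temporal", "paracentral", "parahippocampal", "pars_opercularis",
  "pars_orbitalis", "pars_triangularis", "pericalcarine", "postcentral",
  "posterior_cingulate", "precentral", "precuneus",
  "rostral_anterior_cingulate", "rostral_middle_frontal",
  "superior_frontal", "superior_parietal", "superior_temporal",
  "supramarginal", "temporal_pole", "transverse_temporal")

#' Default cortical ROI names (68 parcels)
#' @return Character vector of 68 ROI names (34 parcels x lh/rh).
#' @export
defaultRoiNames <- function() {
  as.vector(t(outer(c("lh", "rh"), .DK_PARCELS, paste, sep = "_")))
}

## the DMN-like regions where accumulation starts (15 ROIs, matching the
## posterior/isthmus cingulate, precuneus, orbitofrontal, anterior
## cingulate, insula pattern of early accumulators)
.defaultEarlyRois <- function() {
  bi <- c("posterior_cingulate", "isthmus_cingulate", "precuneus",
          "medial_orbitofrontal", "rostral_anterior_cingulate", "insula")
  c(paste0("lh_", bi), paste0("rh_", bi),
    "lh_lateral_orbitofrontal", "lh_superior_frontal",
    "rh_transverse_temporal")
}

## sensorimotor / occipital regions that accumulate late
.defaultLateRois <- function() {
  bi <- c("precentral", "postcentral", "pericalcarine", "paracentral",
          "lingual", "lateral_occipital", "fusiform")
  c(paste0("lh_", bi), paste0("rh_", bi), "lh_cuneus")
}

.defaultRateMeans <- function() {
  m <- rbind(
    "CSF-/PET-" = c(0.5, 0.3, 0.3),
    "CSF+/PET-" = c(2.2, 0.3, 0.8),
    "CSF+/PET+" = c(2.2, 2.4, 1.5),
    "CSF-/PET+" = c(1.5, 1.5, 1.0))
  colnames(m) <- c("early", "late", "other")
  m
}

#' Specification of a synthetic CSF/PET cohort
#'
#' Describes the generative model for a longitudinal amyloid cohort: a
#' two-component Gaussian mixture for CSF A-beta-42 (normal and abnormal
#' components) and for the neocortical PET SUVR, with the PET component
#' drawn conditionally on the CSF component so that all four CSF/PET
#' stage cells are populated; stage- and ROI-class-dependent percent
#' annual accumulation rates; and age/sex/APOE covariate structure.
#'
#' @slot nSubjects Integer, cohort size.
#' @slot csfMixture,petMixture 2 x 3 matrices (rows: normal, abnormal
#'   component; columns: weight, mean, sd). CSF units ng/L, PET units
#'   SUVR. Weights sum to 1.
#' @slot petGivenCsf Numeric(2): P(PET abnormal | CSF normal) and
#'   P(PET abnormal | CSF abnormal).
#' @slot roiNames,earlyRois,lateRois Character vectors; the early and
#'   late sets are disjoint subsets of \code{roiNames}.
#' @slot rateMeans 4 x 3 matrix of mean percent annual SUVR rates by
#'   stage (rows, stage label order) and ROI class (early/late/other).
#' @slot rateSd Between-subject sd of the true rate, percent/yr.
#' @slot roiBaselineSd Across-ROI sd around the subject-level baseline
#'   SUVR.
#' @slot followupNoiseSd Additive measurement noise on follow-up SUVR.
#' @slot ageMean,ageSd,sexPropF Covariate model.
#' @slot apoePrev Numeric(4), APOE e4 prevalence per stage.
#' @slot intervalMean,intervalRange Inter-scan interval (years): mean
#'   and admissible range.
#' @slot seed Integer RNG seed.
#'
#' @seealso [cohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nSubjects = "integer", csfMixture = "matrix", petMixture = "matrix",
    petGivenCsf = "numeric", roiNames = "character",
    earlyRois = "character", lateRois = "character", rateMeans = "matrix",
    rateSd = "numeric", roiBaselineSd = "numeric",
    followupNoiseSd = "numeric", ageMean = "numeric", ageSd = "numeric",
    sexPropF = "numeric", apoePrev = "numeric", intervalMean = "numeric",
    intervalRange = "numeric", seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  for (nm in c("csfMixture", "petMixture")) {
    m <- slot(object, nm)
    if (!identical(dim(m), c(2L, 3L)))
      msg <- c(msg, sprintf("%s must be a 2 x 3 (weight, mean, sd) matrix",
                            nm))
    else {
      if (abs(sum(m[, 1]) - 1) > 1e-8)
        msg <- c(msg, sprintf("%s: weights must sum to 1", nm))
      if (any(m[, 3] <= 0))
        msg <- c(msg, sprintf("%s: sds must be > 0", nm))
    }
  }
  if (length(object@petGivenCsf) != 2L ||
      any(object@petGivenCsf < 0 | object@petGivenCsf > 1))
    msg <- c(msg, "petGivenCsf must be two probabilities")
  if (length(intersect(object@earlyRois, object@lateRois)))
    msg <- c(msg, "earlyRois and lateRois must be disjoint")
  if (!all(c(object@earlyRois, object@lateRois) %in% object@roiNames))
    msg <- c(msg, "earlyRois/lateRois must be subsets of roiNames")
  if (!identical(dim(object@rateMeans), c(4L, 3L)))
    msg <- c(msg, "rateMeans must be a 4 x 3 (stage x ROI class) matrix")
  if (object@rateSd < 0 || object@roiBaselineSd < 0 ||
      object@followupNoiseSd < 0)
    msg <- c(msg, "sds must be >= 0")
  if (length(object@apoePrev) != 4L ||
      any(object@apoePrev < 0 | object@apoePrev > 1))
    msg <- c(msg, "apoePrev must be four probabilities (one per stage)")
  if (length(object@intervalRange) != 2L ||
      object@intervalRange[1] <= 0 ||
      object@intervalRange[1] >= object@intervalRange[2])
    msg <- c(msg, "intervalRange must be 0 < lo < hi")
  if (length(msg)) msg else TRUE
})

#' Build a cohort specification
#'
#' Constructor for \linkS4class{CohortSpec} with defaults emulating a
#' large longitudinal amyloid-PET cohort of non-demented subjects:
#' 473 subjects, a normal CSF component N(234, 27) ng/L against an
#' abnormal component N(150, 30) with 53% abnormal weight, PET
#' components N(0.74, 0.05) / N(1.00, 0.12) SUVR, stage-conditional PET
#' abnormality probabilities chosen so the four stage cells populate at
#' roughly 46/12/40/1%, early (DMN-like) versus late
#' (sensorimotor/occipital) ROI sets among 68 cortical parcels, percent
#' annual rates ~2.2%/yr in early ROIs for early accumulators against
#' ~0.5%/yr in non-accumulators, and a ~2-year inter-scan interval.
#'
#' @param nSubjects Cohort size (default 473).
#' @param csfMixture,petMixture 2 x 3 (weight, mean, sd) matrices; rows
#'   are the normal and abnormal components.
#' @param petGivenCsf P(PET+ | CSF-) and P(PET+ | CSF+).
#' @param roiNames,earlyRois,lateRois ROI names and the early/late
#'   subsets.
#' @param rateMeans 4 x 3 stage-by-class matrix of mean %/yr rates.
#' @param rateSd,roiBaselineSd,followupNoiseSd Noise parameters (%/yr,
#'   SUVR, SUVR).
#' @param ageMean,ageSd,sexPropF,apoePrev Covariate model.
#' @param intervalMean,intervalRange Inter-scan interval model (years).
#' @param seed RNG seed.
#' @return A validated \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nSubjects = 473L,
                       csfMixture = rbind(normal = c(0.47, 234, 27),
                                          abnormal = c(0.53, 150, 30)),
                       petMixture = rbind(normal = c(0.60, 0.74, 0.05),
                                          abnormal = c(0.40, 1.00, 0.12)),
                       petGivenCsf = c(0.022, 0.764),
                       roiNames = defaultRoiNames(),
                       earlyRois = .defaultEarlyRois(),
                       lateRois = .defaultLateRois(),
                       rateMeans = .defaultRateMeans(),
                       rateSd = 1.0, roiBaselineSd = 0.05,
                       followupNoiseSd = 0.04,
                       ageMean = 72, ageSd = 7, sexPropF = 0.47,
                       apoePrev = c(0.16, 0.46, 0.65, 0.40),
                       intervalMean = 2.0, intervalRange = c(0.9, 4.1),
                       seed = 1L) {
  colnames(csfMixture) <- colnames(petMixture) <- c("weight", "mean", "sd")
  rownames(csfMixture) <- rownames(petMixture) <- c("normal", "abnormal")
  colnames(rateMeans) <- c("early", "late", "other")
  rownames(rateMeans) <- STAGE_LABELS
  obj <- new("CohortSpec", nSubjects = .assertCount(nSubjects, "nSubjects"),
             csfMixture = csfMixture, petMixture = petMixture,
             petGivenCsf = petGivenCsf, roiNames = roiNames,
             earlyRois = earlyRois, lateRois = lateRois,
             rateMeans = rateMeans, rateSd = rateSd,
             roiBaselineSd = roiBaselineSd,
             followupNoiseSd = followupNoiseSd, ageMean = ageMean,
             ageSd = ageSd, sexPropF = sexPropF, apoePrev = apoePrev,
             intervalMean = intervalMean, intervalRange = intervalRange,
             seed = .assertSeed(seed))
  validObject(obj)
  obj
}

#' Simulate a longitudinal CSF/PET cohort
#'
#' Draws a cohort from a \linkS4class{CohortSpec}: each subject's CSF
#' A-beta-42 comes from one of the two CSF mixture components, the PET
#' component is drawn conditionally on the CSF component, and the true
#' stage label is the combination of the two generating components.
#' Baseline regional SUVR scatters around the subject-level PET value;
#' follow-up SUVR is \code{baseline * (1 + rate/100 * years) + noise}
#' with the true percent rate drawn per subject and ROI around the
#' stage-by-ROI-class mean (linear change, no compounding). All SUVR
#' values are kept strictly positive. Deterministic given the spec seed.
#'
#' @param spec A \linkS4class{CohortSpec}.
#' @return A \linkS4class{RoiSuvrPanel}; subject-level records (age,
#'   sex, APOE e4, CSF A-beta-42, neocortical PET SUVR, true stage,
#'   interval) are in \code{colData}, ROI classes in \code{rowData}.
#'
#' @examples
#' panel <- simulateCohort(cohortSpec(nSubjects = 50, seed = 7))
#' table(SummarizedExperiment::colData(panel)$stage_true)
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nSubjects
  nRoi <- length(spec@roiNames)

  csfComp <- rbinom(n, 1L, spec@csfMixture["abnormal", "weight"])
  csf <- rnorm(n,
               mean = spec@csfMixture[csfComp + 1L, "mean"],
               sd = spec@csfMixture[csfComp + 1L, "sd"])
  csf <- pmax(csf, 1)
  petComp <- rbinom(n, 1L, spec@petGivenCsf[csfComp + 1L])
  pet <- rnorm(n,
               mean = spec@petMixture[petComp + 1L, "mean"],
               sd = spec@petMixture[petComp + 1L, "sd"])
  pet <- pmax(pet, 0.2)

  stage <- factor(ifelse(csfComp == 1L,
                         ifelse(petComp == 1L, "CSF+/PET+", "CSF+/PET-"),
                         ifelse(petComp == 1L, "CSF-/PET+", "CSF-/PET-")),
                  levels = STAGE_LABELS)

  age <- rnorm(n, spec@ageMean, spec@ageSd)
  sex <- ifelse(runif(n) < spec@sexPropF, "F", "M")
  apoe <- rbinom(n, 1L, spec@apoePrev[as.integer(stage)])
  interval <- pmin(pmax(rnorm(n, spec@intervalMean, 0.5),
                        spec@intervalRange[1]), spec@intervalRange[2])

  roiClass <- rep("other", nRoi)
  roiClass[spec@roiNames %in% spec@earlyRois] <- "early"
  roiClass[spec@roiNames %in% spec@lateRois] <- "late"

  baseline <- matrix(rep(pet, each = nRoi), nRoi, n) +
    matrix(rnorm(nRoi * n, 0, spec@roiBaselineSd), nRoi, n)
  baseline <- pmax(baseline, 0.2)

  rateMean <- spec@rateMeans[cbind(rep(as.integer(stage), each = nRoi),
                                   rep(match(roiClass,
                                             colnames(spec@rateMeans)),
                                       times = n))]
  rate <- matrix(rateMean + rnorm(nRoi * n, 0, spec@rateSd), nRoi, n)
  followup <- baseline * (1 + rate / 100 * rep(interval, each = nRoi)) +
    matrix(rnorm(nRoi * n, 0, spec@followupNoiseSd), nRoi, n)
  followup <- pmax(followup, 0.01)

  ids <- sprintf("subj%04d", seq_len(n))
  dimnames(baseline) <- dimnames(followup) <- list(spec@roiNames, ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(suvr_baseline = baseline, suvr_followup = followup),
    colData = S4Vectors::DataFrame(
      subject = ids, age = age, sex = sex, apoe4 = apoe,
      csf_ab42 = csf, pet_suvr = pet, interval_years = interval,
      stage_true = stage, row.names = ids),
    rowData = S4Vectors::DataFrame(roi_class = roiClass,
                                   row.names = spec@roiNames))
  new("RoiSuvrPanel", se)
}

## split nNodes across the 9 network labels with fixed proportions
.defaultNodeLabels <- function(nNodes) {
  prop <- c(DM = 0.20, FP = 0.14, DA = 0.10, VA = 0.10, SM = 0.13,
            VI = 0.13, FT = 0.07, BG = 0.07, HI = 0.06)
  cuts <- diff(c(0L, round(cumsum(prop / sum(prop)) * nNodes)))
  rep(names(prop), times = cuts)
}

## a connected 10-link set: a DMN core with two DMN-frontoparietal links
.defaultPlantedLinks <- function(labels) {
  dm <- which(labels == "DM")
  fp <- which(labels == "FP")
  if (length(dm) < 4L || length(fp) < 2L)
    stop("too few DM/FP nodes for the default planted component",
         call. = FALSE)
  core <- t(utils::combn(dm[1:4], 2L))
  extra <- rbind(c(dm[1], dm[min(5L, length(dm))]),
                 c(dm[2], dm[min(6L, length(dm))]),
                 c(dm[1], fp[1]), c(dm[2], fp[2]))
  lk <- rbind(core, extra)
  unique(t(apply(lk, 1L, sort)))
}

#' Specification of synthetic connectivity data
#'
#' Generative model for per-subject Fisher-z connectivity matrices with
#' a planted link component whose summed connectivity correlates with
#' CSF A-beta-42 at a configurable Spearman effect size. Planted links
#' share a subject-level latent (signal plus shared noise), so both the
#' per-link and the summed-z correlation with CSF approach
#' \code{effectSize}; off-component links are independent noise.
#'
#' @slot nSubjects,nNodes Integers.
#' @slot nodeLabels Character, network label per node.
#' @slot plantedLinks Integer matrix (2 columns, i < j) of planted
#'   links; may have zero rows.
#' @slot effectSize Target Spearman correlation between the planted
#'   component's summed z and CSF, in [-1, 1].
#' @slot noiseSd Sd of off-component link noise (z units).
#' @slot baselineZ Mean link z value.
#' @slot gain Z-units of planted signal per latent unit.
#' @slot idioFrac Idiosyncratic (link-specific) share of planted-link
#'   noise, as a fraction of \code{noiseSd}.
#' @slot csfMean,csfSd CSF A-beta-42 marginal (ng/L).
#' @slot seed Integer RNG seed.
#'
#' @seealso [connectivitySpec()], [simulateConnectivity()]
#' @export
setClass("ConnectivitySpec",
  representation(
    nSubjects = "integer", nNodes = "integer", nodeLabels = "character",
    plantedLinks = "matrix", effectSize = "numeric", noiseSd = "numeric",
    baselineZ = "numeric", gain = "numeric", idioFrac = "numeric",
    csfMean = "numeric", csfSd = "numeric", seed = "integer"
  )
)

setValidity("ConnectivitySpec", function(object) {
  msg <- character()
  if (object@nNodes < 2L) msg <- c(msg, "nNodes must be >= 2")
  if (length(object@nodeLabels) != object@nNodes)
    msg <- c(msg, "need one node label per node")
  pl <- object@plantedLinks
  if (nrow(pl)) {
    if (any(pl < 1L) || any(pl > object@nNodes))
      msg <- c(msg, "planted link outside the node range")
    if (any(pl[, 1] == pl[, 2]))
      msg <- c(msg, "planted links must join two distinct nodes")
  }
  if (abs(object@effectSize) > 1)
    msg <- c(msg, "|effectSize| must be <= 1")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (length(msg)) msg else TRUE
})

#' Build a connectivity specification
#'
#' Constructor for \linkS4class{ConnectivitySpec}; defaults plant a
#' connected 10-link component among default-mode (and two
#' frontoparietal) nodes of a 30-node, 9-network atlas.
#'
#' @param nSubjects,nNodes Cohort and graph size (defaults 100, 30).
#' @param nodeLabels Network label per node.
#' @param plantedLinks 2-column matrix of links carrying the effect.
#' @param effectSize Target summed-z-vs-CSF Spearman correlation.
#' @param noiseSd,baselineZ,gain,idioFrac Noise/signal geometry (see the
#'   class documentation).
#' @param csfMean,csfSd CSF marginal.
#' @param seed RNG seed.
#' @return A validated \linkS4class{ConnectivitySpec}.
#' @export
connectivitySpec <- function(nSubjects = 100L, nNodes = 30L,
                             nodeLabels = .defaultNodeLabels(nNodes),
                             plantedLinks = .defaultPlantedLinks(nodeLabels),
                             effectSize = 0.8, noiseSd = 0.25,
                             baselineZ = 0.2, gain = 0.3, idioFrac = 0.3,
                             csfMean = 600, csfSd = 150, seed = 1L) {
  storage.mode(plantedLinks) <- "integer"
  if (nrow(plantedLinks))
    plantedLinks <- t(apply(plantedLinks, 1L, sort))
  obj <- new("ConnectivitySpec",
             nSubjects = .assertCount(nSubjects, "nSubjects", min = 2L),
             nNodes = .assertCount(nNodes, "nNodes", min = 2L),
             nodeLabels = nodeLabels, plantedLinks = plantedLinks,
             effectSize = effectSize, noiseSd = noiseSd,
             baselineZ = baselineZ, gain = gain, idioFrac = idioFrac,
             csfMean = csfMean, csfSd = csfSd, seed = .assertSeed(seed))
  validObject(obj)
  obj
}

#' Simulate connectivity matrices with a planted CSF-correlated component
#'
#' Generates per-subject symmetric Fisher-z matrices: every off-planted
#' link is independent Gaussian noise around \code{baselineZ}, while
#' planted links load on a shared subject latent
#' \code{L = effectSize * g(csf) + sqrt(1 - effectSize^2) * eta}
#' (\code{g} = normal scores of the CSF ranks, \code{eta} shared noise),
#' plus a small idiosyncratic term. The Spearman correlation between the
#' per-subject sum of planted-link z values and CSF therefore
#' concentrates near \code{effectSize}. Deterministic given the seed.
#'
#' @param spec A \linkS4class{ConnectivitySpec}.
#' @return List with \code{conn} (a \linkS4class{ConnectivityArray}),
#'   \code{csf} (per-subject values), \code{subjects} (data frame of
#'   age/sex/APOE covariates) and \code{plantedLinks}.
#'
#' @export
simulateConnectivity <- function(spec) {
  stopifnot(is(spec, "ConnectivitySpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nSubjects
  nn <- spec@nNodes
  idx <- .linkIndex(nn)
  L <- nrow(idx)

  csf <- rnorm(n, spec@csfMean, spec@csfSd)
  g <- qnorm(rank(csf) / (n + 1))
  eta <- rnorm(n)
  lat <- spec@effectSize * g + sqrt(1 - spec@effectSize^2) * eta

  Zlinks <- spec@baselineZ +
    matrix(rnorm(n * L, 0, spec@noiseSd), n, L)
  pl <- spec@plantedLinks
  if (nrow(pl)) {
    idxMap <- matrix(NA_integer_, nn, nn)
    idxMap[idx] <- seq_len(L)
    cols <- idxMap[pl]
    Zlinks[, cols] <- spec@baselineZ + spec@gain * lat +
      matrix(rnorm(n * length(cols), 0, spec@idioFrac * spec@noiseSd),
             n, length(cols))
  }

  z <- array(0, dim = c(nn, nn, n))
  for (s in seq_len(n)) {
    m <- matrix(0, nn, nn)
    m[idx] <- Zlinks[s, ]
    z[, , s] <- m + t(m)
  }

  subjects <- data.frame(
    age = rnorm(n, 72, 7),
    sex = ifelse(runif(n) < 0.5, "F", "M"),
    apoe4 = rbinom(n, 1L, 0.4))

  list(conn = connectivityArray(z, spec@nodeLabels),
       csf = csf, subjects = subjects, plantedLinks = pl)
}

#' Specification of synthetic 3-D voxel grids
#'
#' Two-group voxel grids with Gaussian noise everywhere and a constant
#' effect added for group-2 subjects on planted voxel clusters.
#'
#' @slot gridShape Integer(3).
#' @slot mask Logical 3-D array.
#' @slot clusterVoxels List of 0-based integer voxel matrices (i, j, k
#'   columns), one per planted cluster.
#' @slot effectSizes Numeric, one effect per planted cluster.
#' @slot noiseSd Positive noise sd.
#' @slot nPerGroup Integer(2), subjects per group.
#' @slot seed Integer RNG seed.
#'
#' @seealso [gridSpec()], [simulateGrids()]
#' @export
setClass("GridSpec",
  representation(gridShape = "integer", mask = "array",
                 clusterVoxels = "list", effectSizes = "numeric",
                 noiseSd = "numeric", nPerGroup = "integer",
                 seed = "integer")
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be three positive integers")
  if (!identical(dim(object@mask), object@gridShape))
    msg <- c(msg, "mask shape must equal gridShape")
  if (!any(object@mask)) msg <- c(msg, "mask is empty")
  if (length(object@effectSizes) != length(object@clusterVoxels))
    msg <- c(msg, "need one effect size per planted cluster")
  for (cl in object@clusterVoxels) {
    if (ncol(cl) != 3L || any(cl < 0L) ||
        any(sweep(cl, 2L, object@gridShape, ">=")))
      msg <- c(msg, "planted cluster voxels outside the grid")
    else if (!all(object@mask[cl + 1L]))
      msg <- c(msg, "planted cluster voxels outside the mask")
  }
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (length(object@nPerGroup) != 2L || any(object@nPerGroup < 2L))
    msg <- c(msg, "nPerGroup must be two counts >= 2")
  if (length(msg)) msg else TRUE
})

#' Axis-aligned cube of 0-based voxel coordinates
#'
#' @param corner Integer(3), 0-based corner.
#' @param edge Edge length in voxels.
#' @return Integer matrix of \code{edge^3} voxel rows.
#' @export
cubeVoxels <- function(corner, edge) {
  g <- expand.grid(i = corner[1] + 0:(edge - 1),
                   j = corner[2] + 0:(edge - 1),
                   k = corner[3] + 0:(edge - 1))
  as.matrix(g)
}

#' Build a grid specification
#'
#' Constructor for \linkS4class{GridSpec}. Default: a 20^3 grid, full
#' mask, one planted 5^3 cube (125 voxels) with effect 1.0 against unit
#' noise, 40 subjects per group.
#'
#' @param gridShape Integer(3) grid dimensions.
#' @param mask Logical array (default: all voxels).
#' @param clusterVoxels List of 0-based voxel matrices.
#' @param effectSizes One additive group-2 effect per cluster.
#' @param noiseSd Noise sd.
#' @param nPerGroup Subjects per group.
#' @param seed RNG seed.
#' @return A validated \linkS4class{GridSpec}.
#' @export
gridSpec <- function(gridShape = c(20L, 20L, 20L),
                     mask = array(TRUE, dim = gridShape),
                     clusterVoxels = list(cubeVoxels(c(5L, 5L, 5L), 5L)),
                     effectSizes = 1.0, noiseSd = 1.0,
                     nPerGroup = c(40L, 40L), seed = 1L) {
  clusterVoxels <- lapply(clusterVoxels, function(m) {
    storage.mode(m) <- "integer"; m
  })
  obj <- new("GridSpec", gridShape = as.integer(gridShape), mask = mask,
             clusterVoxels = clusterVoxels, effectSizes = effectSizes,
             noiseSd = noiseSd, nPerGroup = as.integer(nPerGroup),
             seed = .assertSeed(seed))
  validObject(obj)
  obj
}

#' Simulate two-group voxel grids with planted effect clusters
#'
#' @param spec A \linkS4class{GridSpec}.
#' @return List with \code{grids} (4-D array x,y,z,subject),
#'   \code{groups} (factor \code{g1}/\code{g2}) and \code{mask}.
#'   Group-2 subjects carry the additive effect on the planted voxels;
#'   everything else is N(0, noiseSd) noise. Deterministic per seed.
#'
#' @export
simulateGrids <- function(spec) {
  stopifnot(is(spec, "GridSpec"))
  validObject(spec)
  set.seed(spec@seed)
  n <- sum(spec@nPerGroup)
  d <- spec@gridShape
  arr <- array(rnorm(prod(d) * n, 0, spec@noiseSd), dim = c(d, n))
  groups <- factor(rep(c("g1", "g2"), times = spec@nPerGroup))
  g2 <- which(groups == "g2")
  for (k in seq_along(spec@clusterVoxels)) {
    vox <- spec@clusterVoxels[[k]] + 1L
    for (s in g2)
      arr[cbind(vox, s)] <- arr[cbind(vox, s)] + spec@effectSizes[k]
  }
  list(grids = arr, groups = groups, mask = spec@mask)
}
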