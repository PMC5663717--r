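#' @include AllClasses.R AllGenerics.R utils.R io.R synthetic.R
NULL

.CONFIG_DEFAULTS <- list(
  n_subjects = 473L, fit_csf = TRUE, fit_pet = TRUE,
  csf_cut = NULL, pet_cut = NULL,
  contrast = c("CSF-/PET-", "CSF+/PET-"),
  covariates = c("age", "sex", "interval_years"),
  fdr_q = 0.05, p_height = 0.001, k_min = 100L, alpha_link = 0.001,
  n_perm = 500L, direction = "positive", seed = NULL, out_dir = NULL)

#' Load and validate a pipeline run configuration
#'
#' Reads a JSON configuration, rejects unknown keys, fills defaults
#' (\code{fdr_q} 0.05, \code{p_height} 0.001, \code{k_min} 100,
#' \code{alpha_link} 0.001) and range-checks every threshold. A seed is
#' mandatory because the pipeline contains stochastic stages.
#'
#' @param path Path to a JSON file; keys are the names of
#'   \code{abstage:::.CONFIG_DEFAULTS}.
#' @return A validated named list.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  full <- .CONFIG_DEFAULTS
  full[names(cfg)] <- cfg
  if (is.null(full$out_dir))
    stop("config key 'out_dir' is required", call. = FALSE)
  if (is.null(full$seed))
    stop("config key 'seed' is required (stochastic stages present)",
         call. = FALSE)
  full$seed <- .assertSeed(full$seed)
  full$n_subjects <- .assertCount(full$n_subjects, "n_subjects", min = 10L)
  full$k_min <- .assertCount(full$k_min, "k_min")
  full$n_perm <- .assertCount(full$n_perm, "n_perm", min = 100L)
  .assertNumber(full$fdr_q, "fdr_q", lower = 0, upper = 1, strict = TRUE)
  .assertNumber(full$p_height, "p_height", lower = 0, upper = 1,
                strict = TRUE)
  .assertNumber(full$alpha_link, "alpha_link", lower = 0, upper = 1,
                strict = TRUE)
  if (!full$direction %in% c("positive", "negative"))
    stop("config key 'direction' must be 'positive' or 'negative'",
         call. = FALSE)
  if (!isTRUE(full$fit_pet) && is.null(full$pet_cut))
    stop("config: either 'pet_cut' or 'fit_pet' = true is required",
         call. = FALSE)
  if (!isTRUE(full$fit_csf) && is.null(full$csf_cut))
    stop("config: either 'csf_cut' or 'fit_csf' = true is required",
         call. = FALSE)
  if (length(full$contrast) != 2L ||
      !all(full$contrast %in% STAGE_LABELS))
    stop("config key 'contrast' must name two stage labels",
         call. = FALSE)
  full
}

## block atlas over a grid: seven networks as bands along the first axis
.blockAtlas <- function(dim) {
  nets <- NETWORK_LABELS[1:7]
  band <- ceiling(seq_len(dim[1]) / dim[1] * 7)
  array(rep(nets[band], times = prod(dim[2:3])), dim = dim)
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes, in order: (1) \emph{simulate} — draw a synthetic cohort,
#' voxel grids with a planted cluster, and connectivity matrices with a
#' planted CSF-correlated component; (2) \emph{stage} — fit mixture
#' cut-offs (or use supplied ones) and assign CSF/PET stages;
#' (3) \emph{rates} — per-ROI accumulation-rate contrast with BH
#' correction; (4) \emph{overlap} — voxelwise t-map, cluster extraction
#' and atlas-overlap report; (5) \emph{component} — the permutation
#' network-component test. All outputs, and a manifest recording the
#' seed, stage status, row counts, wall times and output-file MD5
#' hashes, are written under \code{config$out_dir}. Reruns with the same
#' config reproduce identical stochastic outputs.
#'
#' @param config Validated configuration from [loadRunConfig()] (or an
#'   equivalent named list).
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "abstage",
                   version = as.character(utils::packageVersion("abstage")),
                   seed = config$seed, stages = list())
  files <- character(0)
  state <- new.env(parent = emptyenv())

  runStage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      manifest$partial <<- TRUE
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    res$wall_s <- round(proc.time()[["elapsed"]] - t0, 3)
    res$status <- "complete"
    manifest$stages[[name]] <<- res
  }

  runStage("simulate", function() {
    panel <- simulateCohort(cohortSpec(nSubjects = config$n_subjects,
                                       seed = config$seed))
    grids <- simulateGrids(gridSpec(seed = .childSeed(config$seed, 1L)))
    connSim <- simulateConnectivity(
      connectivitySpec(seed = .childSeed(config$seed, 2L)))
    state$panel <- panel; state$grids <- grids; state$conn <- connSim
    f <- file.path(out, "cohort.tsv")
    writePanelTsv(panel, f, file.path(out, "roi_classes.tsv"))
    files <<- c(files, f)
    list(n_subjects = ncol(panel), n_rois = nrow(panel))
  })

  runStage("stage", function() {
    cd <- SummarizedExperiment::colData(state$panel)
    csfCut <- config$csf_cut
    petCut <- config$pet_cut
    if (is.null(csfCut)) {
      fit <- fitMixtureCutoff(cd$csf_ab42,
                              seed = .childSeed(config$seed, 3L))
      writeMixtureJson(fit, file.path(out, "csf_mixture.json"))
      csfCut <- cutoff(fit)
    }
    if (is.null(petCut)) {
      fit <- fitMixtureCutoff(cd$pet_suvr,
                              seed = .childSeed(config$seed, 4L))
      writeMixtureJson(fit, file.path(out, "pet_mixture.json"))
      petCut <- cutoff(fit)
    }
    stage <- classifyStage(cd$csf_ab42, cd$pet_suvr, csfCut, petCut)
    csfLow <- flagCsfLow(cd$csf_ab42,
                         bandLo = csfCut,
                         bandHi = csfCut * 750 / 517) &
      stage == "CSF-/PET-"
    SummarizedExperiment::colData(state$panel)$stage <- stage
    SummarizedExperiment::colData(state$panel)$csf_low <- csfLow
    f <- file.path(out, "staged.tsv")
    .writeTsv(data.frame(subject = cd$subject, stage = as.character(stage),
                         csf_low = csfLow), f)
    files <<- c(files, f)
    list(csf_cut = csfCut, pet_cut = petCut,
         n_by_stage = as.list(table(stage)))
  })

  runStage("rates", function() {
    res <- roiContrast(state$panel, "stage", config$contrast,
                       covariates = config$covariates, fdrQ = config$fdr_q)
    f <- file.path(out, "rates.tsv")
    .writeTsv(res, f)
    files <<- c(files, f)
    list(n_rois = nrow(res), n_significant = sum(res$bh_significant),
         n_dropped = attr(res, "n_dropped"))
  })

  runStage("overlap", function() {
    g <- state$grids
    map <- adjustedTtestMap(g$grids, g$groups, mask = g$mask)
    clusters <- extractClusters(map, pHeight = config$p_height,
                                kMin = config$k_min)
    writeNiftiVolume(tMap(map), file.path(out, "tmap.nii.gz"))
    writeNiftiVolume(clusterLabelArray(clusters, dim(tMap(map))),
                     file.path(out, "cluster_labels.nii.gz"))
    f <- file.path(out, "clusters.tsv")
    .writeTsv(clusterTable(clusters), f)
    files <<- c(files, f)
    res <- list(n_clusters = length(clusters))
    if (length(clusters)) {
      atlas <- .blockAtlas(dim(tMap(map)))
      ov <- overlapDistribution(clusters[[1L]], atlas)
      fo <- file.path(out, "overlap.tsv")
      .writeTsv(ov, fo)
      files <<- c(files, fo)
      res$top_network <- ov$network[1L]
    }
    res
  })

  runStage("component", function() {
    cs <- state$conn
    comp <- permutationTest(cs$conn, cs$csf, covars = cs$subjects,
                            alphaLink = config$alpha_link,
                            nPerm = config$n_perm,
                            seed = .childSeed(config$seed, 5L),
                            direction = config$direction)
    writeComponentDir(comp, file.path(out, "component"))
    files <<- c(files, file.path(out, "component", "component_summary.json"))
    list(S = componentStat(comp), p = permPvalue(comp),
         n_links = nrow(componentLinks(comp)))
  })

  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
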