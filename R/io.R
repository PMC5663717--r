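#' @include AllClasses.R AllGenerics.R utils.R
NULL

## canonical tabular dialect: TSV, header row, UTF-8, '.' decimal
.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a longitudinal SUVR panel as TSV
#'
#' One row per subject: the subject-level columns of \code{colData}
#' followed by \code{baseline_<roi>} and \code{followup_<roi>} columns.
#' ROI classes are written alongside as a second TSV (\code{roi},
#' \code{roi_class}) when \code{roiClassPath} is given.
#'
#' @param panel A \linkS4class{RoiSuvrPanel}.
#' @param path Output TSV path.
#' @param roiClassPath Optional path for the ROI-class table.
#' @return \code{path}, invisibly (writer); a
#'   \linkS4class{RoiSuvrPanel} (reader).
#' @export
writePanelTsv <- function(panel, path, roiClassPath = NULL) {
  stopifnot(is(panel, "RoiSuvrPanel"))
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  b <- t(suvrBaseline(panel))
  f <- t(suvrFollowup(panel))
  colnames(b) <- paste0("baseline_", colnames(b))
  colnames(f) <- paste0("followup_", colnames(f))
  .writeTsv(cbind(cd, b, f), path)
  if (!is.null(roiClassPath)) {
    rc <- data.frame(roi = rownames(panel),
                     roi_class = SummarizedExperiment::rowData(panel)$roi_class)
    .writeTsv(rc, roiClassPath)
  }
  invisible(path)
}

#' @rdname writePanelTsv
#' @export
readPanelTsv <- function(path, roiClassPath = NULL) {
  df <- .readTsv(path)
  bCols <- grep("^baseline_", colnames(df), value = TRUE)
  fCols <- grep("^followup_", colnames(df), value = TRUE)
  rois <- sub("^baseline_", "", bCols)
  if (!identical(rois, sub("^followup_", "", fCols)))
    stop("baseline/followup ROI columns do not match", call. = FALSE)
  meta <- df[, setdiff(colnames(df), c(bCols, fCols)), drop = FALSE]
  if ("stage_true" %in% colnames(meta))
    meta$stage_true <- factor(meta$stage_true, levels = STAGE_LABELS)
  baseline <- t(as.matrix(df[, bCols, drop = FALSE]))
  followup <- t(as.matrix(df[, fCols, drop = FALSE]))
  rownames(baseline) <- rownames(followup) <- rois
  ids <- if ("subject" %in% colnames(meta)) meta$subject
         else sprintf("subj%04d", seq_len(nrow(df)))
  colnames(baseline) <- colnames(followup) <- ids
  roiClass <- rep("other", length(rois))
  if (!is.null(roiClassPath)) {
    rc <- .readTsv(roiClassPath)
    roiClass <- rc$roi_class[match(rois, rc$roi)]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(suvr_baseline = baseline, suvr_followup = followup),
    colData = S4Vectors::DataFrame(meta, row.names = ids),
    rowData = S4Vectors::DataFrame(roi_class = roiClass,
                                   row.names = rois))
  new("RoiSuvrPanel", se)
}

#' Write / read per-subject connectivity matrices
#'
#' One whitespace-delimited dense matrix file per subject
#' (\code{<id>.txt}) plus a \code{node_labels.tsv} (columns \code{node},
#' \code{network}).
#'
#' @param conn A \linkS4class{ConnectivityArray}.
#' @param dir Directory (created if needed).
#' @return \code{dir} invisibly (writer); a
#'   \linkS4class{ConnectivityArray} (reader).
#' @export
writeConnectivityDir <- function(conn, dir) {
  stopifnot(is(conn, "ConnectivityArray"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  z <- connValues(conn)
  for (s in seq_len(dim(z)[3])) {
    utils::write.table(z[, , s],
                       file.path(dir, paste0(conn@subjectIds[s], ".txt")),
                       sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  .writeTsv(data.frame(node = seq_len(dim(z)[1]),
                       network = nodeLabels(conn)),
            file.path(dir, "node_labels.tsv"))
  invisible(dir)
}

#' @rdname writeConnectivityDir
#' @export
readConnectivityDir <- function(dir) {
  labFile <- file.path(dir, "node_labels.tsv")
  if (!file.exists(labFile))
    stop("missing node_labels.tsv in ", dir, call. = FALSE)
  labs <- .readTsv(labFile)
  files <- sort(setdiff(list.files(dir, pattern = "\\.txt$"), character(0)))
  if (!length(files)) stop("no matrix files in ", dir, call. = FALSE)
  mats <- lapply(files, function(f)
    as.matrix(utils::read.table(file.path(dir, f))))
  connectivityArray(mats, labs$network,
                    subjectIds = sub("\\.txt$", "", files))
}

#' Write a fitted mixture as JSON
#'
#' @param fit A \linkS4class{MixtureFit}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMixtureJson <- function(fit, path) {
  stopifnot(is(fit, "MixtureFit"))
  jsonlite::write_json(mixtureParams(fit)[c("weights", "means", "sds")] |>
                         c(list(cutoff = cutoff(fit),
                                loglik = fit@loglik, n = fit@n)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the outputs of a network-component run
#'
#' Writes the component edge list (\code{component_links.tsv}:
#' node_i, node_j, r), the per-network-pair counts
#' (\code{network_pairs.tsv}) and a JSON summary (S, Spearman r, p,
#' r0, direction, n_perm, seed).
#'
#' @param comp A \linkS4class{NetworkComponent}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeComponentDir <- function(comp, dir) {
  stopifnot(is(comp, "NetworkComponent"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  links <- componentLinks(comp)
  .writeTsv(data.frame(node_i = links$i, node_j = links$j, r = links$r),
            file.path(dir, "component_links.tsv"))
  if (nrow(links))
    .writeTsv(networkBreakdown(comp), file.path(dir, "network_pairs.tsv"))
  jsonlite::write_json(
    list(S = componentStat(comp), spearman_r = comp@spearmanR,
         p = permPvalue(comp), r0 = comp@r0, direction = comp@direction,
         n_perm = comp@nPerm, n_links = nrow(links), seed = comp@seed),
    file.path(dir, "component_summary.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}

#' Read / write 3-D grids as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} so volumetric inputs and outputs
#' (grids, t-maps, p-maps, cluster label maps) use the standard format;
#' any affine in the source header is carried through untouched.
#'
#' @param x Numeric/integer 3-D array (writer).
#' @param path NIfTI file path.
#' @return \code{path} invisibly (writer); a plain array (reader).
#' @export
writeNiftiVolume <- function(x, path) {
  RNifti::writeNifti(x, path)
  invisible(path)
}

#' @rdname writeNiftiVolume
#' @export
readNiftiVolume <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}
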