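#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Annual SUVR change
#'
#' Linear annualised change, \code{(followup - baseline) / years},
#' applied elementwise. When \code{baseline} and \code{followup} are
#' ROI x subject matrices, \code{years} may be a per-subject vector
#' (recycled down each column).
#'
#' @param baseline,followup Numeric vectors or ROI x subject matrices
#'   (SUVR).
#' @param years Positive scalar or per-subject vector of inter-scan
#'   intervals.
#' @return Change in SUVR per year, same shape as the inputs.
#'
#' @examples
#' annualChange(0.80, 0.84, 2)   # 0.02 SUVR/yr
#' @export
annualChange <- function(baseline, followup, years) {
  if (!all(is.finite(years)) || any(years <= 0))
    stop("'years' must be finite and > 0", call. = FALSE)
  d <- followup - baseline
  if (is.matrix(d) && length(years) > 1L) {
    if (length(years) != ncol(d))
      stop("'years' must have one entry per subject (column)", call. = FALSE)
    sweep(d, 2L, years, "/")
  } else {
    d / years
  }
}

#' Annual SUVR change for a longitudinal panel
#'
#' @param panel A \linkS4class{RoiSuvrPanel}.
#' @return ROI x subject matrix of SUVR/yr.
#' @rdname annualChange
#' @export
panelAnnualChange <- function(panel) {
  stopifnot(is(panel, "RoiSuvrPanel"))
  annualChange(suvrBaseline(panel), suvrFollowup(panel), scanInterval(panel))
}

#' Percent annual accumulation rate
#'
#' Expresses a yearly SUVR change as a percentage of the subject's own
#' baseline SUVR, \code{100 * change / baseline}, making rates
#' comparable across tracers and reference regions.
#'
#' @param change Yearly SUVR change (vector or matrix).
#' @param baseline Baseline SUVR, strictly positive, same shape.
#' @return Percent per year.
#'
#' @examples
#' percentRate(0.02, 0.80)   # 2.5 %/yr
#' @export
percentRate <- function(change, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("'baseline' must be finite and > 0", call. = FALSE)
  100 * change / baseline
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control: with ordered p values
#' \code{p_(1) <= ... <= p_(m)}, find the largest k with
#' \code{p_(k) <= k q / m}; hypotheses of rank up to k are significant.
#'
#' @param pvals Numeric vector of p values in [0, 1].
#' @param q Target false discovery rate (default 0.05).
#' @return Logical vector of significance flags.
#'
#' @examples
#' bhFdr(c(0.001, 0.01, 0.02, 0.04, 0.9))   # four discoveries
#' @export
bhFdr <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  .assertNumber(q, "q", lower = 0, upper = 1, strict = TRUE)
  p.adjust(pvals, method = "BH") <= q
}

#' Per-ROI accumulation-rate contrast between two stage groups
#'
#' Fits, for every ROI, an ordinary least-squares general linear model
#' with the yearly SUVR change as dependent variable and the stage-group
#' indicator plus covariates as predictors, reporting the two-sided
#' group-coefficient test. Significance is assessed on SUVR/yr;
#' per-group effect sizes are reported as percent annual rates (each
#' subject's change divided by their own baseline, averaged per group)
#' with normal-theory 95% confidence intervals of the mean. P values are
#' corrected across ROIs by Benjamini-Hochberg at \code{fdrQ}.
#'
#' @param panel A \linkS4class{RoiSuvrPanel}; covariates are taken from
#'   its \code{colData}.
#' @param groups Either the name of a \code{colData} column holding the
#'   stage labels, or a vector of labels (one per subject).
#' @param groupPair Character(2): the two group labels to contrast; the
#'   reported coefficient is \code{groupPair[2] - groupPair[1]}.
#' @param covariates Character vector of \code{colData} column names to
#'   adjust for (default \code{c("age", "sex", "interval_years")});
#'   use \code{character(0)} for an unadjusted contrast.
#' @param fdrQ False discovery rate for the BH flags (default 0.05).
#' @return Data frame, one row per ROI, sorted by p value: columns
#'   \code{roi}, \code{estimate} (SUVR/yr), \code{t}, \code{p},
#'   \code{bh_significant}, and per-group percent-rate summaries
#'   \code{meanPct_*}, \code{ciLoPct_*}, \code{ciHiPct_*}. Attribute
#'   \code{"n_dropped"} counts subjects excluded for incomplete data.
#'
#' @export
roiContrast <- function(panel, groups, groupPair,
                        covariates = c("age", "sex", "interval_years"),
                        fdrQ = 0.05) {
  stopifnot(is(panel, "RoiSuvrPanel"))
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  if (is.character(groups) && length(groups) == 1L) {
    if (!groups %in% colnames(cd))
      stop(sprintf("colData has no column '%s'", groups), call. = FALSE)
    groups <- cd[[groups]]
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(panel))
    stop("'groups' must have one label per subject", call. = FALSE)
  if (length(groupPair) != 2L)
    stop("'groupPair' must name exactly two groups", call. = FALSE)
  if (length(unique(groupPair)) != 2L)
    stop("no contrast: the two groups in 'groupPair' are identical",
         call. = FALSE)
  missingCov <- setdiff(covariates, colnames(cd))
  if (length(missingCov))
    stop("covariate column(s) not in colData: ",
         paste(missingCov, collapse = ", "), call. = FALSE)

  keep <- groups %in% groupPair
  covDf <- cd[, covariates, drop = FALSE]
  complete <- complete.cases(covDf) & !is.na(groups)
  nDropped <- sum(keep & !complete)
  keep <- keep & complete
  if (sum(keep & groups == groupPair[1]) < 2L ||
      sum(keep & groups == groupPair[2]) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)

  g <- as.numeric(groups[keep] == groupPair[2])
  if (length(unique(g)) < 2L)
    stop("no contrast: the group indicator is constant", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, group = g,
             .covarMatrix(covDf[keep, , drop = FALSE], sum(keep)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  rate <- panelAnnualChange(panel)[, keep, drop = FALSE]     # ROI x subj
  pct <- percentRate(rate, suvrBaseline(panel)[, keep, drop = FALSE])
  Y <- t(rate)                                               # subj x ROI
  df <- nrow(X) - ncol(X)
  coefs <- qr.coef(qrX, Y)
  res <- qr.resid(qrX, Y)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  gIdx <- 2L
  se <- sqrt(sigma2 * XtXinv[gIdx, gIdx])
  tstat <- coefs[gIdx, ] / se
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)

  groupSummary <- function(label) {
    m <- pct[, groups[keep] == label, drop = FALSE]
    mu <- rowMeans(m)
    n <- ncol(m)
    sem <- apply(m, 1L, sd) / sqrt(n)
    half <- qt(0.975, n - 1L) * sem
    list(mean = mu, lo = mu - half, hi = mu + half)
  }
  s1 <- groupSummary(groupPair[1])
  s2 <- groupSummary(groupPair[2])

  out <- data.frame(
    roi = rownames(panel), estimate = coefs[gIdx, ], t = tstat, p = pval,
    bh_significant = bhFdr(pval, fdrQ),
    meanPct_1 = s1$mean, ciLoPct_1 = s1$lo, ciHiPct_1 = s1$hi,
    meanPct_2 = s2$mean, ciLoPct_2 = s2$lo, ciHiPct_2 = s2$hi,
    row.names = NULL, check.names = FALSE
  )
  names(out) <- sub("_1$", paste0("_", groupPair[1]), names(out))
  names(out) <- sub("_2$", paste0("_", groupPair[2]), names(out))
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- nDropped
  attr(out, "groupPair") <- groupPair
  out
}

#' Nonparametric rank tests for small stage subgroups
#'
#' Thin, contract-checked front end to the classical rank tests used
#' when group sizes are too small for normal-theory GLMs: Mann-Whitney U
#' (two independent samples), Wilcoxon signed rank (paired differences)
#' and Kruskal-Wallis (two or more groups). Exact p values are used for
#' small untied samples (combined n below 50 for the two-sample tests),
#' a normal approximation with tie correction otherwise.
#'
#' @param x Numeric sample; for \code{"kruskal_wallis"} a list of
#'   samples is also accepted.
#' @param y Second sample (\code{"mann_whitney"}), paired second
#'   measurement (\code{"wilcoxon_signed"}; omit \code{y} to pass
#'   differences directly in \code{x}), or grouping factor
#'   (\code{"kruskal_wallis"} when \code{x} is a vector).
#' @param kind One of \code{"mann_whitney"}, \code{"wilcoxon_signed"},
#'   \code{"kruskal_wallis"}.
#' @param alternative Test direction (two-sample tests), default
#'   \code{"two.sided"}.
#' @return List with \code{statistic}, \code{p.value} and \code{method}.
#'
#' @examples
#' rankTests(c(1, 2), c(3, 4), kind = "mann_whitney",
#'           alternative = "less")   # U = 0, exact p = 1/6
#' @export
rankTests <- function(x, y = NULL,
                      kind = c("mann_whitney", "wilcoxon_signed",
                               "kruskal_wallis"),
                      alternative = "two.sided") {
  kind <- match.arg(kind)
  res <- switch(kind,
    mann_whitney = {
      if (is.null(y)) stop("'y' is required for mann_whitney", call. = FALSE)
      wilcox.test(x, y, alternative = alternative)
    },
    wilcoxon_signed = {
      d <- if (is.null(y)) x else x - y
      if (all(d == 0))
        stop("all paired differences are zero", call. = FALSE)
      wilcox.test(d, alternative = alternative)
    },
    kruskal_wallis = {
      if (is.list(x)) kruskal.test(x)
      else {
        if (is.null(y))
          stop("'y' (grouping) is required for kruskal_wallis",
               call. = FALSE)
        kruskal.test(x, as.factor(y))
      }
    })
  list(statistic = unname(res$statistic), p.value = res$p.value,
       method = res$method)
}
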