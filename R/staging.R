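#' @include AllClasses.R AllGenerics.R utils.R
NULL

## One EM run from given responsibilities; returns NULL on degenerate fit.
.emRun <- function(x, resp, maxIter, tol, sdFloor) {
  n <- length(x)
  loglik <- -Inf
  nIter <- 0L
  converged <- FALSE
  w <- mu <- sg <- NULL
  for (it in seq_len(maxIter)) {
    ## M step
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    if (any(sg < sdFloor)) return(NULL)
    ## E step
    d1 <- w[1] * dnorm(x, mu[1], sg[1])
    d2 <- w[2] * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    if (any(tot <= 0)) return(NULL)
    ll <- sum(log(tot))
    resp <- cbind(d1 / tot, d2 / tot)
    nIter <- it
    if (is.finite(loglik) && abs(ll - loglik) < tol * (abs(ll) + tol)) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
  }
  list(w = w, mu = mu, sg = sg, loglik = loglik, nIter = nIter,
       converged = converged)
}

## posterior-0.5 crossing between the (sorted) component means
.posteriorCutoff <- function(w, mu, sg) {
  f <- function(x) log(w[1]) + dnorm(x, mu[1], sg[1], log = TRUE) -
    log(w[2]) - dnorm(x, mu[2], sg[2], log = TRUE)
  eps <- 1e-9 * max(1, abs(mu[2] - mu[1]))
  lo <- mu[1] + eps
  hi <- mu[2] - eps
  if (hi <= lo) return(NA_real_)
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Fit a two-component Gaussian mixture and derive an abnormality cut-off
#'
#' Fits a univariate two-component Gaussian mixture by
#' expectation-maximisation and derives the biomarker abnormality cut-off
#' as the point between the two component means where the posterior
#' probability of belonging to either component equals 0.5 — the
#' decision boundary under equal misclassification cost. This is the
#' standard unbiased way of setting amyloid biomarker thresholds when no
#' external reference exists: abnormality is defined by the data's own
#' bimodality, never by diagnosis.
#'
#' EM is multimodal, so the fit is restarted: once from a deterministic
#' median split (values below the sample median seed the lower
#' component) and \code{nRestarts} times from random soft assignments.
#' The restart with the highest log-likelihood wins. Restarts whose
#' components collapse (a component standard deviation falling below
#' \code{1e-6} of the sample standard deviation, or an empty component)
#' are discarded.
#'
#' @param values Numeric vector of biomarker measurements (at least 20
#'   finite values with positive sample standard deviation).
#' @param maxIter Maximum EM iterations per restart (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param nRestarts Number of random restarts in addition to the median
#'   split (default 10).
#' @param seed RNG seed for the random restarts (default 1).
#' @return A \linkS4class{MixtureFit}.
#'
#' @examples
#' set.seed(42)
#' suvr <- c(rnorm(300, 0.74, 0.05), rnorm(200, 1.05, 0.12))
#' fit <- fitMixtureCutoff(suvr)
#' cutoff(fit)
#' @export
fitMixtureCutoff <- function(values, maxIter = 500L, tol = 1e-8,
                             nRestarts = 10L, seed = 1L) {
  x <- values[is.finite(values)]
  if (length(x) < 20L)
    stop("need at least 20 finite values to fit a mixture", call. = FALSE)
  sx <- sd(x)
  if (!(sx > 0))
    stop("values have zero sample standard deviation", call. = FALSE)
  maxIter <- .assertCount(maxIter, "maxIter")
  nRestarts <- .assertCount(nRestarts, "nRestarts", min = 0L)
  .assertNumber(tol, "tol", lower = 0, strict = TRUE, upper = 1)
  seed <- .assertSeed(seed)

  sdFloor <- 1e-6 * sx
  n <- length(x)

  ## deterministic initialization: hard split at the sample median
  init <- list((x <= stats::median(x)) * 1)
  set.seed(seed)
  for (r in seq_len(nRestarts)) {
    u <- runif(n)
    init[[r + 1L]] <- (u < runif(1, 0.3, 0.7)) * 1
  }

  best <- NULL
  for (z1 in init) {
    if (min(sum(z1), n - sum(z1)) < 2) next
    resp <- cbind(z1, 1 - z1)
    fit <- .emRun(x, resp, maxIter, tol, sdFloor)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("degenerate fit: all EM restarts collapsed a component",
         call. = FALSE)
  if (!best$converged)
    stop(sprintf("EM did not converge within %d iterations in any restart",
                 maxIter), call. = FALSE)

  ord <- order(best$mu)
  w <- best$w[ord]; mu <- best$mu[ord]; sg <- best$sg[ord]
  if (diff(mu) < 1e-6 * sx)
    stop("no separation: the two fitted components share a mean",
         call. = FALSE)
  cut <- .posteriorCutoff(w, mu, sg)
  if (!is.finite(cut))
    stop("no posterior-0.5 crossing between the component means ",
         "(components are not separated)", call. = FALSE)

  new("MixtureFit", weights = w, means = mu, sds = sg, cutoff = cut,
      loglik = best$loglik, nIter = as.integer(best$nIter),
      converged = best$converged, n = as.integer(n))
}

#' Assign CSF/PET amyloid stages
#'
#' Classifies subjects into the four CSF/PET amyloid stages from their
#' CSF A-beta-42 concentration and amyloid-PET SUVR. CSF is abnormal
#' (CSF+) when strictly below the CSF cut-off; PET is abnormal (PET+)
#' when strictly above the PET cut-off, so boundary values are normal.
#' \code{"CSF+/PET-"} marks early accumulators, \code{"CSF+/PET+"} late
#' accumulators and \code{"CSF-/PET-"} non-accumulators.
#'
#' @param csf Numeric vector, CSF A-beta-42 (e.g. ng/L).
#' @param pet Numeric vector, amyloid-PET SUVR.
#' @param csfCut,petCut Positive scalar cut-offs in the same units.
#' @return Factor with levels \code{c("CSF-/PET-", "CSF+/PET-",
#'   "CSF+/PET+", "CSF-/PET+")}. Missing inputs yield \code{NA}
#'   (explicitly unclassifiable) with a warning, never a silent default.
#'
#' @examples
#' classifyStage(c(165, 234, 136), c(0.78, 0.74, 0.93),
#'               csfCut = 192, petCut = 0.872)
#' @export
classifyStage <- function(csf, pet, csfCut, petCut) {
  .assertNumber(csfCut, "csfCut", lower = 0, strict = TRUE)
  .assertNumber(petCut, "petCut", lower = 0, strict = TRUE)
  if (length(csf) != length(pet))
    stop("'csf' and 'pet' must have equal length", call. = FALSE)
  miss <- !is.finite(csf) | !is.finite(pet)
  if (any(miss))
    warning(sprintf("%d subject(s) unclassifiable (missing CSF or PET)",
                    sum(miss)))
  csfPos <- csf < csfCut
  petPos <- pet > petCut
  lab <- ifelse(csfPos,
                ifelse(petPos, "CSF+/PET+", "CSF+/PET-"),
                ifelse(petPos, "CSF-/PET+", "CSF-/PET-"))
  lab[miss] <- NA_character_
  factor(lab, levels = STAGE_LABELS)
}

#' Flag near-threshold ("CSF-low") normal CSF A-beta-42
#'
#' Biomarker-normal subjects whose CSF A-beta-42 sits just above the
#' abnormality cut-off have a high risk of converting and are treated as
#' very early accumulators. This flags values inside the closed band
#' \code{[bandLo, bandHi]} (default 517–750 ng/L, the band used with the
#' INNOTEST assay whose abnormality cut-off is 517 ng/L).
#'
#' @param csf Numeric vector of CSF A-beta-42 values.
#' @param bandLo,bandHi Band endpoints (inclusive); \code{bandLo} must be
#'   below \code{bandHi}.
#' @return Logical vector (\code{NA} for missing input).
#'
#' @examples
#' flagCsfLow(c(516, 517, 600, 750, 751))
#' @export
flagCsfLow <- function(csf, bandLo = 517, bandHi = 750) {
  .assertNumber(bandLo, "bandLo")
  .assertNumber(bandHi, "bandHi")
  if (bandLo >= bandHi)
    stop("inverted band: 'bandLo' must be < 'bandHi'", call. = FALSE)
  csf >= bandLo & csf <= bandHi
}
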