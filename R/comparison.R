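#' Two-sample Dirichlet-Multinomial likelihood-ratio score
#'
#' The site score z contrasts separate Dirichlet-Multinomial fits for the
#' two replicate samples against a single pooled fit under the null
#' hypothesis that both samples share one underlying base-probability
#' distribution:
#' \deqn{z = \left[\ell(\hat\alpha^I; \tilde D^I) +
#'   \ell(\hat\alpha^{II}; \tilde D^{II})\right] -
#'   \left[\ell(\hat\alpha^{I,II}; \tilde D^I) +
#'   \ell(\hat\alpha^{I,II}; \tilde D^{II})\right],}
#' where \eqn{\hat\alpha^{I,II}} is fitted on the union of both samples'
#' adjusted count vectors. z is symmetric in the two samples, invariant to
#' replicate order, zero (to optimizer tolerance) when the samples are
#' identical, and non-negative up to optimizer tolerance because the
#' pooled fit is a restriction of the separate fits.
#'
#' @param recsI,recsII Lists of replicate records (one sample each), as
#'   stored in a \linkS4class{SiteTallySet}.
#' @param epsilon Pseudocount noise term (default 0.01).
#' @return List with elements \code{z}, \code{fitI}, \code{fitII},
#'   \code{fitPooled}.
#' @seealso [callSites()], [fitAlpha()]
#' @export
zScore <- function(recsI, recsII, epsilon = 0.01) {
  if (length(recsI) < 1L || length(recsII) < 1L) {
    stop("both samples must contain at least one replicate")
  }
  XI <- .adjustedMatrix(recsI, epsilon)
  XII <- .adjustedMatrix(recsII, epsilon)
  fitI <- fitAlpha(XI)
  fitII <- fitAlpha(XII)
  fitP <- fitAlpha(rbind(XI, XII))
  # The pooled model is nested in the separate one, so the separate fits
  # must dominate the pooled parameters on their own data and z must be
  # non-negative. The fit is duplication-invariant (see .momStart), so
  # identical samples give z = 0 exactly; if a separate fit of
  # non-identical data stalled below the pooled evaluation, restart it
  # from the pooled optimum -- the fixed-point iteration ascends, so the
  # refit dominates that evaluation by construction.
  aP <- concentration(fitP)
  llIatP <- sum(logDirMult(XI, aP))
  llIIatP <- sum(logDirMult(XII, aP))
  # slack guards against refitting on mere round-off between equivalent
  # likelihood evaluations (which would break the duplication symmetry)
  slack <- 1e-6
  if (fitI@logLik < llIatP - slack) fitI <- fitAlpha(XI, start = aP)
  if (fitII@logLik < llIIatP - slack) fitII <- fitAlpha(XII, start = aP)
  z <- (fitI@logLik + fitII@logLik) - (llIatP + llIIatP)
  list(z = z, fitI = fitI, fitII = fitII, fitPooled = fitP)
}

## Distinct bases observed across the raw counts of a list of records.
.observedBases <- function(recs) {
  pooled <- Reduce(`+`, lapply(recs, `[[`, "counts"))
  BASES[pooled > 0L]
}

#' Equalize confidence between unbalanced read stacks
#'
#' Very deep, mono-allelic read stacks (typically the genomic DNA sample)
#' can dominate the likelihood and overstate confidence relative to a
#' shallow, poly-allelic partner. When exactly one side shows a single
#' observed base across all its replicates \emph{and} its total coverage
#' exceeds the other side's by more than \code{triggerRatio}, that side is
#' replaced by a copy of the other side's replicate stacks in which every
#' non-reference call is reassigned to the reference channel (qualities of
#' the transplanted calls retained). The replacement side thereby inherits
#' the partner's replicate count and coverage profile. Otherwise the
#' inputs pass through unchanged.
#'
#' @param recsI,recsII Lists of replicate records.
#' @param refBase Reference base at the site (\code{"A","C","G","T"}).
#' @param triggerRatio Coverage ratio triggering the replacement
#'   (default 2).
#' @return List with possibly modified \code{recsI}, \code{recsII} and a
#'   logical \code{balanced}.
#' @export
balanceCoverage <- function(recsI, recsII, refBase, triggerRatio = 2) {
  stopifnot(refBase %in% BASES)
  covI <- sum(vapply(recsI, function(r) sum(r$counts), numeric(1)))
  covII <- sum(vapply(recsII, function(r) sum(r$counts), numeric(1)))
  monoI <- length(.observedBases(recsI)) == 1L
  monoII <- length(.observedBases(recsII)) == 1L

  toRef <- function(rec) {
    counts <- rec$counts
    quals <- rec$quals
    moved <- unlist(quals[BASES != refBase], use.names = FALSE)
    newCounts <- setNames(integer(4L), BASES)
    newCounts[refBase] <- sum(counts)
    newQuals <- lapply(BASES, function(b) integer(0))
    names(newQuals) <- BASES
    newQuals[[refBase]] <- c(quals[[refBase]], moved)
    list(counts = newCounts, quals = newQuals, ctx = rec$ctx)
  }

  if (monoI && !monoII && covI > triggerRatio * covII) {
    list(recsI = lapply(recsII, toRef), recsII = recsII, balanced = TRUE)
  } else if (monoII && !monoI && covII > triggerRatio * covI) {
    list(recsI = recsI, recsII = lapply(recsI, toRef), balanced = TRUE)
  } else {
    list(recsI = recsI, recsII = recsII, balanced = FALSE)
  }
}

## Default score thresholds selected on the in-silico benchmark:
## genomic-vs-RNA (RDD) 1.15, RNA-vs-RNA (RRD) 1.56.
defaultThreshold <- function(mode) {
  switch(mode, RDD = 1.15, RRD = 1.56,
         stop("unknown mode: ", mode))
}

#' Score and call all sites of a tally set
#'
#' For every site: optionally applies coverage balancing, computes the
#' likelihood-ratio score z, evaluates the artifact filter panel, and
#' declares the site \code{passed} when no filter flags fire and z meets
#' the score threshold. Sites where any replicate has zero retained
#' coverage are skipped with a message.
#'
#' @param tally A \linkS4class{SiteTallySet}.
#' @param threshold Score threshold; defaults to 1.15 in RDD mode and 1.56
#'   in RRD mode.
#' @param panel A \linkS4class{FilterPanel}; positional distance filters
#'   are skipped (with one warning) when the tally has no read context.
#' @param epsilon Pseudocount noise term.
#' @param balance Apply coverage balancing (default \code{TRUE}).
#' @param triggerRatio Coverage ratio triggering balancing.
#' @return A \code{GRanges} parallel to the retained sites with metadata
#'   columns \code{ref}, \code{z}, \code{filter} (comma-joined flags, "."
#'   if none), \code{balanced}, \code{passed}, and the per-replicate raw
#'   counts \code{countsI}/\code{countsII} as "A,C,G,T" strings joined by
#'   ";".
#' @examples
#' sim <- simulateDataset("RDD", nSites = 20, nVariant = 10, seed = 1)
#' calls <- callSites(sim$tally)
#' table(calls$passed)
#' @export
callSites <- function(tally, threshold = NULL, panel = FilterPanel(),
                      epsilon = 0.01, balance = TRUE, triggerRatio = 2) {
  stopifnot(is(tally, "SiteTallySet"))
  mode <- comparisonMode(tally)
  if (is.null(threshold)) threshold <- defaultThreshold(mode)

  sites <- siteRanges(tally)
  n <- length(sites)
  keep <- rep(TRUE, n)
  z <- numeric(n)
  balancedFlag <- logical(n)
  filterStr <- character(n)
  countsIStr <- character(n)
  countsIIStr <- character(n)

  distanceActive <- any(names(FILTER_FEATURES) %in% panel@enabled)
  if (distanceActive && !hasReadContext(tally) && n > 0L) {
    warning("tally has no read context: positional distance filters ",
            "are disabled", call. = FALSE)
  }

  for (i in seq_len(n)) {
    recsI <- tally@tallyI[[i]]
    recsII <- tally@tallyII[[i]]
    covs <- c(vapply(recsI, function(r) sum(r$counts), numeric(1)),
              vapply(recsII, function(r) sum(r$counts), numeric(1)))
    if (any(covs == 0)) {
      keep[i] <- FALSE
      next
    }
    ref <- as.character(mcols(sites)$ref[i])
    countsIStr[i] <- .countsString(recsI)
    countsIIStr[i] <- .countsString(recsII)

    used <- list(recsI = recsI, recsII = recsII, balanced = FALSE)
    if (balance && ref %in% BASES) {
      used <- balanceCoverage(recsI, recsII, ref, triggerRatio)
    }
    balancedFlag[i] <- used$balanced
    sc <- zScore(used$recsI, used$recsII, epsilon)
    z[i] <- sc$z

    flags <- applyFilterPanel(
      recsI = recsI, recsII = recsII, ref = ref, panel = panel,
      mode = mode, hasContext = hasReadContext(tally)
    )
    filterStr[i] <- if (length(flags)) paste(flags, collapse = ",") else "."
  }

  if (any(!keep)) {
    message(sum(!keep), " site(s) skipped: zero retained coverage in a ",
            "replicate")
  }

  out <- sites[keep]
  mcols(out)$z <- z[keep]
  mcols(out)$filter <- filterStr[keep]
  mcols(out)$balanced <- balancedFlag[keep]
  mcols(out)$passed <- filterStr[keep] == "." & z[keep] >= threshold
  mcols(out)$countsI <- countsIStr[keep]
  mcols(out)$countsII <- countsIIStr[keep]
  metadata <- S4Vectors::metadata(out)
  metadata$threshold <- threshold
  metadata$mode <- mode
  S4Vectors::metadata(out) <- metadata
  out
}

.countsString <- function(recs) {
  paste(vapply(recs, function(r) paste(r$counts, collapse = ","),
               character(1)), collapse = ";")
}
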