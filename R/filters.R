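## Per-call distance to a named read feature; NA (feature absent from the
## read) counts as infinitely far.
.featureDistance <- function(ctx, feature) {
  d <- switch(feature,
    read_edge = pmin(ctx$dStart, ctx$dEnd),
    indel = ctx$dIndel,
    splice = ctx$dSplice,
    homopolymer = ctx$dHomo,
    stop("unknown feature: ", feature)
  )
  d[is.na(d)] <- Inf
  d
}

#' Positional distance filter
#'
#' Flags a candidate site when too many of its base calls sit close to an
#' artifact-prone read feature: the site is removed when the proportion of
#' calls whose distance to the feature is at most \code{d} reaches
#' \code{r}. False variant calls cluster near read starts/ends, INDELs,
#' splice junctions and homopolymer runs, where alignment and base-calling
#' errors concentrate.
#'
#' @param ctx Data frame of per-call read context pooled over the RNA
#'   replicates at the site (columns \code{dStart}, \code{dEnd},
#'   \code{dIndel}, \code{dSplice}, \code{dHomo}; \code{NA} = feature
#'   absent, treated as infinitely distant).
#' @param feature One of \code{"read_edge"}, \code{"indel"},
#'   \code{"splice"}, \code{"homopolymer"}.
#' @param d Distance cutoff in nucleotides.
#' @param r Proportion cutoff in (0, 1].
#' @return \code{TRUE} if the site is flagged.
#' @export
distanceFilter <- function(ctx, feature, d = 5, r = 0.5) {
  if (is.null(ctx) || nrow(ctx) == 0L) return(FALSE)
  dist <- .featureDistance(ctx, feature)
  mean(dist <= d) >= r
}

#' Genomic homozygosity filter (H)
#'
#' RNA-DNA differences are only defined at genomic positions that are
#' homozygous in the DNA sample; heterozygous positions are germline
#' variation, not editing. The site is flagged (rejected) when the pooled
#' genomic coverage is below \code{minCov} or the pooled minor-allele
#' fraction exceeds \code{maxMinorFrac}.
#'
#' @param gdnaRecs List of replicate records of the genomic DNA sample.
#' @param minCov Minimum pooled coverage (default 10).
#' @param maxMinorFrac Maximum fraction of pooled calls on non-major
#'   alleles (default 0.05).
#' @return \code{TRUE} if the site is flagged.
#' @export
homozygousFilter <- function(gdnaRecs, minCov = 10, maxMinorFrac = 0.05) {
  pooled <- Reduce(`+`, lapply(gdnaRecs, `[[`, "counts"))
  cov <- sum(pooled)
  if (cov < minCov) return(TRUE)
  minorFrac <- 1 - max(pooled) / cov
  minorFrac > maxMinorFrac
}

#' Maximum-allele filter (M)
#'
#' A true single-nucleotide difference involves at most two base types
#' (reference and variant). Sites whose pooled RNA counts show three or
#' more distinct observed bases are flagged as likely artifacts.
#'
#' @param rnaRecs List of replicate records pooled over the RNA sample(s).
#' @return \code{TRUE} if the site is flagged.
#' @export
maxAlleleFilter <- function(rnaRecs) {
  length(.observedBases(rnaRecs)) >= 3L
}

## Optional raw variant-fraction pre-screen ("V"): reproduces the common
## threshold baseline (coverage >= 10, variant frequency >= 10%, a minimum
## number of variant reads). Flags the site when the screen is NOT met.
.variantPrefilter <- function(rnaRecs, ref, minCov, minFreq, minReads) {
  pooled <- Reduce(`+`, lapply(rnaRecs, `[[`, "counts"))
  cov <- sum(pooled)
  varReads <- cov - if (ref %in% BASES) pooled[[ref]] else max(pooled)
  cov < minCov || varReads < minReads || varReads / cov < minFreq
}

#' Apply the full artifact filter panel at one site
#'
#' Evaluates every enabled filter and returns the union of fired flags;
#' the result does not depend on evaluation order. In RDD mode sample I is
#' the genomic DNA sample (used by the H filter) and sample II supplies
#' the RNA calls; in RRD mode both samples are RNA and the H filter is
#' unavailable (a genomic post-hoc check is the documented substitute).
#' Positional distance filters require per-call read context and are
#' silently skipped when \code{hasContext} is \code{FALSE}.
#'
#' @param recsI,recsII Replicate record lists of samples I and II.
#' @param ref Reference base at the site.
#' @param panel A \linkS4class{FilterPanel}.
#' @param mode \code{"RDD"} or \code{"RRD"}.
#' @param hasContext Whether per-call read context is available.
#' @return Character vector of fired filter identifiers (possibly empty).
#' @export
applyFilterPanel <- function(recsI, recsII, ref, panel = FilterPanel(),
                             mode = c("RRD", "RDD"), hasContext = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(panel, "FilterPanel"))
  rnaRecs <- if (mode == "RDD") recsII else c(recsI, recsII)
  flags <- character(0)

  if (hasContext) {
    ctxs <- lapply(rnaRecs, `[[`, "ctx")
    ctxs <- ctxs[!vapply(ctxs, is.null, logical(1))]
    ctx <- if (length(ctxs)) do.call(rbind, ctxs) else NULL
    for (letter in intersect(names(FILTER_FEATURES), panel@enabled)) {
      feature <- FILTER_FEATURES[[letter]]
      d <- if (feature %in% names(panel@dOverride)) {
        panel@dOverride[[feature]]
      } else {
        panel@d
      }
      if (distanceFilter(ctx, feature, d, panel@r)) {
        flags <- c(flags, letter)
      }
    }
  }

  if ("H" %in% panel@enabled && mode == "RDD" &&
      homozygousFilter(recsI, panel@hMinCov, panel@hMaxMinorFrac)) {
    flags <- c(flags, "H")
  }
  if ("M" %in% panel@enabled && maxAlleleFilter(rnaRecs)) {
    flags <- c(flags, "M")
  }
  if ("V" %in% panel@enabled &&
      .variantPrefilter(rnaRecs, ref, panel@vMinCov, panel@vMinFreq,
                        panel@vMinReads)) {
    flags <- c(flags, "V")
  }
  flags[order(match(flags, FILTER_IDS))]
}
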