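#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

BASES <- c("A", "C", "G", "T")

#' Fitted Dirichlet-Multinomial concentration vector
#'
#' Holds the maximum-likelihood concentration parameters
#' \eqn{\alpha = (\alpha_A, \alpha_C, \alpha_G, \alpha_T)} of a
#' Dirichlet-Multinomial model fitted to the adjusted base-count vectors of
#' one replicate sample, together with the attained log-likelihood and
#' optimizer diagnostics.
#'
#' @slot alpha Named positive numeric 4-vector of concentration parameters.
#' @slot logLik Log-likelihood at the returned \code{alpha}.
#' @slot converged \code{TRUE} if the fit met its tolerance before the
#'   iteration cap; otherwise the best iterate so far is returned and flagged.
#' @slot iterations Number of fixed-point iterations performed.
#' @slot trace Log-likelihood trajectory, one value per iterate (including
#'   the starting point); non-decreasing by construction.
#'
#' @seealso [fitAlpha()], [logDirMult()]
#' @export
setClass("ConcentrationFit",
  representation(
    alpha = "numeric",
    logLik = "numeric",
    converged = "logical",
    iterations = "integer",
    trace = "numeric"
  )
)

setValidity("ConcentrationFit", function(object) {
  msg <- NULL
  if (length(object@alpha) != 4L || any(!is.finite(object@alpha)) ||
      any(object@alpha <= 0)) {
    msg <- c(msg, "'alpha' must be a finite, strictly positive 4-vector")
  }
  if (length(object@logLik) != 1L) msg <- c(msg, "'logLik' must be scalar")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ConcentrationFit Concentration parameters \eqn{\alpha}.
#' @param object,x A \code{ConcentrationFit}.
#' @export
setGeneric("concentration", function(x) standardGeneric("concentration"))

#' @rdname ConcentrationFit
#' @export
setMethod("concentration", "ConcentrationFit", function(x) x@alpha)

#' @describeIn ConcentrationFit Total concentration \eqn{\alpha_0 = \sum_k
#'   \alpha_k}, the overdispersion scale (larger means closer to multinomial).
#' @export
setGeneric("alpha0", function(x) standardGeneric("alpha0"))

#' @rdname ConcentrationFit
#' @export
setMethod("alpha0", "ConcentrationFit", function(x) sum(x@alpha))

setMethod("show", "ConcentrationFit", function(object) {
  cat("ConcentrationFit\n")
  cat("  alpha:", paste(sprintf("%s=%.4g", BASES, object@alpha),
                        collapse = " "), "\n")
  cat(sprintf("  alpha0: %.4g  logLik: %.6g\n", sum(object@alpha),
              object@logLik))
  cat(sprintf("  converged: %s after %d iteration(s)\n",
              object@converged, object@iterations))
})

#' Artifact filter panel configuration
#'
#' Configures the panel of site-level artifact filters:
#' positional distance filters against read edges (\code{D}), homopolymer
#' runs (\code{B}), INDEL positions (\code{I}) and splice sites (\code{Y}),
#' the genomic homozygosity filter (\code{H}) and the maximum-allele filter
#' (\code{M}). A distance filter removes a site when a proportion of at
#' least \code{r} of its RNA base calls lies within distance \code{d} of the
#' named read feature.
#'
#' Feature names (\code{read_edge}, \code{homopolymer}, \code{indel},
#' \code{splice}) are the primary configuration vocabulary; the single
#' letters are aliases.
#'
#' @slot enabled Character subset of \code{c("D","B","I","Y","H","M","V")};
#'   \code{V} is the optional raw variant-fraction pre-screen (off by
#'   default) used to reproduce threshold-based baseline callers.
#' @slot d Shared distance cutoff in nucleotides (default 5).
#' @slot r Proportion cutoff in (0, 1] (default 0.5).
#' @slot dOverride Named numeric of per-feature overrides of \code{d}
#'   (names among the feature names above).
#' @slot hMinCov Minimum pooled gDNA coverage for the H filter (default 10).
#' @slot hMaxMinorFrac Maximum pooled gDNA minor-allele fraction still
#'   considered homozygous (default 0.05).
#' @slot vMinCov,vMinFreq,vMinReads Coverage, variant-frequency and
#'   variant-read floors of the optional pre-screen (defaults 10, 0.1, 2).
#'
#' @seealso [applyFilterPanel()], [distanceFilter()]
#' @export
setClass("FilterPanel",
  representation(
    enabled = "character",
    d = "numeric",
    r = "numeric",
    dOverride = "numeric",
    hMinCov = "numeric",
    hMaxMinorFrac = "numeric",
    vMinCov = "numeric",
    vMinFreq = "numeric",
    vMinReads = "numeric"
  ),
  prototype(
    enabled = c("D", "B", "I", "Y", "H", "M"),
    d = 5, r = 0.5,
    dOverride = setNames(numeric(0), character(0)),
    hMinCov = 10, hMaxMinorFrac = 0.05,
    vMinCov = 10, vMinFreq = 0.1, vMinReads = 2
  )
)

FILTER_IDS <- c("D", "B", "I", "Y", "H", "M", "V")
FILTER_FEATURES <- c(D = "read_edge", B = "homopolymer", I = "indel",
                     Y = "splice")

setValidity("FilterPanel", function(object) {
  msg <- NULL
  if (!all(object@enabled %in% FILTER_IDS)) {
    msg <- c(msg, sprintf("'enabled' must be a subset of {%s}",
                          paste(FILTER_IDS, collapse = ",")))
  }
  if (object@d < 0) msg <- c(msg, "'d' must be >= 0")
  if (object@r <= 0 || object@r > 1) msg <- c(msg, "'r' must be in (0, 1]")
  if (length(object@dOverride) &&
      !all(names(object@dOverride) %in% FILTER_FEATURES)) {
    msg <- c(msg, "'dOverride' names must be feature names")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a FilterPanel
#'
#' @param enabled Filter identifiers to enable; letters or feature names
#'   (feature names are translated to their letter).
#' @param d,r Distance (nt) and proportion cutoffs of the distance filters.
#' @param dOverride Named per-feature distance overrides, e.g.
#'   \code{c(splice = 10)}.
#' @param hMinCov,hMaxMinorFrac Homozygosity filter: minimum pooled gDNA
#'   coverage and maximum minor-allele fraction.
#' @param vMinCov,vMinFreq,vMinReads Optional variant-fraction pre-screen
#'   thresholds (enable with \code{"V"}).
#' @return A \code{FilterPanel} object.
#' @examples
#' FilterPanel()                      # full default panel
#' FilterPanel(enabled = c("H", "M")) # no positional filters
#' @export
FilterPanel <- function(enabled = c("D", "B", "I", "Y", "H", "M"),
                        d = 5, r = 0.5,
                        dOverride = numeric(0),
                        hMinCov = 10, hMaxMinorFrac = 0.05,
                        vMinCov = 10, vMinFreq = 0.1, vMinReads = 2) {
  feat2letter <- setNames(names(FILTER_FEATURES), FILTER_FEATURES)
  enabled <- vapply(enabled, function(f) {
    if (f %in% names(feat2letter)) feat2letter[[f]] else f
  }, character(1), USE.NAMES = FALSE)
  new("FilterPanel", enabled = unique(enabled), d = d, r = r,
      dOverride = dOverride, hMinCov = hMinCov,
      hMaxMinorFrac = hMaxMinorFrac,
      vMinCov = vMinCov, vMinFreq = vMinFreq, vMinReads = vMinReads)
}

setMethod("show", "FilterPanel", function(object) {
  cat("FilterPanel\n")
  cat("  enabled:", if (length(object@enabled))
    paste(object@enabled, collapse = ",") else "(none)", "\n")
  cat(sprintf("  distance d=%g nt, proportion r=%g\n", object@d, object@r))
  if (length(object@dOverride)) {
    cat("  d overrides:", paste(sprintf("%s=%g", names(object@dOverride),
                                        object@dOverride), collapse = " "),
        "\n")
  }
  cat(sprintf("  H: min gDNA coverage %g, max minor fraction %g\n",
              object@hMinCov, object@hMaxMinorFrac))
})

#' Per-site replicate base-count tallies for a two-sample comparison
#'
#' The central data container: for each genomic site, the base-call count
#' vectors of every replicate of both samples (sample I and sample II), as
#' produced by [tallyBam()], [readCountTable()] or [simulateDataset()].
#' In RNA-DNA mode ("RDD") sample I is the genomic DNA sample; in RNA-RNA
#' mode ("RRD") both samples are cDNA.
#'
#' Each per-replicate record is a list with elements \code{counts} (named
#' integer A/C/G/T vector), \code{quals} (list of four integer vectors of
#' per-call Phred scores, one per base channel) and, for BAM-derived
#' tallies, \code{ctx}: a data frame of per-call read context (called base,
#' quality, distances in nt to read start/end, nearest INDEL, nearest splice
#' junction and nearest homopolymer run; \code{NA} when the read has no such
#' feature). Text count tables carry no read context, so positional filters
#' are disabled for them.
#'
#' @slot sites \code{GRanges} of the tallied sites (width-1 ranges,
#'   0-based-start stored as 1-based GRanges positions) with a \code{ref}
#'   metadata column holding the reference base.
#' @slot tallyI,tallyII Lists parallel to \code{sites}; element \code{i} is
#'   the list of per-replicate records of that sample at site \code{i}.
#' @slot mode \code{"RDD"} or \code{"RRD"}.
#' @slot hasContext \code{TRUE} when per-call read context is available.
#'
#' @seealso [callSites()], [tallyBam()], [readCountTable()]
#' @export
setClass("SiteTallySet",
  representation(
    sites = "GRanges",
    tallyI = "list",
    tallyII = "list",
    mode = "character",
    hasContext = "logical"
  )
)

setValidity("SiteTallySet", function(object) {
  msg <- NULL
  n <- length(object@sites)
  if (length(object@tallyI) != n || length(object@tallyII) != n) {
    msg <- c(msg, "tally lists must be parallel to 'sites'")
  }
  if (!object@mode %in% c("RDD", "RRD")) {
    msg <- c(msg, "'mode' must be \"RDD\" or \"RRD\"")
  }
  if (is.null(mcols(object@sites)$ref)) {
    msg <- c(msg, "'sites' must carry a 'ref' metadata column")
  }
  if (n > 0L) {
    ns1 <- lengths(object@tallyI)
    ns2 <- lengths(object@tallyII)
    if (any(ns1 < 1L) || any(ns2 < 1L)) {
      msg <- c(msg, "every site needs at least one replicate per sample")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a SiteTallySet
#'
#' @param sites \code{GRanges} with a \code{ref} metadata column.
#' @param tallyI,tallyII Per-site lists of per-replicate records (see
#'   \linkS4class{SiteTallySet}).
#' @param mode \code{"RDD"} (sample I is genomic DNA) or \code{"RRD"}.
#' @param hasContext Whether per-call read context is present.
#' @return A \code{SiteTallySet}.
#' @export
SiteTallySet <- function(sites, tallyI, tallyII, mode = c("RRD", "RDD"),
                         hasContext = FALSE) {
  mode <- match.arg(mode)
  new("SiteTallySet", sites = sites, tallyI = tallyI, tallyII = tallyII,
      mode = mode, hasContext = hasContext)
}

#' @describeIn SiteTallySet Site coordinates as \code{GRanges}.
#' @param x A \code{SiteTallySet}.
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' @rdname SiteTallySet
#' @export
setMethod("siteRanges", "SiteTallySet", function(x) x@sites)

#' @describeIn SiteTallySet Per-replicate records for one sample;
#'   \code{sample} is \code{"I"} or \code{"II"}.
#' @param sample Which sample, \code{"I"} or \code{"II"}.
#' @export
setGeneric("replicateTallies",
           function(x, sample = c("I", "II"))
             standardGeneric("replicateTallies"))

#' @rdname SiteTallySet
#' @export
setMethod("replicateTallies", "SiteTallySet", function(x,
                                                       sample = c("I", "II")) {
  sample <- match.arg(sample)
  if (sample == "I") x@tallyI else x@tallyII
})

#' @describeIn SiteTallySet Comparison mode, \code{"RDD"} or \code{"RRD"}.
#' @export
setGeneric("comparisonMode", function(x) standardGeneric("comparisonMode"))

#' @rdname SiteTallySet
#' @export
setMethod("comparisonMode", "SiteTallySet", function(x) x@mode)

#' @describeIn SiteTallySet Whether per-call read context is available
#'   (BAM-derived tallies only).
#' @export
setGeneric("hasReadContext", function(x) standardGeneric("hasReadContext"))

#' @rdname SiteTallySet
#' @export
setMethod("hasReadContext", "SiteTallySet", function(x) x@hasContext)

setMethod("length", "SiteTallySet", function(x) length(x@sites))

setMethod("show", "SiteTallySet", function(object) {
  n <- length(object@sites)
  cat(sprintf("SiteTallySet (%s mode): %d site(s)\n", object@mode, n))
  if (n > 0L) {
    cat(sprintf("  replicates: sample I n=%d, sample II n=%d\n",
                length(object@tallyI[[1L]]), length(object@tallyII[[1L]])))
  }
  cat(sprintf("  read context: %s\n",
              if (object@hasContext) "available" else "absent"))
})

#' Subset a SiteTallySet by site index
#'
#' @param x A \code{SiteTallySet}.
#' @param i Integer or logical index over sites.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "SiteTallySet", function(x, i, j, ..., drop = FALSE) {
  new("SiteTallySet", sites = x@sites[i], tallyI = x@tallyI[i],
      tallyII = x@tallyII[i], mode = x@mode, hasContext = x@hasContext)
})

## Internal constructor for one replicate record. `quals` may be a scalar
## (constant quality for all calls) or a list of four per-channel vectors.
.repRecord <- function(counts, quals = 30L, ctx = NULL) {
  counts <- as.integer(counts)
  names(counts) <- BASES
  if (!is.list(quals)) {
    quals <- lapply(counts, function(k) rep(as.integer(quals), k))
  }
  names(quals) <- BASES
  stopifnot(all(lengths(quals) == counts))
  list(counts = counts, quals = quals, ctx = ctx)
}
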