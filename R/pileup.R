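#' @importFrom Rsamtools BamFile ScanBamParam scanBam scanBamFlag FaFile
#'   scanFa scanFaIndex indexFa asBam
#' @importFrom Biostrings DNAStringSet
#' @importFrom GenomeInfoDb seqnames
NULL

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Parse a CIGAR string into (length, op) pairs.
.parseCigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops) || paste(ops, collapse = "") != cigar) {
    stop("malformed CIGAR: ", cigar)
  }
  list(len = as.integer(sub("[MIDNSHP=X]", "", ops)),
       op = sub("\\d+", "", ops))
}

## Walk one read's CIGAR: per aligned base, reference position, query
## position, and distances (nt) to the nearest INDEL and splice junction.
## Distance convention: a base immediately adjacent to a junction/INDEL
## boundary has distance 1; read-edge distances are 0 at the terminal base.
.walkCigar <- function(pos, cigar, qlen) {
  cg <- .parseCigar(cigar)
  refPos <- pos
  qPos <- 1L
  refAt <- integer(0)
  qAt <- integer(0)
  indels <- list() # each: c(start, end) in ref space (insertion: end<start)
  splices <- list()
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]
    len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      refAt <- c(refAt, refPos:(refPos + len - 1L))
      qAt <- c(qAt, qPos:(qPos + len - 1L))
      refPos <- refPos + len
      qPos <- qPos + len
    } else if (op == "I") {
      # insertion between refPos-1 and refPos
      indels[[length(indels) + 1L]] <- c(refPos, refPos - 1L)
      qPos <- qPos + len
    } else if (op == "D") {
      indels[[length(indels) + 1L]] <- c(refPos, refPos + len - 1L)
      refPos <- refPos + len
    } else if (op == "N") {
      splices[[length(splices) + 1L]] <- c(refPos, refPos + len - 1L)
      refPos <- refPos + len
    } else if (op == "S") {
      qPos <- qPos + len
    } # H, P consume nothing we track
  }

  distTo <- function(features) {
    if (!length(features)) return(rep(NA_integer_, length(refAt)))
    d <- rep(Inf, length(refAt))
    for (f in features) {
      s <- f[1L]
      e <- f[2L]
      if (e < s) { # insertion point between s-1 and s
        di <- ifelse(refAt < s, s - refAt, refAt - s + 1L)
      } else {
        di <- ifelse(refAt < s, s - refAt,
                     ifelse(refAt > e, refAt - e, 0L))
      }
      d <- pmin(d, di)
    }
    as.integer(d)
  }

  data.frame(
    refPos = refAt,
    qPos = qAt,
    dStart = qAt - 1L,
    dEnd = qlen - qAt,
    dIndel = distTo(indels),
    dSplice = distTo(splices)
  )
}

## Homopolymer runs (>= minRun identical bases) in a reference chunk.
## Returns matrix with columns start, end (absolute coordinates).
.homopolymerRuns <- function(refChars, offset, minRun = 7L) {
  r <- rle(refChars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= minRun & r$values %in% BASES
  cbind(start = starts[keep] + offset - 1L, end = ends[keep] + offset - 1L)
}

.distToRuns <- function(pos, runs) {
  if (is.null(runs) || nrow(runs) == 0L) return(rep(NA_integer_, length(pos)))
  d <- rep(Inf, length(pos))
  for (i in seq_len(nrow(runs))) {
    di <- ifelse(pos < runs[i, 1L], runs[i, 1L] - pos,
                 ifelse(pos > runs[i, 2L], pos - runs[i, 2L], 0L))
    d <- pmin(d, di)
  }
  as.integer(d)
}

## Transcribed-strand assignment for one read under a library type.
.readStrand <- function(flag, libraryType) {
  isReverse <- bitwAnd(flag, 16L) > 0L
  isPaired <- bitwAnd(flag, 1L) > 0L
  isFirst <- bitwAnd(flag, 64L) > 0L
  readStrand <- if (isReverse) "-" else "+"
  if (libraryType == "unstranded") return(".")
  flipRead1 <- libraryType == "fr-firststrand"
  flip <- if (!isPaired || isFirst) flipRead1 else !flipRead1
  if (flip) c("+" = "-", "-" = "+")[[readStrand]] else readStrand
}

## Extract per-call records from one BAM over one region.
.bamCalls <- function(bamPath, region, minMapq, minBaseQual, libraryType,
                      homopolymerRuns) {
  bf <- BamFile(bamPath)
  if (is.na(Rsamtools::index(bf)) || !file.exists(Rsamtools::index(bf))) {
    stop("BAM file is not indexed (expected .bai): ", bamPath)
  }
  param <- ScanBamParam(
    which = region,
    what = c("flag", "pos", "mapq", "cigar", "seq", "qual"),
    flag = scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                       isDuplicate = FALSE, isSupplementaryAlignment = FALSE)
  )
  res <- scanBam(bf, param = param)[[1L]]
  keep <- !is.na(res$mapq) & res$mapq >= minMapq & !is.na(res$pos) &
    !is.na(res$cigar)
  if (!any(keep)) {
    return(data.frame(refPos = integer(0), strand = character(0),
                      base = character(0), qual = integer(0),
                      dStart = integer(0), dEnd = integer(0),
                      dIndel = integer(0), dSplice = integer(0),
                      dHomo = integer(0)))
  }
  seqs <- as.character(res$seq[keep])
  quals <- as(res$qual[keep], "IntegerList")
  flags <- res$flag[keep]
  poss <- res$pos[keep]
  cigars <- res$cigar[keep]

  out <- vector("list", sum(keep))
  for (i in seq_along(poss)) {
    qlen <- nchar(seqs[i])
    walk <- .walkCigar(poss[i], cigars[i], qlen)
    chars <- substring(seqs[i], walk$qPos, walk$qPos)
    qv <- quals[[i]][walk$qPos]
    strand <- .readStrand(flags[i], libraryType)
    if (strand == "-") chars <- COMPLEMENT[chars]
    ok <- chars %in% BASES & qv >= minBaseQual
    if (!any(ok)) next
    out[[i]] <- data.frame(
      refPos = walk$refPos[ok], strand = strand, base = unname(chars[ok]),
      qual = qv[ok], dStart = walk$dStart[ok], dEnd = walk$dEnd[ok],
      dIndel = walk$dIndel[ok], dSplice = walk$dSplice[ok]
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(refPos = integer(0), strand = character(0),
               base = character(0), qual = integer(0), dStart = integer(0),
               dEnd = integer(0), dIndel = integer(0), dSplice = integer(0))
  calls$dHomo <- .distToRuns(calls$refPos, homopolymerRuns)
  calls
}

## One replicate record (counts/quals/ctx) from a call table at one site.
.callsToRecord <- function(calls) {
  counts <- vapply(BASES, function(b) sum(calls$base == b), integer(1))
  quals <- lapply(BASES, function(b) as.integer(calls$qual[calls$base == b]))
  names(quals) <- BASES
  ctx <- data.frame(base = calls$base, qual = calls$qual,
                    dStart = calls$dStart, dEnd = calls$dEnd,
                    dIndel = calls$dIndel, dSplice = calls$dSplice,
                    dHomo = calls$dHomo)
  list(counts = counts, quals = quals, ctx = ctx)
}

#' Build per-site replicate base-count tallies from BAM files
#'
#' Extracts, for every site in \code{region} covered by all replicates of
#' both samples, the per-replicate base-call count vectors together with
#' the per-call read context (distances to read edges, INDELs, splice
#' junctions and reference homopolymer runs) needed by the positional
#' artifact filters. Reads below \code{minMapq}, duplicate-flagged reads
#' (SAM flag 0x400; mark duplicates upstream), secondary/supplementary
#' alignments and base calls below \code{minBaseQual} or calling N are
#' excluded. For stranded library types, calls are assigned to the
#' transcribed strand (base identities complemented for reverse-strand
#' assignments) and sites are reported per strand.
#'
#' Overlapping mate pairs are counted twice (both mates contribute); set
#' deduplication upstream if single-molecule counting is required.
#'
#' @param bamsI,bamsII Character vectors of coordinate-sorted, indexed BAM
#'   paths, one per replicate of sample I / II.
#' @param region \code{GRanges} of length 1 delimiting the tallied window.
#' @param fasta Path to the reference FASTA (a .fai index is created if
#'   absent).
#' @param minMapq Minimum read mapping quality (default 20).
#' @param minBaseQual Minimum base-call Phred quality (default 20).
#' @param libraryType \code{"unstranded"}, \code{"fr-firststrand"} or
#'   \code{"fr-secondstrand"}.
#' @param mode Comparison mode stored in the result (\code{"RDD"}: sample
#'   I is genomic DNA).
#' @param homopolymerMinRun Minimum length of a reference homopolymer run
#'   (default 7 nt).
#' @return A \linkS4class{SiteTallySet} with read context.
#' @export
tallyBam <- function(bamsI, bamsII, region, fasta,
                     minMapq = 20, minBaseQual = 20,
                     libraryType = c("unstranded", "fr-firststrand",
                                     "fr-secondstrand"),
                     mode = c("RDD", "RRD"), homopolymerMinRun = 7L) {
  libraryType <- match.arg(libraryType)
  mode <- match.arg(mode)
  stopifnot(is(region, "GRanges"), length(region) == 1L)

  fa <- FaFile(fasta)
  if (!file.exists(paste0(fasta, ".fai"))) indexFa(fa)
  idx <- scanFaIndex(fa)
  contig <- as.character(seqnames(region))
  if (!contig %in% as.character(seqnames(idx))) {
    stop("contig '", contig, "' absent from reference ", fasta)
  }

  # reference chunk (padded) for homopolymer-run detection and ref lookup
  pad <- 200L
  contigLen <- GenomicRanges::end(idx)[
    as.character(seqnames(idx)) == contig][1L]
  from <- max(1L, GenomicRanges::start(region) - pad)
  to <- min(contigLen, GenomicRanges::end(region) + pad)
  refChunk <- GRanges(contig, IRanges(from, to))
  refChars <- strsplit(toupper(as.character(scanFa(fa, refChunk)[[1L]])),
                       "")[[1L]]
  runs <- .homopolymerRuns(refChars, from, homopolymerMinRun)

  perBam <- function(paths) {
    lapply(paths, .bamCalls, region = region, minMapq = minMapq,
           minBaseQual = minBaseQual, libraryType = libraryType,
           homopolymerRuns = runs)
  }
  callsI <- perBam(bamsI)
  callsII <- perBam(bamsII)

  keyOf <- function(calls) paste(calls$refPos, calls$strand)
  inRegion <- function(calls) {
    calls[calls$refPos >= GenomicRanges::start(region) &
            calls$refPos <= GenomicRanges::end(region), , drop = FALSE]
  }
  callsI <- lapply(callsI, inRegion)
  callsII <- lapply(callsII, inRegion)
  covered <- function(calls) unique(keyOf(calls))
  common <- Reduce(intersect, c(lapply(callsI, covered),
                                lapply(callsII, covered)))
  if (!length(common)) {
    sites <- GRanges(ref = character(0))
    return(SiteTallySet(sites, list(), list(), mode = mode,
                        hasContext = TRUE))
  }
  parts <- do.call(rbind, strsplit(common, " "))
  posns <- as.integer(parts[, 1L])
  strands <- parts[, 2L]
  o <- order(posns, strands)
  posns <- posns[o]
  strands <- strands[o]
  common <- common[o]

  refBase <- refChars[posns - from + 1L]
  flip <- strands == "-"
  refBase[flip] <- COMPLEMENT[refBase[flip]]

  recordsFor <- function(callsList) {
    lapply(seq_along(common), function(i) {
      lapply(callsList, function(calls) {
        .callsToRecord(calls[keyOf(calls) == common[i], , drop = FALSE])
      })
    })
  }
  tallyI <- recordsFor(callsI)
  tallyII <- recordsFor(callsII)
  # transpose: we built per-site lists already
  sites <- GRanges(contig, IRanges(posns, posns),
                   strand = ifelse(strands == ".", "*", strands),
                   ref = refBase)
  SiteTallySet(sites, tallyI, tallyII, mode = mode, hasContext = TRUE)
}
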