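## Run a block of code with a locally scoped RNG seed; the caller's RNG
## state is untouched.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Draw a realized variant frequency around an expected target
#'
#' Adds biological variability to a site's expected variant frequency by
#' drawing from a Beta distribution with mean \code{expected} and
#' concentration \code{betaConc} (shapes \eqn{a = f\beta},
#' \eqn{b = (1-f)\beta}): small \eqn{\beta} (10) yields highly variable
#' sites, large \eqn{\beta} (100) near-deterministic ones. Degenerate
#' means 0 and 1 return themselves.
#'
#' @param expected Expected frequency in \[0, 1\].
#' @param betaConc Concentration parameter \eqn{\beta > 0}.
#' @param seed Optional integer seed (locally scoped).
#' @return A draw in \[0, 1\].
#' @export
sampleTargetFrequency <- function(expected, betaConc, seed = NULL) {
  stopifnot(expected >= 0, expected <= 1, betaConc > 0)
  .withSeed(seed, {
    if (expected <= 0) return(0)
    if (expected >= 1) return(1)
    stats::rbeta(1L, shape1 = expected * betaConc,
                 shape2 = (1 - expected) * betaConc)
  })
}

## Per-replicate count vector: two-allele mixture plus uniform sequencing
## error at rate errRate (each read miscalls uniformly over the other 3).
.siteCounts <- function(refBase, varBase, freq, coverage, errRate) {
  p <- setNames(numeric(4L), BASES)
  p[refBase] <- 1 - freq
  p[varBase] <- p[varBase] + freq
  p <- p * (1 - errRate) + (1 - p) * errRate / 3
  as.integer(stats::rmultinom(1L, size = coverage, prob = p))
}

#' Simulate a two-sample benchmark dataset
#'
#' Generates per-site replicate count stacks reproducing the in-silico
#' benchmark designs at desk scale, together with a ground-truth table.
#'
#' In the \strong{RDD} scenario sample I is a mono-allelic genomic DNA
#' sample (reference base plus sequencing errors) and sample II is a set
#' of cDNA replicates; variant sites carry a Beta-sampled variant
#' frequency in the cDNA only. In the \strong{RRD} scenario both samples
#' are cDNA replicate sets; variant sites differ in expected frequency by
#' at least \code{deltaFloor} between the samples, and SNP sites carry
#' pairwise-equal expected frequencies (0.5 or 1, heterozygous or
#' homozygous) in both samples, functioning as negatives/noise. Remaining
#' sites are clean (sequencing error only). Expected variant frequencies
#' are drawn once per site (RDD: uniform on \[0.05, 0.95\]; RRD: base
#' frequency uniform on \[0.05, 0.45\] plus a gap uniform on
#' \[\code{deltaFloor}, 0.5\]); realized per-replicate frequencies are
#' Beta-distributed around the sample target with concentration
#' \code{betaConc}.
#'
#' @param scenario \code{"RDD"} or \code{"RRD"}.
#' @param nSites Total number of sites (default 2000, desk scale).
#' @param nVariant Number of variant sites (default \code{nSites/2}).
#' @param nSnp Number of SNP sites (RRD only; default \code{nSites/2} in
#'   RRD, 0 in RDD).
#' @param replicates cDNA replicates per sample, 1..5 (default 3).
#' @param coverageRange Per-replicate coverage drawn uniformly from this
#'   integer range (default c(5, 1000)).
#' @param betaConc Beta concentration of the frequency draws, one of the
#'   benchmark's 10/50/100 regimes (default 100).
#' @param baseErrorRate Uniform per-base sequencing error rate (default
#'   0.001, consistent with the constant simulated quality of 30).
#' @param qual Constant Phred score attached to simulated calls.
#' @param deltaFloor Minimum expected-frequency difference of RRD variant
#'   sites (default 0.1).
#' @param variantFreqI,variantFreqII Optional fixed expected variant
#'   frequencies for the variant sites (recycled), overriding the random
#'   draws; used for controlled effect-size sweeps. In RDD the genomic
#'   side is always 0 and \code{variantFreqI} must be absent.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return List with \code{tally} (a \linkS4class{SiteTallySet}) and
#'   \code{truth} (data frame: contig, position (0-based), class,
#'   refBase, varBase, targetFreqI, targetFreqII, realizedFreqsI/II
#'   (comma-joined per replicate), betaConc, seed).
#' @examples
#' sim <- simulateDataset("RRD", nSites = 50, seed = 1)
#' table(sim$truth$class)
#' @export
simulateDataset <- function(scenario = c("RDD", "RRD"),
                            nSites = 2000L,
                            nVariant = NULL, nSnp = NULL,
                            replicates = 3L,
                            coverageRange = c(5L, 1000L),
                            betaConc = 100,
                            baseErrorRate = 0.001,
                            qual = 30L,
                            deltaFloor = 0.1,
                            variantFreqI = NULL, variantFreqII = NULL,
                            seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(nVariant)) nVariant <- nSites %/% 2L
  if (is.null(nSnp)) nSnp <- if (scenario == "RRD") nSites %/% 2L else 0L
  if (scenario == "RDD" && nSnp > 0L) {
    stop("SNP sites are only implanted in the RRD scenario")
  }
  if (nVariant + nSnp > nSites) {
    stop("nVariant + nSnp must not exceed nSites")
  }
  stopifnot(replicates >= 1L, replicates <= 5L,
            coverageRange[1L] >= 1L, coverageRange[2L] >= coverageRange[1L])

  .withSeed(seed, {
    classes <- c(rep("variant", nVariant), rep("snp", nSnp),
                 rep("clean", nSites - nVariant - nSnp))
    classes <- sample(classes)
    refBase <- sample(BASES, nSites, replace = TRUE)
    varBase <- vapply(refBase, function(r)
      sample(setdiff(BASES, r), 1L), character(1))

    fI <- numeric(nSites)
    fII <- numeric(nSites)
    isVar <- classes == "variant"
    isSnp <- classes == "snp"
    if (scenario == "RDD") {
      if (!is.null(variantFreqI)) {
        stop("the genomic side of an RDD simulation has frequency 0")
      }
      fII[isVar] <- if (is.null(variantFreqII)) {
        stats::runif(sum(isVar), 0.05, 0.95)
      } else {
        rep_len(variantFreqII, sum(isVar))
      }
    } else {
      if (is.null(variantFreqI) != is.null(variantFreqII)) {
        stop("supply both or neither of variantFreqI/variantFreqII")
      }
      if (!is.null(variantFreqI)) {
        fI[isVar] <- rep_len(variantFreqI, sum(isVar))
        fII[isVar] <- rep_len(variantFreqII, sum(isVar))
      } else {
        base <- stats::runif(sum(isVar), 0.05, 0.45)
        gap <- stats::runif(sum(isVar), deltaFloor, 0.5)
        hi <- pmin(base + gap, 1)
        flip <- stats::runif(sum(isVar)) < 0.5
        fI[isVar] <- ifelse(flip, hi, base)
        fII[isVar] <- ifelse(flip, base, hi)
      }
      fSnp <- sample(c(0.5, 1), sum(isSnp), replace = TRUE)
      fI[isSnp] <- fSnp
      fII[isSnp] <- fSnp
    }

    nRepI <- if (scenario == "RDD") 1L else replicates
    nRepII <- replicates

    drawSample <- function(target, nRep, ref, var) {
      lapply(seq_len(nRep), function(i) {
        f <- if (target <= 0) 0 else if (target >= 1) 1 else
          stats::rbeta(1L, target * betaConc, (1 - target) * betaConc)
        cov <- sample(coverageRange[1L]:coverageRange[2L], 1L)
        counts <- .siteCounts(ref, var, f, cov, baseErrorRate)
        attr(counts, "freq") <- f
        counts
      })
    }

    tallyI <- vector("list", nSites)
    tallyII <- vector("list", nSites)
    realI <- character(nSites)
    realII <- character(nSites)
    for (s in seq_len(nSites)) {
      cI <- drawSample(fI[s], nRepI, refBase[s], varBase[s])
      cII <- drawSample(fII[s], nRepII, refBase[s], varBase[s])
      realI[s] <- paste(sprintf("%.6f", vapply(cI, attr, numeric(1),
                                               "freq")), collapse = ",")
      realII[s] <- paste(sprintf("%.6f", vapply(cII, attr, numeric(1),
                                                "freq")), collapse = ",")
      tallyI[[s]] <- lapply(cI, .repRecord, quals = qual)
      tallyII[[s]] <- lapply(cII, .repRecord, quals = qual)
    }

    pos <- 100L + (seq_len(nSites) - 1L) * 10L # 1-based, non-overlapping
    sites <- GRanges("sim1", IRanges(pos, pos), strand = "*",
                     ref = refBase)
    tally <- SiteTallySet(sites, tallyI, tallyII, mode = scenario,
                          hasContext = FALSE)
    truth <- data.frame(
      contig = "sim1", position = pos - 1L, class = classes,
      refBase = refBase, varBase = varBase,
      targetFreqI = fI, targetFreqII = fII,
      realizedFreqsI = realI, realizedFreqsII = realII,
      betaConc = betaConc,
      seed = if (is.null(seed)) NA_integer_ else seed
    )
    list(tally = tally, truth = truth)
  })
}

#' Write / read a simulation truth table
#'
#' @param truth Truth data frame from [simulateDataset()].
#' @param path TSV path.
#' @return \code{path} (write) or the truth data frame (read).
#' @export
writeTruthTable <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Score calls against a simulation truth table
#'
#' Joins a call set with a truth table by coordinate and tabulates the
#' confusion matrix: a site is a true positive when its truth class is
#' \code{variant} and it passed; SNP and clean sites are negatives (SNP
#' sites deliberately so in the RRD design, where they act as noise).
#' Precision is reported as \code{NaN} with a warning when there are no
#' predicted positives.
#'
#' @param calls \code{GRanges} from [callSites()] (or [readResults()]).
#' @param truth Truth data frame from [simulateDataset()].
#' @param threshold If supplied, re-derives \code{passed} as
#'   \code{filter == "." & z >= threshold}; otherwise the calls' own
#'   \code{passed} column is used.
#' @return One-row data frame: TP, FP, TN, FN, TPR, precision, accuracy,
#'   F, threshold.
#' @export
evaluateCalls <- function(calls, truth, threshold = NULL) {
  keyCalls <- paste(seqnames(calls), GenomicRanges::start(calls) - 1L)
  keyTruth <- paste(truth$contig, truth$position)
  idx <- match(keyCalls, keyTruth)
  if (anyNA(idx)) stop("call sites missing from the truth table")
  passed <- if (is.null(threshold)) {
    calls$passed
  } else {
    calls$filter == "." & calls$z >= threshold
  }
  isVar <- truth$class[idx] == "variant"
  # truth sites never called (e.g. zero-coverage skips) count as missed
  missedVar <- sum(truth$class == "variant") - sum(isVar)
  missedNeg <- sum(truth$class != "variant") - sum(!isVar)
  tp <- sum(isVar & passed)
  fp <- sum(!isVar & passed)
  fn <- sum(isVar & !passed) + missedVar
  tn <- sum(!isVar & !passed) + missedNeg
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NaN
  prec <- if (tp + fp > 0) {
    tp / (tp + fp)
  } else {
    warning("no predicted positives: precision undefined", call. = FALSE)
    NaN
  }
  acc <- (tp + tn) / (tp + fp + tn + fn)
  f <- if (is.finite(prec) && is.finite(tpr) && prec + tpr > 0) {
    2 * prec * tpr / (prec + tpr)
  } else {
    NaN
  }
  data.frame(TP = tp, FP = fp, TN = tn, FN = fn,
             TPR = tpr, precision = prec, accuracy = acc, F = f,
             threshold = if (is.null(threshold)) NA_real_ else threshold)
}

#' Metrics across all distinct score thresholds
#'
#' Evaluates the benchmark metrics at every distinct z value of the call
#' set, supporting threshold selection (the route by which the default
#' thresholds 1.15/1.56 were chosen on the original benchmark).
#'
#' @param calls \code{GRanges} from [callSites()].
#' @param truth Truth data frame from [simulateDataset()].
#' @return Data frame, one row per distinct threshold, columns as in
#'   [evaluateCalls()].
#' @export
thresholdSweep <- function(calls, truth) {
  thresholds <- sort(unique(calls$z))
  out <- lapply(thresholds, function(t)
    suppressWarnings(evaluateCalls(calls, truth, threshold = t)))
  do.call(rbind, out)
}

#' Write a small synthetic SAM file
#'
#' Emits a valid single-contig SAM file from a read table; intended to
#' build tiny text fixtures exercising the pileup extraction and the
#' positional filters (spliced/INDEL/homopolymer read contexts). Reads
#' are written in coordinate order.
#'
#' @param reads Data frame with columns \code{qname}, \code{flag},
#'   \code{pos} (1-based), \code{mapq}, \code{cigar}, \code{seq} and
#'   optionally \code{qual} (string; defaults to constant Phred 30).
#' @param path Output SAM path.
#' @param contig,contigLength Reference sequence name and length for the
#'   \code{@SQ} header.
#' @return \code{path}, invisibly.
#' @export
writeSimulatedSam <- function(reads, path, contig = "sim1",
                              contigLength = 10000L) {
  need <- c("qname", "flag", "pos", "mapq", "cigar", "seq")
  stopifnot(all(need %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) {
    reads$qual
  } else {
    vapply(nchar(reads$seq), function(n)
      paste(rep(rawToChar(as.raw(30L + 33L)), n), collapse = ""),
      character(1))
  }
  o <- order(reads$pos)
  rows <- vapply(o, function(i) {
    paste(reads$qname[i], reads$flag[i], contig, reads$pos[i],
          reads$mapq[i], reads$cigar[i], "*", 0L, 0L, reads$seq[i],
          qual[i], sep = "\t")
  }, character(1))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, contigLength),
               rows), con = path)
  invisible(path)
}
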