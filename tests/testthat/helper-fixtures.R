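suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(Rsamtools)
})

BASES4 <- c("A", "C", "G", "T")

## Replicate record with constant (or per-channel) qualities.
makeRec <- function(counts, quals = 30L, ctx = NULL) {
  rddiff:::.repRecord(counts, quals = quals, ctx = ctx)
}

makeSample <- function(countMatrix, quals = 30L) {
  lapply(seq_len(nrow(countMatrix)), function(i)
    makeRec(countMatrix[i, ], quals = quals))
}

## All compositions of n into 4 non-negative parts.
compositions4 <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    out[[length(out) + 1L]] <- c(a, b, cc, n - a - b - cc)
  }
  do.call(rbind, out)
}

## Independent Dirichlet-Multinomial pmf for integer counts, computed
## with rising factorials (Pochhammer products) -- no lgamma, no shared
## code with the implementation under test.
pochhammer <- function(a, k) {
  if (k == 0L) return(1)
  prod(a + 0:(k - 1L))
}

dirmultPmfOracle <- function(x, alpha) {
  n <- sum(x)
  coef <- factorial(n) / prod(factorial(x))
  coef * prod(mapply(pochhammer, alpha, x)) / pochhammer(sum(alpha), n)
}

## Coarse grid search over alpha; returns the best grid log-likelihood.
gridFitOracle <- function(X, gridValues = c(0.25, 0.5, 1, 2, 4, 8, 16, 32,
                                            64, 128)) {
  best <- -Inf
  for (a in gridValues) for (b in gridValues) {
    for (cc in gridValues) for (d in gridValues) {
      ll <- sum(logDirMult(X, c(a, b, cc, d)))
      if (ll > best) best <- ll
    }
  }
  best
}

## Random per-call context table, as the BAM path would produce it.
randomCtx <- function(nCalls, pNA = 0.3) {
  mk <- function() {
    v <- sample(0:40, nCalls, replace = TRUE)
    v[runif(nCalls) < pNA] <- NA_integer_
    v
  }
  data.frame(
    base = sample(BASES4, nCalls, replace = TRUE),
    qual = sample(20:40, nCalls, replace = TRUE),
    dStart = sample(0:60, nCalls, replace = TRUE),
    dEnd = sample(0:60, nCalls, replace = TRUE),
    dIndel = mk(), dSplice = mk(), dHomo = mk()
  )
}

## Reference with a known homopolymer run (A x 10 at positions 301..310).
testReference <- function(dir = tempfile("ref")) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(4242)
  chars <- sample(BASES4, 1000, replace = TRUE, prob = c(.3, .2, .2, .3))
  # avoid accidental runs >= 7, then implant one
  r <- rle(chars)
  r$lengths[r$lengths >= 7] <- 6
  chars <- inverse.rle(r)
  chars <- chars[1:600]
  chars[301:310] <- "A"
  chars[300] <- "C" # keep the implanted run exactly 301..310
  chars[311] <- "C"
  seq <- DNAStringSet(paste(chars, collapse = ""))
  names(seq) <- "sim1"
  fa <- file.path(dir, "ref.fa")
  writeXStringSet(seq, fa)
  indexFa(fa)
  list(fasta = fa, chars = chars)
}

## SAM text -> sorted+indexed BAM in tempdir.
samToBam <- function(samPath) {
  dest <- sub("\\.sam$", "", samPath)
  asBam(samPath, destination = dest, overwrite = TRUE,
        indexDestination = TRUE)
}

## A read data frame row for writeSimulatedSam.
samRead <- function(qname, pos, cigar, seq, flag = 0L, mapq = 60L,
                    qual = NULL) {
  if (is.null(qual)) {
    qual <- paste(rep(rawToChar(as.raw(30L + 33L)), nchar(seq)),
                  collapse = "")
  }
  data.frame(qname = qname, flag = flag, pos = pos, mapq = mapq,
             cigar = cigar, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

## Independent minimal CIGAR walker used as the oracle for the pileup
## extraction: returns ref positions and bases of aligned M-block calls.
oracleWalk <- function(pos, cigar, seq) {
  nums <- as.integer(strsplit(gsub("[MIDNSH]", ",", cigar), ",")[[1]])
  ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1]]
  refp <- pos
  qp <- 1L
  out <- NULL
  for (i in seq_along(ops)) {
    if (ops[i] == "M") {
      for (k in 0:(nums[i] - 1L)) {
        out <- rbind(out, data.frame(
          refPos = refp + k,
          base = substr(seq, qp + k, qp + k),
          qPos = qp + k
        ))
      }
      refp <- refp + nums[i]
      qp <- qp + nums[i]
    } else if (ops[i] %in% c("D", "N")) {
      refp <- refp + nums[i]
    } else if (ops[i] %in% c("I", "S")) {
      qp <- qp + nums[i]
    }
  }
  out
}
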