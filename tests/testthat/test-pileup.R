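ref <- testReference()
refSeq <- paste(ref$chars, collapse = "")

## Sequence matching the reference over [pos, pos+len-1].
refRead <- function(pos, len) substr(refSeq, pos, pos + len - 1)

test_that("simple reads are counted and thresholds enforced", {
  dir <- tempfile("bam")
  dir.create(dir)
  # three reads over position 120 calling the reference (A-substituted),
  # plus one low-MAPQ read that must not contribute
  seqA <- paste0(refRead(101, 19), "A", refRead(121, 30)) # A at pos 120
  reads <- rbind(
    samRead("r1", 101, "50M", seqA),
    samRead("r2", 105, "50M", paste0(refRead(105, 15), "A",
                                     refRead(121, 34))),
    samRead("r3", 110, "50M", paste0(refRead(110, 10), "A",
                                     refRead(121, 39))),
    samRead("rLow", 101, "50M", seqA, mapq = 10L)
  )
  sam <- file.path(dir, "s1.sam")
  writeSimulatedSam(reads, sam, contig = "sim1", contigLength = 600)
  bam <- samToBam(sam)

  tally <- tallyBam(bam, bam, GRanges("sim1", IRanges(115, 125)),
                    ref$fasta, mode = "RRD")
  sites <- siteRanges(tally)
  i <- which(start(sites) == 120)
  expect_length(i, 1)
  rec <- replicateTallies(tally, "I")[[i]][[1]]
  # MAPQ-10 read excluded: 3 calls, all A
  expect_equal(unname(rec$counts), c(3, 0, 0, 0))
  expect_equal(sum(rec$counts), nrow(rec$ctx))
})

test_that("spliced reads carry junction distances from the CIGAR walk", {
  dir <- tempfile("bam")
  dir.create(dir)
  # 50M100N50M starting at 101: left block covers 101..150, junction
  # before 251. Site 148 sits 3 nt left of the junction.
  seq <- paste0(refRead(101, 50), refRead(251, 50))
  reads <- samRead("sp1", 101, "50M100N50M", seq)
  sam <- file.path(dir, "sp.sam")
  writeSimulatedSam(reads, sam, contig = "sim1", contigLength = 600)
  bam <- samToBam(sam)
  tally <- tallyBam(bam, bam, GRanges("sim1", IRanges(148, 148)),
                    ref$fasta, mode = "RRD")
  rec <- replicateTallies(tally, "I")[[1]][[1]]
  expect_equal(rec$ctx$dSplice, 3L)
  # oracle CIGAR walk agrees on which reference bases the read covers
  walk <- oracleWalk(101, "50M100N50M", seq)
  expect_true(148 %in% walk$refPos)
  expect_false(200 %in% walk$refPos) # intron is not covered
  # read-edge distances: 48th query base, 0-based from start
  expect_equal(rec$ctx$dStart, 47L)
  expect_equal(rec$ctx$dEnd, 100L - 48L)
})

test_that("indel and homopolymer distances populate the read context", {
  dir <- tempfile("bam")
  dir.create(dir)
  # deletion of 160..161: read 20M2D20M from 141 (query skips 2 ref nt)
  seq <- paste0(refRead(141, 20), refRead(163, 20))
  reads <- samRead("d1", 141, "20M2D20M", seq)
  sam <- file.path(dir, "del.sam")
  writeSimulatedSam(reads, sam, contig = "sim1", contigLength = 600)
  bam <- samToBam(sam)
  tally <- tallyBam(bam, bam, GRanges("sim1", IRanges(155, 170)),
                    ref$fasta, mode = "RRD")
  sites <- siteRanges(tally)
  rec <- replicateTallies(tally, "I")[[which(start(sites) == 158)]][[1]]
  # deletion spans 161..162; the base adjacent to it (160) has distance 1
  expect_equal(rec$ctx$dIndel, 3L)

  # homopolymer run implanted at 301..310: distance 0 inside, grows outside
  seqH <- refRead(296, 40)
  readsH <- samRead("h1", 296, "40M", seqH)
  samH <- file.path(dir, "homo.sam")
  writeSimulatedSam(readsH, samH, contig = "sim1", contigLength = 600)
  bamH <- samToBam(samH)
  tallyH <- tallyBam(bamH, bamH, GRanges("sim1", IRanges(298, 315)),
                     ref$fasta, mode = "RRD")
  sitesH <- siteRanges(tallyH)
  dh <- vapply(c(298, 305, 313), function(p) {
    replicateTallies(tallyH, "I")[[
      which(start(sitesH) == p)]][[1]]$ctx$dHomo
  }, integer(1))
  expect_equal(dh, c(3L, 0L, 3L))
})

test_that("stranded libraries complement reverse-assigned calls", {
  dir <- tempfile("bam")
  dir.create(dir)
  seq <- refRead(401, 50)
  # single-end reverse-strand read (flag 16): under fr-secondstrand the
  # transcribed strand is '-' and bases are complemented
  reads <- samRead("f1", 401, "50M", seq, flag = 16L)
  sam <- file.path(dir, "str.sam")
  writeSimulatedSam(reads, sam, contig = "sim1", contigLength = 600)
  bam <- samToBam(sam)

  un <- tallyBam(bam, bam, GRanges("sim1", IRanges(420, 420)), ref$fasta,
                 libraryType = "unstranded", mode = "RRD")
  st <- tallyBam(bam, bam, GRanges("sim1", IRanges(420, 420)), ref$fasta,
                 libraryType = "fr-secondstrand", mode = "RRD")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  base <- ref$chars[420]
  recU <- replicateTallies(un, "I")[[1]][[1]]
  recS <- replicateTallies(st, "I")[[1]][[1]]
  expect_equal(recU$counts[[base]], 1L)
  expect_equal(recS$counts[[comp[[base]]]], 1L)
  expect_equal(as.character(strand(siteRanges(st))), "-")
  # complementing site ref too: involution keeps them consistent
  expect_equal(siteRanges(st)$ref, comp[[base]])
  expect_equal(comp[[comp[[base]]]], base)
})

test_that("missing contig and unindexed input fail loudly", {
  dir <- tempfile("bam")
  dir.create(dir)
  reads <- samRead("r1", 101, "50M", refRead(101, 50))
  sam <- file.path(dir, "e.sam")
  writeSimulatedSam(reads, sam, contig = "sim1", contigLength = 600)
  bam <- samToBam(sam)
  expect_error(
    tallyBam(bam, bam, GRanges("chrUnknown", IRanges(1, 10)), ref$fasta),
    "absent from reference"
  )
  # strip the index
  noIdx <- file.path(dir, "noidx.bam")
  file.copy(bam, noIdx)
  expect_error(
    tallyBam(noIdx, noIdx, GRanges("sim1", IRanges(1, 10)), ref$fasta)
  )
})

test_that("base calls below the quality floor are dropped", {
  dir <- tempfile("bam")
  dir.create(dir)
  seq <- refRead(101, 30)
  lowq <- paste(rep(rawToChar(as.raw(10L + 33L)), 30), collapse = "")
  reads <- rbind(
    samRead("hi", 101, "30M", seq),
    samRead("lo", 101, "30M", seq, qual = lowq)
  )
  sam <- file.path(dir, "q.sam")
  writeSimulatedSam(reads, sam, contig = "sim1", contigLength = 600)
  bam <- samToBam(sam)
  tally <- tallyBam(bam, bam, GRanges("sim1", IRanges(110, 110)),
                    ref$fasta, minBaseQual = 20, mode = "RRD")
  rec <- replicateTallies(tally, "I")[[1]][[1]]
  expect_equal(sum(rec$counts), 1L) # only the q30 read contributes
})
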