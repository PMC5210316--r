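#' @importFrom utils read.table write.table
NULL

## Decimal round-half-even formatting. Works on the %.12f decimal
## representation of the double so that printed-decimal ties (e.g.
## 1.2345675 -> "1.234568") resolve by the half-even rule rather than by
## binary representation accidents.
.formatHalfEven <- function(x, digits = 6L) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(format(v))
    neg <- v < 0
    s <- sprintf("%.12f", abs(v))
    dot <- regexpr(".", s, fixed = TRUE)
    intPart <- substr(s, 1L, dot - 1L)
    frac <- substr(s, dot + 1L, nchar(s))
    keep <- substr(frac, 1L, digits)
    rest <- substr(frac, digits + 1L, nchar(frac))
    half <- paste0("5", strrep("0", nchar(rest) - 1L))
    roundUp <- (rest > half) ||
      (rest == half &&
         as.integer(substr(keep, digits, digits)) %% 2L == 1L)
    val <- as.numeric(paste0(intPart, ".", keep))
    if (roundUp) val <- val + 10^(-digits)
    sprintf("%s%.*f", if (neg && val != 0) "-" else "", digits, val)
  }, character(1))
}

.countTableHeader <- function(n1, n2) {
  c("contig", "position", "strand",
    paste0("s1_r", seq_len(n1)), paste0("s2_r", seq_len(n2)))
}

#' Read a per-site base-count table
#'
#' Parses the tab-separated count-table format: a header line (prefixed
#' \code{#}) naming columns \code{contig}, \code{position} (0-based),
#' \code{strand}, then one \code{"A,C,G,T"} integer quadruple per
#' replicate, samples identified by the \code{s1_r*}/\code{s2_r*} naming
#' convention. Count tables carry no per-call read context, so positional
#' distance filters are disabled downstream (a warning is issued once at
#' call time); per-call qualities are imputed as the constant
#' \code{defaultQual}.
#'
#' @param path Path to the TSV file.
#' @param mode Comparison mode of the resulting tally set.
#' @param defaultQual Constant Phred score assumed for all calls
#'   (default 30).
#' @return A \linkS4class{SiteTallySet} without read context.
#' @seealso [writeCountTable()]
#' @export
readCountTable <- function(path, mode = c("RRD", "RDD"), defaultQual = 30L) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1L], "#")) {
    stop("count table must start with a '#'-prefixed header line")
  }
  header <- strsplit(sub("^#", "", lines[1L]), "\t")[[1L]]
  s1 <- grep("^s1_r", header)
  s2 <- grep("^s2_r", header)
  if (!identical(header[1:3], c("contig", "position", "strand")) ||
      !length(s1) || !length(s2)) {
    stop("malformed count-table header: ", lines[1L])
  }
  body <- lines[-1L]
  nField <- length(header)

  parseQuad <- function(txt, lineNo) {
    v <- suppressWarnings(as.integer(strsplit(txt, ",")[[1L]]))
    if (length(v) != 4L || any(is.na(v)) || any(v < 0)) {
      stop("malformed A,C,G,T quadruple at line ", lineNo, ": '", txt, "'")
    }
    v
  }

  n <- length(body)
  contig <- character(n)
  posn <- integer(n)
  strand <- character(n)
  tallyI <- vector("list", n)
  tallyII <- vector("list", n)
  for (i in seq_len(n)) {
    lineNo <- i + 1L
    f <- strsplit(body[i], "\t")[[1L]]
    if (length(f) != nField) {
      stop("line ", lineNo, ": expected ", nField, " columns, found ",
           length(f))
    }
    contig[i] <- f[1L]
    posn[i] <- suppressWarnings(as.integer(f[2L]))
    if (is.na(posn[i]) || posn[i] < 0) {
      stop("line ", lineNo, ": invalid position '", f[2L], "'")
    }
    strand[i] <- f[3L]
    if (!strand[i] %in% c("+", "-", ".")) {
      stop("line ", lineNo, ": invalid strand '", f[3L], "'")
    }
    tallyI[[i]] <- lapply(f[s1], function(x)
      .repRecord(parseQuad(x, lineNo), defaultQual))
    tallyII[[i]] <- lapply(f[s2], function(x)
      .repRecord(parseQuad(x, lineNo), defaultQual))
  }
  sites <- GRanges(contig, IRanges(posn + 1L, posn + 1L),
                   strand = ifelse(strand == ".", "*", strand),
                   ref = rep(NA_character_, n))
  SiteTallySet(sites, tallyI, tallyII, mode = mode, hasContext = FALSE)
}

#' Write a SiteTallySet as a count table
#'
#' Inverse of [readCountTable()]: positions are written 0-based; a
#' round-trip reproduces all counts exactly. Read context and per-call
#' qualities are not representable in this format and are dropped.
#'
#' @param tally A \linkS4class{SiteTallySet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(tally, path) {
  stopifnot(is(tally, "SiteTallySet"))
  n <- length(tally)
  n1 <- if (n) length(tally@tallyI[[1L]]) else 1L
  n2 <- if (n) length(tally@tallyII[[1L]]) else 1L
  header <- paste0("#", paste(.countTableHeader(n1, n2), collapse = "\t"))
  sites <- siteRanges(tally)
  rows <- vapply(seq_len(n), function(i) {
    quadsI <- vapply(tally@tallyI[[i]], function(r)
      paste(r$counts, collapse = ","), character(1))
    quadsII <- vapply(tally@tallyII[[i]], function(r)
      paste(r$counts, collapse = ","), character(1))
    st <- as.character(GenomicRanges::strand(sites)[i])
    if (st == "*") st <- "."
    paste(c(as.character(seqnames(sites)[i]),
            GenomicRanges::start(sites)[i] - 1L, st, quadsI, quadsII),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a comparison result table
#'
#' Writes one BED-like TSV row per tested site, in coordinate order:
#' \code{contig}, \code{start} (0-based), \code{end}, \code{ref_base},
#' \code{z} (6 decimals, round-half-even), \code{strand}, one
#' \code{"A,C,G,T"} quadruple per replicate of sample I then sample II,
#' \code{filter} (comma-joined flags or \code{.}), \code{balanced} (0/1)
#' and \code{passed} (0/1). The header line is prefixed \code{#}; a
#' \code{##config=} line echoes the run configuration when supplied.
#'
#' @param calls \code{GRanges} as returned by [callSites()].
#' @param path Output path.
#' @param config Optional named list echoed into a \code{##config=} line.
#' @return \code{path}, invisibly.
#' @seealso [readResults()]
#' @export
writeResults <- function(calls, path, config = NULL) {
  n1 <- if (length(calls)) length(strsplit(calls$countsI[1L], ";")[[1L]])
        else 1L
  n2 <- if (length(calls)) length(strsplit(calls$countsII[1L], ";")[[1L]])
        else 1L
  header <- paste0("#", paste(
    c("contig", "start", "end", "ref_base", "z", "strand",
      paste0("s1_r", seq_len(n1)), paste0("s2_r", seq_len(n2)),
      "filter", "balanced", "passed"), collapse = "\t"))
  pre <- character(0)
  if (!is.null(config)) {
    pre <- paste0("##config=", paste(names(config),
                                     vapply(config, function(x)
                                       paste(x, collapse = ","),
                                       character(1)),
                                     sep = "=", collapse = ";"))
  }
  rows <- vapply(seq_along(calls), function(i) {
    st <- as.character(GenomicRanges::strand(calls)[i])
    if (st == "*") st <- "."
    ref <- calls$ref[i]
    if (is.na(ref)) ref <- "N"
    paste(c(as.character(seqnames(calls)[i]),
            GenomicRanges::start(calls)[i] - 1L,
            GenomicRanges::end(calls)[i],
            ref, .formatHalfEven(calls$z[i]), st,
            strsplit(calls$countsI[i], ";")[[1L]],
            strsplit(calls$countsII[i], ";")[[1L]],
            calls$filter[i],
            as.integer(calls$balanced[i]),
            as.integer(calls$passed[i])), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb") # byte-stable newlines across platforms
  on.exit(close(con))
  writeLines(c(pre, header, rows), con, sep = "\n")
  invisible(path)
}

#' Read a comparison result table
#'
#' @param path Path written by [writeResults()].
#' @return \code{GRanges} with the same metadata columns [callSites()]
#'   produces (counts re-joined into \code{countsI}/\code{countsII}).
#' @export
readResults <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (!length(lines) || !startsWith(lines[1L], "#")) {
    stop("missing header line in ", path)
  }
  header <- strsplit(sub("^#", "", lines[1L]), "\t")[[1L]]
  s1 <- grep("^s1_r", header)
  s2 <- grep("^s2_r", header)
  body <- lines[-1L]
  if (!length(body)) {
    gr <- GRanges(ref = character(0))
    mcols(gr) <- DataFrame(ref = character(0), z = numeric(0),
                           filter = character(0), balanced = logical(0),
                           passed = logical(0), countsI = character(0),
                           countsII = character(0))
    return(gr)
  }
  f <- do.call(rbind, strsplit(body, "\t"))
  gr <- GRanges(f[, 1L],
                IRanges(as.integer(f[, 2L]) + 1L, as.integer(f[, 3L])),
                strand = ifelse(f[, 6L] == ".", "*", f[, 6L]))
  mcols(gr) <- DataFrame(
    ref = f[, 4L],
    z = as.numeric(f[, 5L]),
    filter = f[, match("filter", header)],
    balanced = f[, match("balanced", header)] == "1",
    passed = f[, match("passed", header)] == "1",
    countsI = apply(f[, s1, drop = FALSE], 1L, paste, collapse = ";"),
    countsII = apply(f[, s2, drop = FALSE], 1L, paste, collapse = ";")
  )
  gr
}
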